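#' Scale adjustment of a limited-coverage relationship matrix
#'
#' Solves the 2x2 linear system
#' \deqn{\mathrm{Avg}(\mathrm{diag}\,K)\,\alpha + \beta = \mathrm{Avg}(\mathrm{diag}\,V_{22})}
#' \deqn{\mathrm{Avg}(\mathrm{offdiag}\,K)\,\alpha + \beta = \mathrm{Avg}(\mathrm{offdiag}\,V_{22})}
#' and returns \eqn{K^* = \alpha K + \beta} (\eqn{\beta} added to every
#' entry), so that the average diagonal and off-diagonal of \eqn{K^*} match
#' those of \eqn{V_{22}}. When the system is singular (average diagonal equals
#' average off-diagonal of `K`), the fallback keeps the diagonal scale:
#' \eqn{\alpha = \mathrm{Avg}(\mathrm{diag}\,V_{22})/\mathrm{Avg}(\mathrm{diag}\,K)},
#' \eqn{\beta = 0}, with a warning.
#'
#' @param K square matrix over the subset-2 individuals (dimension >= 2).
#' @param V22 square matrix of the same dimension.
#' @return list with `alpha`, `beta`, `Kstar`.
#' @export
adjust_scale <- function(K, V22) {
  if (!all(dim(K) == dim(V22)) || nrow(K) < 2) {
    rlang::abort("K and V22 must be square, same dimension >= 2")
  }
  dK <- mean(diag(K)); oK <- offdiag_mean(K)
  dV <- mean(diag(V22)); oV <- offdiag_mean(V22)
  if (abs(dK - oK) <= 1e-12 * max(1, abs(dK))) {
    rlang::warn("scale-adjustment system singular (Avg diag K = Avg offdiag K); keeping diagonal scale only")
    alpha <- dV / dK
    beta <- 0
  } else {
    alpha <- (dV - oV) / (dK - oK)
    beta <- dV - alpha * dK
  }
  Kstar <- alpha * unclass(K) + beta
  dimnames(Kstar) <- dimnames(K)
  list(alpha = alpha, beta = beta, Kstar = Kstar)
}

#' Blend an adjusted matrix with the corresponding V block
#'
#' \deqn{K_w = (1 - w) K^* + w V_{22}} where the weighting factor `w` is the
#' fraction of genetic variation taken as uncaptured by the richer data layer.
#'
#' @param Kstar scale-adjusted matrix (see [adjust_scale()]).
#' @param V22 matching block of the full-coverage matrix.
#' @param w weight in `[0, 1]`.
#' @return the blended matrix.
#' @export
blend_Kw <- function(Kstar, V22, w) {
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1) {
    rlang::abort("w must be a single value in [0, 1]")
  }
  if (!all(dim(Kstar) == dim(V22))) rlang::abort("dimension mismatch between Kstar and V22")
  (1 - w) * Kstar + w * unclass(V22)
}

#' Single-step combined relationship matrix (H)
#'
#' Embeds a limited-coverage relationship matrix `K` (subset 2 = individuals
#' with the richer data layer) into a full-coverage matrix `V`:
#' \deqn{H_{11} = V_{11} + V_{12} V_{22}^{-1} (K_w - V_{22}) V_{22}^{-1} V_{21}}
#' \deqn{H_{12} = V_{12} V_{22}^{-1} K_w, \quad H_{21} = K_w V_{22}^{-1} V_{21}, \quad H_{22} = K_w}
#' with \eqn{K_w = (1-w) K^* + w V_{22}} and \eqn{K^*} from [adjust_scale()].
#' Subset 2 is identified by the row IDs of `K`; the output keeps `V`'s sample
#' order (blocks are reassembled in place). At `w = 1`, `H = V` exactly; with
#' an empty subset 1, `H = K_w`.
#'
#' @param K [grm()] or matrix over subset-2 IDs (all must appear in `V`).
#' @param V full-coverage [grm()] or ID-indexed matrix.
#' @param w weighting factor in `[0, 1]`.
#' @param ridge optional ridge added to `V22` before inversion (default 0;
#'   the printed formula relies on `w` for conditioning, but `w` does not
#'   enter `V22` itself).
#' @param cond_max condition-number gate for `V22` (default `1e12`).
#' @return a [grm()] of kind `"H"` over `V`'s samples, symmetrized on output.
#' @export
make_H <- function(K, V, w, ridge = 0, cond_max = 1e12) {
  ids2 <- check_ids(rownames(K), "subset-2")
  idsV <- check_ids(rownames(V), "V")
  missing2 <- setdiff(ids2, idsV)
  if (length(missing2)) {
    rlang::abort(sprintf("subset-2 IDs absent from V: %s",
                         paste(utils::head(missing2, 5), collapse = ", ")))
  }
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    rlang::abort("w must be a single value in [0, 1]")
  }
  idx2 <- which(idsV %in% ids2)
  idx1 <- setdiff(seq_along(idsV), idx2)
  ord2 <- idsV[idx2]
  Ko <- unclass(K)[ord2, ord2, drop = FALSE]   # K in V's subset-2 order
  Vm <- unclass(V)
  V22 <- Vm[idx2, idx2, drop = FALSE]

  adj <- adjust_scale(Ko, V22)
  Kw <- blend_Kw(adj$Kstar, V22, w)

  # internal consistency: the adjusted matrix must match V22's averages
  if (abs(dKs <- mean(diag(adj$Kstar)) - mean(diag(V22))) > 1e-8 * max(1, mean(abs(diag(V22))))) {
    rlang::abort(sprintf("scale adjustment failed its invariant (diag gap %.3g)", dKs))
  }

  n <- length(idsV)
  H <- matrix(0, n, n, dimnames = list(idsV, idsV))
  if (length(idx1) == 0) {
    H[idx2, idx2] <- Kw
  } else {
    if (rcond(V22 + ridge * diag(nrow(V22))) < 1 / cond_max) {
      rlang::abort("V22 is numerically singular; raise w, pass ridge > 0, or psd_repair V")
    }
    V22inv <- chol_inverse(V22 + ridge * diag(nrow(V22)), "V22 (+ ridge)")
    V12 <- Vm[idx1, idx2, drop = FALSE]
    T12 <- V12 %*% V22inv
    H[idx1, idx1] <- Vm[idx1, idx1, drop = FALSE] + T12 %*% (Kw - V22) %*% t(T12)
    H12 <- T12 %*% Kw
    H[idx1, idx2] <- H12
    H[idx2, idx1] <- t(H12)
    H[idx2, idx2] <- Kw
  }
  grm(symmetrize(H), kind = "H")
}

#' Nested single-step matrix for triple integration
#'
#' Integrates three data layers by composing [make_H()] twice: first the
#' inner layer (e.g. genomic `G` over the genotyped subset) is embedded into
#' the base matrix (pedigree `A` over everyone) giving `H_GA`; then the outer
#' layer (e.g. transcriptomic `E` over the expression subset) is embedded
#' into `H_GA`. Subsets must nest: outer IDs within inner IDs within the base
#' universe. When `K_inner` is `NULL` this reduces to a single [make_H()]
#' call. One `w` applied to both levels reproduces a single-w sweep;
#' different `w_inner` / `w_outer` are allowed.
#'
#' @param K_outer matrix over the smallest subset (e.g. `E`).
#' @param V_base full-coverage base matrix (e.g. `A`).
#' @param K_inner optional matrix over the intermediate subset (e.g. `G`).
#' @param w_inner,w_outer weighting factors in `[0, 1]`.
#' @inheritParams make_H
#' @return a [grm()] of kind `"H"` over `V_base`'s samples.
#' @export
make_H_nested <- function(K_outer, V_base, K_inner = NULL,
                          w_inner, w_outer = w_inner, ridge = 0,
                          cond_max = 1e12) {
  if (is.null(K_inner)) {
    return(make_H(K_outer, V_base, w_outer, ridge = ridge, cond_max = cond_max))
  }
  ids_out <- rownames(K_outer); ids_in <- rownames(K_inner); ids_base <- rownames(V_base)
  bad_in <- setdiff(ids_in, ids_base)
  bad_out <- setdiff(ids_out, ids_in)
  if (length(bad_in) || length(bad_out)) {
    rlang::abort(sprintf(
      "subset nesting violated (outer within inner within base); offending IDs: %s",
      paste(utils::head(c(bad_out, bad_in), 10), collapse = ", ")))
  }
  H_inner <- make_H(K_inner, V_base, w_inner, ridge = ridge, cond_max = cond_max)
  make_H(K_outer, H_inner, w_outer, ridge = ridge, cond_max = cond_max)
}

#' Additive relationship matrix for a named model
#'
#' Maps the model vocabulary to matrix constructions:
#' `"A"` pedigree, `"G"` genomic, `"EG"` = H(E into G), `"GA"` = H(G into A),
#' `"EA"` = H(E into A), `"EGA"` = H(E into H(G into A)) (nested single-step).
#'
#' @param kind one of `"A"`, `"G"`, `"EG"`, `"GA"`, `"EA"`, `"EGA"`.
#' @param w weighting factor for the single-step kinds (ignored for A, G).
#' @param A,G,E the base matrices, as needed by `kind`.
#' @inheritParams make_H
#' @return a [grm()].
#' @export
make_model_grm <- function(kind, w = 0, A = NULL, G = NULL, E = NULL,
                           ridge = 0) {
  kind <- match.arg(kind, c("A", "G", "EG", "GA", "EA", "EGA"))
  need <- function(x, nm) {
    if (is.null(x)) rlang::abort(sprintf("model kind '%s' needs matrix %s", kind, nm))
    x
  }
  switch(kind,
    A = need(A, "A"),
    G = need(G, "G"),
    EG = make_H(need(E, "E"), need(G, "G"), w, ridge = ridge),
    GA = make_H(need(G, "G"), need(A, "A"), w, ridge = ridge),
    EA = make_H(need(E, "E"), need(A, "A"), w, ridge = ridge),
    EGA = make_H_nested(need(E, "E"), need(A, "A"), K_inner = need(G, "G"),
                        w_inner = w, w_outer = w, ridge = ridge))
}
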