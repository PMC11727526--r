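#' Genotype quality control
#'
#' Sequential marker filters as used for SNP-chip data: (1) drop markers with
#' call rate below `callrate_min`; (2) optionally impute remaining missing
#' calls (naive = per-marker rounded mean dosage); (3) drop markers with minor
#' allele frequency below `maf_min`. Each marker is counted once, at its first
#' failing stage.
#'
#' @param g a [geno_matrix()] with `n >= 2` samples.
#' @param callrate_min minimum fraction of non-missing calls (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param impute `"none"` or `"naive"`.
#' @return list with `geno` (filtered [geno_matrix()]) and `report` (a
#'   `qc_report` list: counts plus a per-marker tibble with allele frequency
#'   `p` of the counted allele and the filter verdict).
#' @export
qc_filter <- function(g, callrate_min = 0.95, maf_min = 0.01,
                      impute = c("none", "naive")) {
  impute <- match.arg(impute)
  calls <- g$calls
  if (nrow(calls) < 2) rlang::abort("need at least 2 samples for QC")
  n_input <- ncol(calls)

  callrate <- colMeans(!is.na(calls))
  fail_cr <- callrate < callrate_min

  calls2 <- calls[, !fail_cr, drop = FALSE]
  if (impute == "naive" && anyNA(calls2)) {
    mu <- colMeans(calls2, na.rm = TRUE)
    for (j in which(colSums(is.na(calls2)) > 0)) {
      calls2[is.na(calls2[, j]), j] <- as.integer(round(mu[j]))
    }
  }

  p2 <- colMeans(calls2, na.rm = TRUE) / 2
  maf2 <- pmin(p2, 1 - p2)
  fail_maf2 <- maf2 < maf_min

  verdict <- rep("retained", n_input)
  verdict[fail_cr] <- "fail_callrate"
  verdict[!fail_cr][fail_maf2] <- "fail_maf"
  p <- rep(NA_real_, n_input)
  p[!fail_cr] <- p2

  report <- structure(list(
    n_input = n_input,
    n_fail_callrate = sum(fail_cr),
    n_fail_maf = sum(fail_maf2),
    n_retained = sum(verdict == "retained"),
    markers = tibble::tibble(marker = colnames(calls),
                             callrate = callrate, p = p, verdict = verdict)
  ), class = "qc_report")

  if (report$n_retained == 0) {
    rlang::abort("all markers removed by QC",
                 class = "ssexp_qc_empty", report = report)
  }
  keep <- verdict == "retained"
  out <- geno_matrix(calls2[, !fail_maf2, drop = FALSE], g$map[keep, , drop = FALSE])
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<QC: %d markers in; %d fail call rate, %d fail MAF, %d retained>\n",
              x$n_input, x$n_fail_callrate, x$n_fail_maf, x$n_retained))
  invisible(x)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method: founders have \eqn{a_{ii} = 1}; in topological
#' order, \eqn{a_{ij} = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})} for earlier `j`
#' and \eqn{a_{ii} = 1 + 0.5\, a_{sire(i),dam(i)}}; unknown-parent terms
#' contribute 0. Inbreeding falls out of the recursion.
#'
#' @param ped a `ssexp_pedigree` (see [read_pedigree()], [as_pedigree()]).
#' @param subset optional IDs to return (submatrix of the full-pedigree A).
#' @return a [grm()] of kind `"A"`.
#' @export
make_A <- function(ped, subset = NULL) {
  ord <- attr(ped, "topo_order") %||% pedigree_topo_order(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  # index n+1 = "unknown parent" slot, kept identically zero
  si <- ifelse(is.na(ped$sire), n + 1L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), n + 1L, idx[ped$dam])
  A <- matrix(0, n + 1L, n + 1L)
  pos <- integer(n)  # topological position of each individual
  pos[ord] <- seq_len(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- si[i]; d <- di[i]
    if (k > 1L) {
      earlier <- ord[seq_len(k - 1L)]
      A[earlier, i] <- 0.5 * (A[earlier, s] + A[earlier, d])
      A[i, earlier] <- A[earlier, i]
    }
    A[i, i] <- 1 + 0.5 * A[s, d]
  }
  A <- A[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(A) <- list(ped$id, ped$id)
  out <- grm(A, kind = "A")
  if (!is.null(subset)) out <- grm_subset(out, subset)
  out
}

#' Genomic additive relationship matrix (G)
#'
#' \deqn{G = M_G M_G^\top / \sum_i 2 p_i (1 - p_i)} with columns of
#' \eqn{M_G} coded \eqn{0 - 2p_i,\ 1 - 2p_i,\ 2 - 2p_i} for genotypes
#' aa / Aa / AA, where \eqn{p_i} is the frequency of the counted allele A
#' computed from all genotyped individuals. Monomorphic markers contribute
#' zero columns and zero to the denominator and are reported via a message.
#'
#' @param g a [geno_matrix()] without missing calls (run [qc_filter()] first).
#' @return a [grm()] of kind `"G"`.
#' @export
make_G <- function(g) {
  calls <- g$calls
  if (anyNA(calls)) rlang::abort("make_G requires complete genotypes; run qc_filter() with imputation")
  p <- colMeans(calls) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) rlang::abort("all markers monomorphic: G undefined")
  if (any(!poly)) rlang::inform(sprintf("%d monomorphic marker(s) contribute nothing to G", sum(!poly)))
  M <- sweep(calls[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- sum(2 * p[poly] * (1 - p[poly]))
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(calls), rownames(calls))
  grm(G, kind = "G")
}

#' Genomic dominance relationship matrix (D)
#'
#' \deqn{D = M_D M_D^\top / (\mathrm{tr}(M_D M_D^\top)/n)} with genotypic
#' codes (aa, Aa, AA) = \eqn{(-2 p_{AA} p_{Aa},\ 4 p_{AA} p_{aa},\
#' -2 p_{aa} p_{Aa}) / c}, \eqn{c = p_{AA} + p_{aa} - (p_{AA} - p_{aa})^2},
#' where \eqn{p_{AA}, p_{Aa}, p_{aa}} are observed genotypic frequencies.
#' Markers with \eqn{c \le 10^{-12}} (including monomorphic ones) have
#' undefined codes; they are skipped and excluded from the trace
#' normalization. `trace(D) = n` by construction.
#'
#' @inheritParams make_G
#' @return a [grm()] of kind `"D"`.
#' @export
make_D <- function(g) {
  calls <- g$calls
  if (anyNA(calls)) rlang::abort("make_D requires complete genotypes; run qc_filter() with imputation")
  n <- nrow(calls)
  pAA <- colMeans(calls == 2)
  pAa <- colMeans(calls == 1)
  paa <- colMeans(calls == 0)
  cc <- pAA + paa - (pAA - paa)^2
  usable <- cc > 1e-12
  if (!any(usable)) rlang::abort("no usable markers for D (all degenerate)")
  if (any(!usable)) rlang::inform(sprintf("%d degenerate marker(s) skipped in D", sum(!usable)))
  M <- matrix(0, n, sum(usable))
  u <- which(usable)
  for (k in seq_along(u)) {
    j <- u[k]
    code <- unname(c(-2 * pAA[j] * pAa[j], 4 * pAA[j] * paa[j],
                     -2 * paa[j] * pAa[j]) / cc[j])
    M[, k] <- code[calls[, j] + 1L]
  }
  MMt <- tcrossprod(M)
  D <- MMt / (sum(diag(MMt)) / n)
  dimnames(D) <- list(rownames(calls), rownames(calls))
  grm(D, kind = "D")
}

#' Transcriptomic relationship matrix (E)
#'
#' \deqn{E = R R^\top / r} where `R` is the expression matrix with every
#' column (gene) centered to mean 0, and `r` the number of genes. With
#' `scale_columns = TRUE` columns are additionally scaled to unit variance
#' (zero-variance genes are dropped with a message).
#'
#' @param x numeric samples-by-genes matrix with ID rownames, `n >= 2`.
#' @param scale_columns center-only (default, the printed definition) or
#'   center-and-scale.
#' @return a [grm()] of kind `"E"`; rows sum to zero by construction.
#' @export
make_E <- function(x, scale_columns = FALSE) {
  if (!is.matrix(x) || nrow(x) < 2) rlang::abort("expression matrix must have >= 2 samples")
  if (anyNA(x) || any(!is.finite(x))) rlang::abort("expression matrix has non-finite values")
  check_ids(rownames(x))
  R <- scale(x, center = TRUE, scale = FALSE)
  if (scale_columns) {
    sds <- apply(R, 2, stats::sd)
    drop <- sds == 0
    if (any(drop)) rlang::inform(sprintf("%d zero-variance gene(s) dropped under scaling", sum(drop)))
    R <- R[, !drop, drop = FALSE]
    if (!ncol(R)) rlang::abort("no genes left after dropping zero-variance columns")
    R <- sweep(R, 2, sds[!drop], "/")
  }
  E <- tcrossprod(R) / ncol(R)
  dimnames(E) <- list(rownames(x), rownames(x))
  grm(E, kind = "E")
}

#' Repair a relationship matrix to positive semidefiniteness
#'
#' Eigenvalue clipping at zero plus re-symmetrization. Never applied
#' silently by other functions; call it explicitly when a solver complains.
#'
#' @param K a [grm()] or symmetric matrix.
#' @param min_eigen eigenvalues below this are raised to it (default 0).
#' @return repaired [grm()], same kind.
#' @export
psd_repair <- function(K, min_eigen = 0) {
  kind <- attr(K, "kind") %||% "custom"
  ev <- eigen(symmetrize(unclass(K)), symmetric = TRUE)
  vals <- pmax(ev$values, min_eigen)
  M <- ev$vectors %*% (vals * t(ev$vectors))
  dimnames(M) <- dimnames(K)
  grm(symmetrize(M), kind = kind)
}
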