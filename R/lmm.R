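#' Build a mixed-model design from a phenotype table
#'
#' Assembles `y` (trait records), `X` (intercept + reference-coded
#' categorical covariates; single-level covariates are dropped), `Z`
#' (record-to-individual incidence into `K_a`'s index) and `W` (incidence
#' into `K_D`'s index; all-zero rows for individuals outside `K_D`, whose
#' dominance contribution is taken as 0). Records with a missing trait value
#' are excluded from `y`/`X`/`Z`/`W`; their individuals stay in the K
#' matrices, which is how record-less individuals receive predictions.
#'
#' @param pheno long phenotype tibble (`id`, `trait`, `value`, covariates).
#' @param trait trait name.
#' @param K_a additive relationship matrix ([grm()]); every phenotyped ID
#'   must appear in its index.
#' @param K_D optional dominance relationship matrix.
#' @param fixed character vector of covariate column names (default
#'   `c("sex", "birth_year")`); the intercept is always included.
#' @return list of class `ssexp_design`: `y`, `X`, `Z`, `W`, `K_a`, `K_D`,
#'   `ids` (record IDs), `trait`.
#' @export
build_design <- function(pheno, trait, K_a, K_D = NULL,
                         fixed = c("sex", "birth_year")) {
  rows <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(rows)) rlang::abort(sprintf("no records for trait '%s'", trait))
  if (anyDuplicated(rows$id)) rlang::abort("duplicate (id, trait) records")
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  ids_a <- rownames(K_a)
  missing_ids <- setdiff(rows$id, ids_a)
  if (length(missing_ids)) {
    rlang::abort(sprintf("phenotyped IDs absent from the additive matrix: %s",
                         paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  n <- nrow(rows)

  fixed <- intersect(fixed, names(rows))
  fac <- lapply(rows[fixed], function(x) factor(as.character(x)))
  fac <- fac[vapply(fac, nlevels, 0L) >= 2]  # constants carry no contrast
  X <- if (length(fac)) {
    stats::model.matrix(~ ., data = as.data.frame(fac))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(sprintf("fixed-effect design is rank deficient; aliased: %s",
                         paste(aliased, collapse = ", ")))
  }

  Z <- matrix(0, n, length(ids_a), dimnames = list(NULL, ids_a))
  Z[cbind(seq_len(n), match(rows$id, ids_a))] <- 1
  W <- NULL
  if (!is.null(K_D)) {
    ids_d <- rownames(K_D)
    W <- matrix(0, n, length(ids_d), dimnames = list(NULL, ids_d))
    hit <- rows$id %in% ids_d
    W[cbind(which(hit), match(rows$id[hit], ids_d))] <- 1
  }
  structure(list(y = rows$value, X = X, Z = Z, W = W,
                 K_a = K_a, K_D = K_D, ids = rows$id, trait = trait),
            class = "ssexp_design")
}

# REML pieces at a given variance-component vector.
# Vparts: list of n x n covariance kernels (one per component).
reml_eval <- function(y, X, Vparts, theta) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vparts)) V <- V + theta[i] * Vparts[[i]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Vinv <- chol2inv(cV)
  XtVi <- crossprod(X, Vinv)
  XtViX <- XtVi %*% X
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  P <- Vinv - crossprod(XtVi, chol2inv(cX) %*% XtVi)
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + sum(y * Py))
  list(P = P, Py = Py, ll = ll, Vinv = Vinv, XtVi = XtVi, XtViX = XtViX)
}

#' Fit variance components by average-information REML
#'
#' Maximizes the REML log-likelihood of
#' \deqn{y = X b + Z a + W d + e,\quad a \sim N(0, K_a \sigma^2_a),\ d \sim
#'   N(0, K_D \sigma^2_d),\ e \sim N(0, I \sigma^2_e)}
#' over \eqn{\theta = (\sigma^2_a, \sigma^2_d, \sigma^2_e)} using the
#' average-information update \eqn{\theta \leftarrow \theta + AI^{-1} s} with
#' \eqn{s_i = -\tfrac12[\mathrm{tr}(P V_i) - y^\top P V_i P y]} and
#' \eqn{AI_{ij} = \tfrac12 y^\top P V_i P V_j P y}. Steps that would leave
#' the feasible region fall back to a multiplicative EM-style update; any
#' step that decreases the log-likelihood is halved, so accepted iterations
#' are non-decreasing in log-likelihood. Components are clamped below at
#' `1e-8 * var(y)`. Convergence: `|delta logLik| < tol` and maximum relative
#' parameter change `< 100 * tol`. A singular average-information matrix at
#' convergence with free components signals a non-identifiable structure
#' (e.g. `K_a` and `K_D` proportional) and raises an error reporting the
#' condition number.
#'
#' @param design a `ssexp_design` from [build_design()].
#' @param init optional named initial values
#'   (`sigma2_a`, `sigma2_d`, `sigma2_e`); default splits `var(y)` evenly.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return a `ssexp_fit`: variance components, REML log-likelihood and its
#'   per-iteration trace, convergence info, and the BLUP solutions from
#'   [blup_solve()] at the estimates.
#' @export
aireml_fit <- function(design, init = NULL, max_iter = 100, tol = 1e-6) {
  y <- design$y; X <- design$X
  n <- length(y)
  if (n <= ncol(X) + 2) rlang::abort("too few records for REML (need n > n_fixed + 2)")
  Vparts <- list(additive = design$Z %*% tcrossprod(unclass(design$K_a), design$Z))
  if (!is.null(design$W)) {
    Vparts$dominance <- design$W %*% tcrossprod(unclass(design$K_D), design$W)
  }
  Vparts$residual <- diag(n)
  k <- length(Vparts)
  vy <- stats::var(y)
  lower <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / k, k) else {
    th <- c(init$sigma2_a, if (k == 3) init$sigma2_d, init$sigma2_e)
    if (length(th) != k) rlang::abort("init does not match the model's components")
    th
  }
  theta <- pmax(theta, lower)

  ev <- reml_eval(y, X, Vparts, theta)
  if (is.null(ev)) rlang::abort("initial covariance matrix not positive definite")
  ll_trace <- ev$ll
  converged <- FALSE
  ai <- NULL
  iter <- 0
  for (iter in seq_len(max_iter)) {
    q <- vapply(Vparts, function(Vi) drop(Vi %*% ev$Py), numeric(n))  # n x k
    yPVPy <- drop(crossprod(q, ev$Py))
    trPV <- vapply(Vparts, function(Vi) sum(ev$P * Vi), 0)
    score <- -0.5 * (trPV - yPVPy)
    Pq <- ev$P %*% q
    ai <- 0.5 * crossprod(q, Pq)

    proposal <- tryCatch(theta + solve(ai, score), error = function(e) NULL)
    if (!is.null(proposal) && all(is.finite(proposal)) && any(proposal < lower)) {
      # active-set step: pin boundary components at the clamp, Newton on the rest
      fix <- proposal < lower
      red <- tryCatch({
        out <- theta
        out[fix] <- lower
        if (any(!fix)) {
          out[!fix] <- theta[!fix] +
            solve(ai[!fix, !fix, drop = FALSE],
                  score[!fix] - ai[!fix, fix, drop = FALSE] %*% (lower - theta[fix]))
        }
        out
      }, error = function(e) NULL)
      proposal <- red
    }
    if (is.null(proposal) || any(!is.finite(proposal)) || any(proposal < lower)) {
      # EM-style multiplicative fallback keeps positivity
      proposal <- theta * yPVPy / pmax(trPV, .Machine$double.eps)
      proposal[!is.finite(proposal)] <- theta[!is.finite(proposal)]
    }
    proposal <- pmax(proposal, lower)

    # step-halving toward the current point until the likelihood does not drop
    new_ev <- NULL
    step <- proposal - theta
    for (h in 0:20) {
      cand <- pmax(theta + step / 2^h, lower)
      cand_ev <- reml_eval(y, X, Vparts, cand)
      if (!is.null(cand_ev) && cand_ev$ll >= ev$ll - 1e-10) {
        new_ev <- cand_ev; new_theta <- cand; break
      }
    }
    if (is.null(new_ev)) { new_theta <- theta; new_ev <- ev }

    d_ll <- new_ev$ll - ev$ll
    rel <- max(abs(new_theta - theta) / pmax(theta, lower))
    theta <- new_theta; ev <- new_ev
    ll_trace <- c(ll_trace, ev$ll)
    if (abs(d_ll) < tol && rel < 100 * tol) { converged <- TRUE; break }
  }

  free <- theta > lower * 1.0001
  if (converged && any(free) && !is.null(ai)) {
    rc <- rcond(ai)
    if (rc < 1e-12 && sum(free) > 1) {
      rlang::abort(sprintf(
        "variance components not identifiable (average-information matrix singular, rcond = %.2e); are K_a and K_D proportional?",
        rc))
    }
  }

  vc <- list(sigma2_a = unname(theta[1]),
             sigma2_d = if (k == 3) unname(theta[2]) else 0,
             sigma2_e = unname(theta[k]))
  fit <- blup_solve(design, vc)
  fit$reml_loglik <- ev$ll
  fit$ll_trace <- ll_trace
  fit$n_iter <- iter
  fit$converged <- converged
  fit
}

#' BLUP solutions at fixed variance components
#'
#' Henderson-style predictions in the inverse-free formulation: with
#' \eqn{V = Z K_a Z^\top \sigma^2_a + W K_D W^\top \sigma^2_d + I \sigma^2_e}
#' and \eqn{P} the REML projector,
#' \eqn{\hat b = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y},
#' \eqn{\hat a = \sigma^2_a K_a Z^\top P y},
#' \eqn{\hat d = \sigma^2_d K_D W^\top P y}. Because \eqn{K_a} covers every
#' individual in its index, record-less (e.g. validation) individuals get
#' predictions through the off-diagonal blocks of \eqn{K_a}.
#'
#' @param design a `ssexp_design` from [build_design()].
#' @param vc list with `sigma2_a`, `sigma2_d` (0 if no dominance term),
#'   `sigma2_e`.
#' @return a `ssexp_fit`: `b_hat`, `a_hat` (all individuals in `K_a`),
#'   `d_hat` (all individuals in `K_D`, or `NULL`), `vc`, `trait`, `ids`.
#' @export
blup_solve <- function(design, vc) {
  y <- design$y; X <- design$X
  n <- length(y)
  Vparts <- list(design$Z %*% tcrossprod(unclass(design$K_a), design$Z))
  th <- c(vc$sigma2_a)
  if (!is.null(design$W) && vc$sigma2_d > 0) {
    Vparts <- c(Vparts, list(design$W %*% tcrossprod(unclass(design$K_D), design$W)))
    th <- c(th, vc$sigma2_d)
  }
  Vparts <- c(Vparts, list(diag(n)))
  th <- c(th, vc$sigma2_e)
  ev <- reml_eval(y, X, Vparts, th)
  if (is.null(ev)) rlang::abort("V singular at the supplied variance components")
  b_hat <- tryCatch(drop(solve(ev$XtViX, ev$XtVi %*% y)),
                    error = function(e) drop(MASS::ginv(ev$XtViX) %*% ev$XtVi %*% y))
  names(b_hat) <- colnames(X)
  a_hat <- drop(vc$sigma2_a * unclass(design$K_a) %*% crossprod(design$Z, ev$Py))
  names(a_hat) <- rownames(design$K_a)
  d_hat <- NULL
  if (!is.null(design$W)) {
    d_hat <- drop(vc$sigma2_d * unclass(design$K_D) %*% crossprod(design$W, ev$Py))
    names(d_hat) <- rownames(design$K_D)
  }
  structure(list(b_hat = b_hat, a_hat = a_hat, d_hat = d_hat, vc = vc,
                 reml_loglik = ev$ll, ll_trace = ev$ll, n_iter = 0L,
                 converged = NA, trait = design$trait, ids = design$ids),
            class = "ssexp_fit")
}

#' @export
print.ssexp_fit <- function(x, ...) {
  cat(sprintf("<BLUP fit: trait %s, %d records, logLik %.3f%s>\n",
              x$trait %||% "?", length(x$ids), x$reml_loglik,
              if (isTRUE(x$converged)) sprintf(", converged in %d iter", x$n_iter) else ""))
  cat(sprintf("  sigma2: additive %.4g, dominance %.4g, residual %.4g\n",
              x$vc$sigma2_a, x$vc$sigma2_d, x$vc$sigma2_e))
  invisible(x)
}

#' @export
tidy.ssexp_fit <- function(x, effects = c("fixed", "additive", "dominance"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    fixed = tibble::tibble(term = names(x$b_hat), estimate = unname(x$b_hat)),
    additive = tibble::tibble(id = names(x$a_hat), estimate = unname(x$a_hat)),
    dominance = {
      if (is.null(x$d_hat)) rlang::abort("fit has no dominance term")
      tibble::tibble(id = names(x$d_hat), estimate = unname(x$d_hat))
    })
}

#' @export
glance.ssexp_fit <- function(x, ...) {
  tot <- x$vc$sigma2_a + x$vc$sigma2_d + x$vc$sigma2_e
  tibble::tibble(
    logLik = x$reml_loglik,
    sigma2_additive = x$vc$sigma2_a,
    sigma2_dominance = x$vc$sigma2_d,
    sigma2_residual = x$vc$sigma2_e,
    h2_narrow = x$vc$sigma2_a / tot,
    n_records = length(x$ids),
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' High-level model fit on an aligned dataset
#'
#' Convenience wrapper: builds the model's additive matrix with
#' [make_model_grm()], the dominance matrix with [make_D()] (unless
#' `include_dominance = FALSE`), the design with [build_design()], and fits
#' by [aireml_fit()].
#'
#' @param data list with elements `pheno` (long tibble), and whichever of
#'   `A`, `G`, `E`, `K_D` the model needs (see [simulate_population()] /
#'   [prepare_matrices()]).
#' @param trait trait name.
#' @param kind model's additive matrix kind (see [make_model_grm()]).
#' @param w weighting factor for single-step kinds.
#' @param include_dominance include the dominance random effect (the `_D`
#'   model family); default `TRUE`.
#' @param ... passed to [aireml_fit()].
#' @return a `ssexp_fit`.
#' @export
fit_blup <- function(data, trait, kind = "G", w = 0, include_dominance = TRUE, ...) {
  K_a <- make_model_grm(kind, w = w, A = data$A, G = data$G, E = data$E)
  K_D <- if (include_dominance) data$K_D else NULL
  design <- build_design(data$pheno, trait, K_a = K_a, K_D = K_D)
  aireml_fit(design, ...)
}
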