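#' Negative-allowed Box-Cox transformation
#'
#' Monotone power transform that tolerates non-positive phenotypes:
#' \deqn{z = 0.5\,(y + \sqrt{y^2 + \gamma^2})}{z = 0.5 (y + sqrt(y^2 + gamma^2))}
#' \deqn{y(\lambda,\gamma) = (z^\lambda - 1)/\lambda \ (\lambda \neq 0),\quad \ln z \ (\lambda = 0)}
#' With \eqn{\gamma > 0}, \eqn{z > 0} for every real \eqn{y}; with
#' \eqn{\gamma = 0} it reduces to the classical Box-Cox transform and requires
#' all-positive input. \eqn{|\lambda| < 10^{-8}} is snapped to the log branch
#' to avoid catastrophic cancellation in \eqn{(z^\lambda - 1)/\lambda}.
#'
#' @param y numeric vector.
#' @param lambda power parameter.
#' @param gamma offset parameter, `>= 0`; must be `> 0` if any `y <= 0`.
#' @return transformed numeric vector.
#' @export
boxcox_apply <- function(y, lambda, gamma = 0) {
  if (gamma < 0) rlang::abort("gamma must be >= 0")
  if (gamma == 0 && any(y <= 0, na.rm = TRUE)) {
    rlang::abort("gamma = 0 requires strictly positive phenotypes")
  }
  z <- 0.5 * (y + sqrt(y^2 + gamma^2))
  if (abs(lambda) < 1e-8) log(z) else (z^lambda - 1) / lambda
}

#' @rdname boxcox_apply
#' @param t transformed values to invert.
#' @export
boxcox_inverse <- function(t, lambda, gamma = 0) {
  z <- if (abs(lambda) < 1e-8) exp(t) else (lambda * t + 1)^(1 / lambda)
  # algebraic inverse of z = 0.5 (y + sqrt(y^2 + gamma^2))
  z - gamma^2 / (4 * z)
}

# profile log-likelihood of the transformed data under normality,
# including the Jacobian term sum(log dY/dy)
boxcox_loglik <- function(y, lambda, gamma) {
  z <- 0.5 * (y + sqrt(y^2 + gamma^2))
  if (any(z <= 0)) return(-Inf)
  t <- if (abs(lambda) < 1e-8) log(z) else (z^lambda - 1) / lambda
  n <- length(y)
  s2 <- stats::var(t) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  dzdy <- 0.5 * (1 + y / sqrt(y^2 + gamma^2))
  log_jac <- sum((lambda - 1) * log(z) + log(dzdy))
  -n / 2 * log(s2) + log_jac
}

#' Fit Box-Cox parameters by profile maximum likelihood
#'
#' Maximizes the normal-theory profile log-likelihood of the transformed data
#' (Jacobian included) over a 2-D candidate grid — \eqn{\lambda \in [-2, 2]}
#' step 0.05; \eqn{\gamma} over `0` (only when all `y > 0`) plus log-spaced
#' positive values scaled to the spread of `y` — followed by Nelder-Mead
#' refinement from the best grid point.
#'
#' @param y numeric vector, at least 10 finite observations with nonzero spread.
#' @return list of class `ssexp_boxcox`: `lambda`, `gamma`, `loglik`.
#' @export
boxcox_fit <- function(y) {
  y <- y[is.finite(y)]
  if (length(y) < 10) rlang::abort("need >= 10 finite observations to fit Box-Cox")
  spread <- stats::sd(y)
  if (!is.finite(spread) || spread == 0) rlang::abort("constant phenotype: Box-Cox fit is degenerate")

  lambdas <- seq(-2, 2, by = 0.05)
  gammas <- spread * 2^seq(-6, 3, by = 1)
  if (min(y) > 0) gammas <- c(0, gammas)
  grid <- expand.grid(lambda = lambdas, gamma = gammas)
  ll <- mapply(function(l, g) boxcox_loglik(y, l, g), grid$lambda, grid$gamma)
  best <- which.max(ll)

  # refine on (lambda, log-gamma); gamma = 0 refined on lambda only
  g0 <- grid$gamma[best]
  if (g0 == 0) {
    opt <- stats::optim(grid$lambda[best],
                        function(l) -boxcox_loglik(y, l, 0),
                        method = "Brent", lower = -3, upper = 3)
    fit <- list(lambda = opt$par, gamma = 0, loglik = -opt$value)
  } else {
    opt <- stats::optim(c(grid$lambda[best], log(g0)),
                        function(p) -boxcox_loglik(y, p[1], exp(p[2])),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500))
    fit <- list(lambda = opt$par[1], gamma = exp(opt$par[2]), loglik = -opt$value)
  }
  if (fit$loglik < max(ll)) fit <- list(lambda = grid$lambda[best],
                                        gamma = g0, loglik = ll[best])
  if (abs(fit$lambda) < 1e-8) fit$lambda <- 0
  structure(fit, class = "ssexp_boxcox")
}

#' @export
print.ssexp_boxcox <- function(x, ...) {
  cat(sprintf("<Box-Cox fit: lambda = %.4f, gamma = %.4g, logLik = %.3f>\n",
              x$lambda, x$gamma, x$loglik))
  invisible(x)
}

#' Transform one trait of a phenotype table
#'
#' Fits [boxcox_fit()] on the trait's non-missing values (once, on the full
#' vector) and replaces `value` by the transformed value.
#'
#' @param pheno long phenotype tibble (see [read_phenotypes()]).
#' @param trait trait name to transform.
#' @return the tibble with transformed `value`; the `ssexp_boxcox` fit is
#'   attached as attribute `boxcox`.
#' @export
transform_phenotypes <- function(pheno, trait) {
  rows <- pheno$trait == trait & !is.na(pheno$value)
  if (!any(rows)) rlang::abort(sprintf("no non-missing values for trait '%s'", trait))
  fit <- boxcox_fit(pheno$value[rows])
  pheno$value[rows] <- boxcox_apply(pheno$value[rows], fit$lambda, fit$gamma)
  attr(pheno, "boxcox") <- fit
  pheno
}
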