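# internal helpers shared across modules

# mean of off-diagonal entries; n >= 2 guaranteed by callers
offdiag_mean <- function(M) {
  n <- nrow(M)
  (sum(M) - sum(diag(M))) / (n * n - n)
}

# symmetrize and complain if the asymmetry is material
symmetrize <- function(M, warn_above = NULL, what = "matrix") {
  asym <- max(abs(M - t(M)))
  if (!is.null(warn_above) && asym > warn_above) {
    rlang::warn(sprintf("%s asymmetric (max |M - t(M)| = %.3g); symmetrized by (M + t(M))/2",
                        what, asym))
  }
  (M + t(M)) / 2
}

# ids attached to matrix-like objects must be unique, non-empty character
check_ids <- function(ids, what = "sample") {
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    rlang::abort(sprintf("%s IDs must be present and non-empty", what))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(sprintf("duplicate %s IDs: %s", what,
                         paste(utils::head(dup, 5), collapse = ", ")))
  }
  as.character(ids)
}

# derive a 32-bit-safe stream seed from (seed, index)
derive_seed <- function(seed, index = 0L) {
  as.integer((as.double(seed) %% 1e6) * 2011 + as.double(index) * 7919 + 1)
}

# solve a symmetric positive-definite system via Cholesky, with a clear error
chol_inverse <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    rlang::abort(sprintf("%s is not positive definite; consider psd_repair() or a ridge",
                         what))
  }
  chol2inv(ch)
}
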