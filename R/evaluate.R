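#' Cross-validation plan
#'
#' @param n_folds folds per replicate (default 10).
#' @param n_replicates independent re-partitions (default 10).
#' @param seed base seed; folds are deterministic given (seed, replicate).
#' @param w_grid weighting factors to sweep (default 0 to 1 step 0.05).
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10, n_replicates = 10, seed = 42,
                    w_grid = seq(0, 1, by = 0.05)) {
  stopifnot(n_folds >= 2, n_replicates >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), w_grid = w_grid),
            class = "cv_plan")
}

#' Partition individuals into validation folds
#'
#' Shuffled-index striping with a seeded generator: IDs are shuffled using a
#' stream derived from `(seed, replicate)` and dealt into `n_folds` sets
#' whose sizes differ by at most one. Deterministic given the pair.
#'
#' @param ids character vector of individual IDs.
#' @param plan a [cv_plan()] (or a fold count, with `seed` given).
#' @param replicate replicate number (1-based) feeding the stream.
#' @param seed base seed when `plan` is a bare fold count.
#' @return list of `n_folds` character vectors partitioning `ids`.
#' @export
make_folds <- function(ids, plan, replicate = 1L, seed = 42L) {
  if (!inherits(plan, "cv_plan")) plan <- cv_plan(n_folds = plan, seed = seed)
  n <- length(ids)
  if (n < plan$n_folds) {
    rlang::abort(sprintf("cannot split %d individuals into %d folds", n, plan$n_folds))
  }
  shuffled <- withr::with_seed(derive_seed(plan$seed, replicate),
                               sample(ids, n))
  split(shuffled, rep(seq_len(plan$n_folds), length.out = n))
}

#' Prediction accuracy of one validation fold
#'
#' Pearson correlation between predicted genetic values and (typically
#' fixed-effect-adjusted) observed phenotypes. Returns `NA` with a warning
#' when either vector has (near-)zero variance, so degenerate folds can be
#' dropped from summaries rather than poisoning them.
#'
#' @param pred,obs numeric vectors, length >= 3.
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
accuracy_cor <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 3) {
    rlang::abort("accuracy needs >= 3 prediction/observation pairs")
  }
  if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12) {
    rlang::warn("zero variance in predictions or observations; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs)
}

# fit on training records, return accuracy on the validation set.
# Validation individuals keep their place in the K matrices; only their
# records leave y/X/Z/W.
cv_fold_accuracy <- function(pheno, trait, K_a, K_D, val_ids,
                             metric = "genetic_adjusted") {
  train <- pheno[!(pheno$id %in% val_ids), , drop = FALSE]
  design <- build_design(train, trait, K_a = K_a, K_D = K_D)
  fit <- aireml_fit(design)

  val <- pheno[pheno$id %in% val_ids & pheno$trait == trait &
                 !is.na(pheno$value), , drop = FALSE]
  pred <- fit$a_hat[val$id]
  if (metric != "additive_adjusted" && !is.null(fit$d_hat)) {
    dv <- fit$d_hat[val$id]
    dv[is.na(dv)] <- 0  # individuals outside K_D contribute no dominance
    pred <- pred + dv
  }
  obs <- val$value
  if (metric != "raw") {
    # adjust by the training-fold fixed effects, using the training coding
    Xv <- design_fixed_rows(design, val)
    obs <- obs - drop(Xv %*% fit$b_hat)
  }
  accuracy_cor(pred, obs)
}

# rebuild fixed-effect rows for new records under the training design coding
design_fixed_rows <- function(design, rows) {
  Xv <- matrix(0, nrow(rows), ncol(design$X),
               dimnames = list(NULL, colnames(design$X)))
  Xv[, "(Intercept)"] <- 1
  for (cn in setdiff(colnames(design$X), "(Intercept)")) {
    # columns are reference-coded factor indicators named <var><level>
    for (v in c("sex", "birth_year")) {
      if (startsWith(cn, v) && v %in% names(rows)) {
        Xv[, cn] <- as.numeric(as.character(rows[[v]]) == sub(v, "", cn))
      }
    }
  }
  Xv
}

#' Replicated k-fold cross-validation of one model
#'
#' For each replicate, individuals with records are partitioned into folds;
#' for each fold, variance components are re-estimated on the training
#' records only ([aireml_fit()]), predictions for the held-out individuals
#' come from the K-matrix off-diagonal blocks, and accuracy is the Pearson
#' correlation of predicted genetic value (additive + dominance) with the
#' fixed-effect-adjusted phenotype. K matrices are built once per
#' (model, w) — they do not depend on phenotypes.
#'
#' @param data list with `pheno` plus `A`/`G`/`E`/`K_D` as the model needs.
#' @param trait trait name.
#' @param kind additive matrix kind (see [make_model_grm()]).
#' @param w weighting factor.
#' @param plan a [cv_plan()].
#' @param include_dominance include the dominance random effect.
#' @param metric `"genetic_adjusted"` (default: additive + dominance vs
#'   fixed-effect-adjusted phenotype), `"additive_adjusted"`, or `"raw"`.
#' @return tibble of class `ssexp_cv` with one row per (replicate, fold):
#'   `trait`, `model`, `w`, `replicate`, `fold`, `n_val`, `accuracy`,
#'   `failed`.
#' @export
cross_validate <- function(data, trait, kind = "G", w = 0, plan = cv_plan(),
                           include_dominance = TRUE,
                           metric = c("genetic_adjusted", "additive_adjusted", "raw")) {
  metric <- match.arg(metric)
  K_a <- make_model_grm(kind, w = w, A = data$A, G = data$G, E = data$E)
  K_D <- if (include_dominance) data$K_D else NULL
  pheno <- data$pheno[data$pheno$trait == trait & !is.na(data$pheno$value), ,
                      drop = FALSE]
  pheno <- pheno[pheno$id %in% rownames(K_a), , drop = FALSE]
  ids <- sort(unique(pheno$id))

  res <- purrr::map_dfr(seq_len(plan$n_replicates), function(r) {
    folds <- make_folds(ids, plan, replicate = r)
    purrr::imap_dfr(folds, function(val_ids, f) {
      acc <- tryCatch(cv_fold_accuracy(pheno, trait, K_a, K_D, val_ids, metric),
                      error = function(e) NA_real_)
      tibble::tibble(trait = trait, model = model_label(kind, include_dominance),
                     w = w, replicate = r, fold = as.integer(f),
                     n_val = length(val_ids), accuracy = acc,
                     failed = is.na(acc))
    })
  })
  if (mean(res$failed) > 0.2) {
    rlang::abort(sprintf("%.0f%% of folds failed; check model/data",
                         100 * mean(res$failed)))
  }
  class(res) <- c("ssexp_cv", class(res))
  res
}

model_label <- function(kind, include_dominance) {
  base <- switch(kind, A = "ABLUP", G = "GBLUP", EG = "ssEGBLUP",
                 GA = "ssGABLUP", EA = "ssEABLUP", EGA = "ssEGABLUP")
  if (include_dominance) paste0(base, "_D") else base
}

#' @export
summary.ssexp_cv <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$trait, .data$model, .data$w),
    mean_acc = mean(.data$accuracy, na.rm = TRUE),
    sd_acc = stats::sd(.data$accuracy, na.rm = TRUE),
    n_folds = dplyr::n(), n_failed = sum(.data$failed),
    .groups = "drop")
}

#' Sweep the weighting factor across models
#'
#' Runs [cross_validate()] for every model kind over the plan's `w_grid`
#' (single-step kinds) or once (`A`, `G`, which do not depend on `w`), and
#' summarises accuracy per (model, w). The per-model best `w` rows break
#' ties toward the smaller `w`.
#'
#' @inheritParams cross_validate
#' @param kinds character vector of model kinds.
#' @return tibble of class `ssexp_sweep`: `trait`, `model`, `w`, `mean_acc`,
#'   `sd_acc`, `n_folds`; attribute `best` holds the per-model argmax rows.
#' @export
sweep_w <- function(data, trait, kinds, plan = cv_plan(),
                    include_dominance = TRUE,
                    metric = "genetic_adjusted") {
  rows <- purrr::map_dfr(kinds, function(kind) {
    ws <- if (kind %in% c("A", "G")) NA_real_ else plan$w_grid
    purrr::map_dfr(ws, function(w) {
      cv <- cross_validate(data, trait, kind = kind,
                           w = if (is.na(w)) 0 else w, plan = plan,
                           include_dominance = include_dominance,
                           metric = metric)
      out <- summary(cv)
      out$w <- w
      out
    })
  })
  structure(rows, best = pick_best_w(rows),
            class = c("ssexp_sweep", class(rows)))
}

# per-model argmax over w; exact accuracy ties break toward the smaller w
pick_best_w <- function(rows) {
  dplyr::ungroup(dplyr::slice_min(
    dplyr::group_by(
      dplyr::slice_max(dplyr::group_by(tibble::as_tibble(rows), .data$model),
                       .data$mean_acc, n = 1, with_ties = TRUE),
      .data$model),
    .data$w, n = 1, with_ties = FALSE, na_rm = FALSE))
}

#' @export
print.ssexp_sweep <- function(x, ...) {
  NextMethod()
  cat("\nBest w per model:\n")
  print(attr(x, "best"))
  invisible(x)
}
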