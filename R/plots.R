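#' Plot a w-sweep
#'
#' Mean cross-validated accuracy against the weighting factor `w`, one line
#' (or point, for w-independent baselines) per model, with a ribbon of one
#' standard deviation across folds. Baseline models (`ABLUP`, `GBLUP`) are
#' drawn as horizontal reference lines.
#'
#' @param object a `ssexp_sweep` from [sweep_w()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.ssexp_sweep <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  base <- tab[is.na(tab$w), , drop = FALSE]
  ss <- tab[!is.na(tab$w), , drop = FALSE]
  p <- ggplot2::ggplot(ss, ggplot2::aes(x = .data$w, y = .data$mean_acc,
                                        colour = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_acc - .data$sd_acc,
                                      ymax = .data$mean_acc + .data$sd_acc,
                                      fill = .data$model),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "weighting factor w", y = "mean prediction accuracy",
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
  if (nrow(base)) {
    p <- p + ggplot2::geom_hline(
      data = base,
      ggplot2::aes(yintercept = .data$mean_acc, linetype = .data$model))
  }
  p
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object a `ssexp_cv` from [cross_validate()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.ssexp_cv <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$replicate),
                                    y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "replicate", y = "fold accuracy",
                  title = unique(tab$model)) +
    ggplot2::theme_minimal()
}
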