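#' Plot an imputation-accuracy report
#'
#' Histogram of per-animal imputation accuracies (the distribution is
#' typically negatively skewed under sparse panels).
#'
#' @param object An `imputation_accuracy` report.
#' @param bin_width Histogram bin width (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imputation_accuracy <- function(object, bin_width = 0.05, ...) {
  h <- per_animal_distribution(object, bin_width)$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(min(0, min(h$bin_mid[h$count > 0])), 1)) +
    ggplot2::labs(x = "per-animal imputation accuracy (r)",
                  y = "number of animals",
                  title = object$scenario_label %||% NULL) +
    ggplot2::theme_minimal()
}

#' Imputation accuracy against minor allele frequency
#'
#' @param report An `imputation_accuracy` report.
#' @param bin_width MAF bin width (default 0.05).
#' @return A ggplot with per-bin means and a loess smooth of the per-SNP
#'   correlations.
#' @export
plot_maf_accuracy <- function(report, bin_width = 0.05) {
  curve <- maf_binned_accuracy(report, bin_width = bin_width)
  pts <- report$per_snp[!is.na(report$per_snp$r), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$maf, y = .data$r)) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::geom_point(data = curve[!is.na(curve$mean_r), ],
                        ggplot2::aes(x = .data$bin_mid, y = .data$mean_r),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "minor allele frequency",
                  y = "imputation accuracy (per-SNP r)") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated prediction accuracies by method
#'
#' @param object A `scenario_table` (with prediction results) or a tibble
#'   with `method`, `trait`, `accuracy`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_table <- function(object, ...) {
  df <- if (inherits(object, "scenario_table")) object$prediction else object
  assert_that(!is.null(df), "no prediction results to plot")
  df$method <- factor(df$method, unique(df$method))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$accuracy,
                                   fill = .data$trait)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "prediction accuracy r(y1,y2)/h") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.imputation_accuracy
#' @param x An `imputation_accuracy` object.
#' @param y Unused.
#' @export
plot.imputation_accuracy <- function(x, y, ...) print(autoplot(x, ...))
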