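#' Tidy an animal-model fit
#'
#' @param x An `animal_model` from [em_reml()].
#' @param ... Unused.
#' @return One row per fixed-effect coefficient.
#' @export
tidy.animal_model <- function(x, ...) {
  tibble::tibble(term = paste0("b", seq_along(x$b) - 1L), estimate = x$b)
}

#' @rdname tidy.animal_model
#' @return `glance()`: a one-row tibble with the variance components,
#'   heritability and convergence status.
#' @export
glance.animal_model <- function(x, ...) {
  tibble::tibble(sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, h2 = x$h2,
                 converged = x$converged, iterations = x$iterations)
}

#' Tidy cross-validation accuracies
#'
#' @param x A `cv_accuracy` from [cross_validate()].
#' @param ... Unused.
#' @return Per-fold rows with method and trait attached.
#' @export
tidy.cv_accuracy <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), trait = attr(x, "trait"),
                 fold = x$fold, n_valid = x$n_valid,
                 h2_train = x$h2_train, r = x$r, accuracy = x$accuracy)
}

#' @rdname tidy.cv_accuracy
#' @export
glance.cv_accuracy <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), trait = attr(x, "trait"),
                 k = nrow(x), mean_accuracy = attr(x, "mean_accuracy"),
                 mean_h2_train = mean(x$h2_train, na.rm = TRUE))
}

#' Tidy an imputation-accuracy report
#'
#' @param x An `imputation_accuracy` report.
#' @param unit `"animal"` (default) or `"snp"`.
#' @param ... Unused.
#' @return The per-animal or per-SNP correlation table.
#' @export
tidy.imputation_accuracy <- function(x, unit = c("animal", "snp"), ...) {
  unit <- match.arg(unit)
  if (unit == "animal") x$per_animal else x$per_snp
}

#' @rdname tidy.imputation_accuracy
#' @export
glance.imputation_accuracy <- function(x, ...) {
  tibble::tibble(overall_r = x$overall_r, mean_snp_r = x$mean_snp_r,
                 n_animals = nrow(x$per_animal), n_snps = nrow(x$per_snp),
                 n_undefined_animals = x$n_undefined_animals,
                 n_undefined_snps = x$n_undefined_snps,
                 genotype_mode = x$genotype_mode,
                 scenario = x$scenario_label %||% NA_character_)
}

#' Tidy an imputation result into long format
#'
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @return One row per masked cell: `id`, `snp_id`, `p0`, `p1`, `p2`,
#'   `dosage`, `most_likely`.
#' @export
tidy.imputation_result <- function(x, ...) {
  cells <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(
    id = rownames(x$mask)[cells[, 1]],
    snp_id = colnames(x$mask)[cells[, 2]],
    p0 = x$p0[cells], p1 = x$p1[cells], p2 = x$p2[cells],
    dosage = x$dosage[cells], most_likely = x$most_likely[cells]
  )
}
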