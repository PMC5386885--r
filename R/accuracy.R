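#' Imputation accuracy report
#'
#' Scores imputed genotypes against the truth on masked cells only
#' (unmasked cells are trivially correct and would inflate the
#' correlation). The primary summary is the mean of per-animal
#' correlations, with the mean of per-SNP correlations reported alongside;
#' correlations undefined because one vector is constant are excluded and
#' counted.
#'
#' @param true_genotypes Individual x SNP 0/1/2 matrix of true genotypes.
#' @param result An `imputation_result`.
#' @param mask Optional logical matrix of scored cells (default: the
#'   result's own mask).
#' @param genotype_mode `"most_likely"` (default) or `"dosage"`: which
#'   imputed value enters the correlation.
#' @param scenario_label Optional label carried into the report.
#' @return List of class `imputation_accuracy` with `overall_r` (mean
#'   per-animal r), `mean_snp_r`, `per_animal` (tibble: `id`, `n_cells`,
#'   `r`), `per_snp` (tibble: `snp_id`, `n_animals`, `r`, `maf`),
#'   `n_undefined_animals`, `n_undefined_snps`, `scenario_label`.
#' @export
imputation_accuracy <- function(true_genotypes, result, mask = NULL,
                                genotype_mode = c("most_likely", "dosage"),
                                scenario_label = NULL) {
  genotype_mode <- match.arg(genotype_mode)
  mask <- mask %||% result$mask
  assert_that(any(mask), "no masked cells to score")
  imp <- if (genotype_mode == "dosage") result$dosage else result$most_likely
  ids <- rownames(imp)
  truth <- true_genotypes[ids, colnames(imp), drop = FALSE]

  per_animal <- purrr::map_dfr(ids, function(oid) {
    cells <- mask[oid, ]
    x <- truth[oid, cells]; yv <- imp[oid, cells]
    ok <- !is.na(yv)
    r <- if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(yv[ok]) > 0) {
      cor(x[ok], yv[ok])
    } else NA_real_
    tibble::tibble(id = oid, n_cells = sum(ok), r = r)
  })
  p <- colMeans(truth, na.rm = TRUE) / 2
  per_snp <- purrr::map_dfr(seq_len(ncol(imp)), function(j) {
    rows <- mask[, j]
    x <- truth[rows, j]; yv <- imp[rows, j]
    ok <- !is.na(yv)
    r <- if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(yv[ok]) > 0) {
      cor(x[ok], yv[ok])
    } else NA_real_
    tibble::tibble(snp_id = colnames(imp)[j], n_animals = sum(ok), r = r,
                   maf = min(p[j], 1 - p[j]))
  })
  structure(list(
    overall_r = mean(per_animal$r, na.rm = TRUE),
    mean_snp_r = mean(per_snp$r, na.rm = TRUE),
    per_animal = per_animal, per_snp = per_snp,
    n_undefined_animals = sum(is.na(per_animal$r)),
    n_undefined_snps = sum(is.na(per_snp$r)),
    genotype_mode = genotype_mode,
    scenario_label = scenario_label
  ), class = "imputation_accuracy")
}

#' @export
print.imputation_accuracy <- function(x, ...) {
  cat("<imputation_accuracy", if (!is.null(x$scenario_label))
    paste0(" [", x$scenario_label, "]"), "> mean per-animal r = ",
    sprintf("%.4f", x$overall_r), ", mean per-SNP r = ",
    sprintf("%.4f", x$mean_snp_r), " (", x$genotype_mode, ")\n", sep = "")
  invisible(x)
}

#' Imputation accuracy by minor-allele-frequency bin
#'
#' @param report An `imputation_accuracy` object.
#' @param maf_values Optional per-SNP MAF (default: taken from the report).
#' @param bin_width MAF bin width (default 0.05).
#' @return Tibble with `bin_low`, `bin_mid`, `mean_r`, `n_snps`; empty bins
#'   are reported with `NA` mean, not zero.
#' @export
maf_binned_accuracy <- function(report, maf_values = NULL, bin_width = 0.05) {
  df <- report$per_snp
  if (!is.null(maf_values)) df$maf <- maf_values
  edges <- seq(0, 0.5 + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < 0.5) edges <- c(edges, 0.5)
  bin <- cut(df$maf, edges, include.lowest = TRUE, right = FALSE)
  all_bins <- levels(bin)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, r = df$r), bin),
    mean_r = mean(.data$r, na.rm = TRUE), n_snps = sum(!is.na(.data$r)),
    .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(bin = factor(all_bins, all_bins)),
                          agg, by = "bin")
  lows <- edges[-length(edges)]
  tibble::tibble(
    bin_low = lows,
    bin_mid = lows + diff(edges) / 2,
    mean_r = ifelse(is.nan(out$mean_r) | is.na(out$mean_r), NA_real_,
                    out$mean_r),
    n_snps = dplyr::coalesce(out$n_snps, 0L)
  )
}

#' Distribution of per-animal imputation accuracy
#'
#' @param report An `imputation_accuracy` object.
#' @param bin_width Histogram bin width over \[-1, 1\] (default 0.05).
#' @return List with `histogram` (tibble: `bin_low`, `bin_mid`, `count`)
#'   and `skewness` of the per-animal accuracy distribution.
#' @export
per_animal_distribution <- function(report, bin_width = 0.05) {
  r <- report$per_animal$r
  r <- r[!is.na(r)]
  edges <- seq(-1, 1 + 1e-9, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- cut(r, edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  lows <- edges[-length(edges)]
  list(histogram = tibble::tibble(bin_low = lows,
                                  bin_mid = lows + diff(edges) / 2,
                                  count = counts),
       skewness = sample_skewness(r))
}
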