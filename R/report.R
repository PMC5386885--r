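#' Relative improvement of one prediction accuracy over a baseline
#'
#' @param acc_a Accuracy of the method being compared.
#' @param acc_b Baseline accuracy (> 0), e.g. pedigree BLUP.
#' @return List with `percent` (unrounded `100 * (acc_a - acc_b) / acc_b`)
#'   and `percent_rounded` (nearest integer, for reporting).
#' @examples
#' relative_improvement(0.60, 0.48)$percent_rounded  # 25
#' @export
relative_improvement <- function(acc_a, acc_b) {
  assert_that(acc_b > 0, "baseline accuracy `acc_b` must be > 0")
  pct <- 100 * (acc_a - acc_b) / acc_b
  list(percent = pct, percent_rounded = round(pct))
}

#' Genotyping cost of an imputation design
#'
#' Compares the cost of the imputation design (parents and full-density
#' offspring at the full-panel price, low-density offspring at the cheap
#' panel price) against genotyping every sample at the full panel.
#'
#' @param design A `panel_design` (used for the LD offspring count), or
#'   `NULL` if `n_ld_offspring` is given.
#' @param n_parents,n_offspring Sample counts.
#' @param price_full Full-density price per sample (default 40).
#' @param price_ld Low-density price per sample (default 5).
#' @param n_ld_offspring Optional explicit LD offspring count.
#' @return List of class `cost_model`: per-class counts, `total_imputation_design`,
#'   `total_all_full`, `percent_saving`.
#' @export
genotyping_cost <- function(design = NULL, n_parents, n_offspring,
                            price_full = 40, price_ld = 5,
                            n_ld_offspring = NULL) {
  assert_that(price_full > 0 && price_ld > 0, "prices must be > 0")
  n_ld <- n_ld_offspring %||% length(design$offspring_ld_ids)
  assert_that(n_ld <= n_offspring, "more LD offspring than offspring")
  n_full_off <- n_offspring - n_ld
  total_design <- n_parents * price_full + n_full_off * price_full +
    n_ld * price_ld
  total_full <- (n_parents + n_offspring) * price_full
  structure(list(
    n_parents = n_parents, n_full_offspring = n_full_off,
    n_ld_offspring = n_ld, price_full = price_full, price_ld = price_ld,
    total_imputation_design = total_design, total_all_full = total_full,
    percent_saving = 100 * (1 - total_design / total_full)
  ), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> design ", x$total_imputation_design, " vs all-full ",
      x$total_all_full, ": saving ",
      sprintf("%.4f", x$percent_saving), "%\n", sep = "")
  invisible(x)
}

#' Run the full imputation and prediction scenario grid
#'
#' Simulates one population and evaluates (i) the eight imputation cells
#' (two base panels x two mask fractions x two offspring genotyping
#' strategies) and (ii) the prediction comparison on the medium-density
#' base panel: pedigree BLUP, GBLUP on the low-density SNPs only, GBLUP on
#' imputed genotypes, and GBLUP on true genotypes, for both traits.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param md_fraction Fraction of the full map forming the medium-density
#'   base panel (default `25634 / 78362`, the ratio of the arrays the
#'   design emulates).
#' @param mask_fractions Mask levels (default `c(0.90, 0.99)`).
#' @param prop_ld_levels Offspring LD proportions (default `c(1, 0.75)`).
#' @param prediction_cell Which imputation scenario feeds GBLUP_imputed:
#'   list of `base`, `mask_fraction`, `prop_ld` (default MD, 0.99, 0.75).
#' @param h2 Optional fixed heritability for cross-validation (default:
#'   per-fold EM-REML).
#' @param k_folds Cross-validation folds (default 5).
#' @param genotype_mode Scoring mode for imputation accuracy.
#' @param run_prediction Set `FALSE` to run only the imputation grid.
#' @return List of class `scenario_table`: `imputation` (tibble of the
#'   eight cells with mean per-animal accuracy), `prediction` (tibble by
#'   method and trait), `cost` (a `cost_model`), plus the population and
#'   traits used.
#' @export
run_scenarios <- function(config = sim_config(), seed = 1L,
                          md_fraction = 25634 / 78362,
                          mask_fractions = c(0.90, 0.99),
                          prop_ld_levels = c(1, 0.75),
                          prediction_cell = list(base = "MD",
                                                 mask_fraction = 0.99,
                                                 prop_ld = 0.75),
                          h2 = NULL, k_folds = 5L,
                          genotype_mode = "most_likely",
                          run_prediction = TRUE) {
  pop <- simulate_population(config, seed)
  traits <- simulate_traits(pop, seed = seed)
  map <- pop$map
  ped <- pop$pedigree
  off <- pedigree_offspring(ped)
  hd_ids <- map$snp_id
  md_ids <- select_evenly_spaced(map, keep_fraction = md_fraction)
  base_sets <- list(HD = hd_ids, MD = md_ids)

  grid <- tidyr::expand_grid(base = c("HD", "MD"),
                             mask_fraction = mask_fractions,
                             prop_ld = prop_ld_levels)
  imput_rows <- list()
  imputed_for_prediction <- NULL
  for (i in seq_len(nrow(grid))) {
    base <- grid$base[i]; mf <- grid$mask_fraction[i]; pl <- grid$prop_ld[i]
    base_ids <- base_sets[[base]]
    geno <- pop$genotypes[, base_ids, drop = FALSE]
    des <- panel_design(map, ped, base_panel = base, base_snp_ids = base_ids,
                        mask_fraction = mf, prop_ld = pl, seed = seed)
    masked <- apply_mask(geno, des)
    res <- impute_population(masked, ped, map[map$snp_id %in% base_ids, ])
    acc <- imputation_accuracy(pop$genotypes, res,
                               genotype_mode = genotype_mode,
                               scenario_label = des$scenario_label)
    imput_rows[[i]] <- tibble::tibble(
      base_panel = base, mask_fraction = mf, prop_ld = pl,
      n_ld_snps = length(des$ld_snp_ids),
      scenario = des$scenario_label,
      mean_animal_r = acc$overall_r, mean_snp_r = acc$mean_snp_r)
    if (run_prediction && base == prediction_cell$base &&
        isTRUE(all.equal(mf, prediction_cell$mask_fraction)) &&
        isTRUE(all.equal(pl, prediction_cell$prop_ld))) {
      imputed_for_prediction <- list(design = des, masked = masked,
                                     result = res)
    }
  }
  imputation <- dplyr::bind_rows(imput_rows)

  prediction <- NULL
  cost <- NULL
  if (run_prediction) {
    cell <- imputed_for_prediction
    assert_that(!is.null(cell), "prediction_cell not found in the grid")
    md_map <- map[map$snp_id %in% md_ids, ]
    folds <- make_folds(off$id, k = k_folds, seed = seed)
    A <- compute_nrm(ped)
    g_true <- compute_grm(pop$genotypes[, md_ids, drop = FALSE])
    g_imp <- compute_grm(imputed_genotypes(cell$masked, cell$result))
    ld_ids <- cell$design$ld_snp_ids
    g_ld <- compute_grm(pop$genotypes[, ld_ids, drop = FALSE])
    kmats <- list(PBLUP = A, GBLUP_ld_only = g_ld,
                  GBLUP_imputed = g_imp, GBLUP_true = g_true)
    trait_cols <- c(lice = "lice_transformed", weight = "weight")
    prediction <- purrr::map_dfr(names(kmats), function(m) {
      purrr::map_dfr(names(trait_cols), function(tr) {
        cv <- cross_validate(traits, trait_cols[[tr]], kmats[[m]], folds,
                             h2 = h2, method = m)
        tibble::tibble(method = m, trait = tr,
                       accuracy = attr(cv, "mean_accuracy"),
                       mean_r = mean(cv$r, na.rm = TRUE))
      })
    })
    n_par <- sum(ped$generation == "founder")
    cost <- genotyping_cost(cell$design, n_parents = n_par,
                            n_offspring = nrow(off))
  }
  structure(list(imputation = imputation, prediction = prediction,
                 cost = cost, population = pop, traits = traits, seed = seed),
            class = "scenario_table")
}

#' Write a scenario report to disk
#'
#' Emits `imputation_accuracy.csv`, `prediction_accuracy.csv` (when
#' present) and a short markdown summary, with floating-point values
#' printed to 4 decimals.
#'
#' @param scenarios A `scenario_table` from [run_scenarios()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_scenarios <- function(scenarios, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 4)))
  paths <- character(0)
  p1 <- file.path(dir, "imputation_accuracy.csv")
  readr::write_csv(fmt(scenarios$imputation), p1)
  paths <- p1
  if (!is.null(scenarios$prediction)) {
    p2 <- file.path(dir, "prediction_accuracy.csv")
    readr::write_csv(fmt(scenarios$prediction), p2)
    paths <- c(paths, p2)
  }
  md <- c("# Scenario report", "",
          "## Imputation accuracy (mean per-animal r, masked cells)", "",
          knit_simple_table(fmt(scenarios$imputation)))
  if (!is.null(scenarios$prediction)) {
    md <- c(md, "", "## Prediction accuracy (r(y1,y2)/h, fivefold CV)", "",
            knit_simple_table(fmt(scenarios$prediction)),
            "", sprintf("Genotyping cost saving: %.4f%%",
                        scenarios$cost$percent_saving))
  }
  p3 <- file.path(dir, "report.md")
  writeLines(md, p3)
  invisible(c(paths, p3))
}

# Minimal markdown table (avoids a knitr dependency at run time).
knit_simple_table <- function(df) {
  hdr <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  rows <- apply(df, 1L, function(r) paste(r, collapse = " | "))
  c(hdr, sep, rows)
}
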