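# Build a small hand-made imputation_result for metric tests.
toy_result <- function(true, imp, mask = NULL) {
  mask <- mask %||% matrix(TRUE, nrow(true), ncol(true),
                           dimnames = dimnames(true))
  structure(list(dosage = imp, most_likely = round(imp),
                 p0 = NULL, p1 = NULL, p2 = NULL,
                 mask = mask, freq = rep(0.5, ncol(true))),
            class = "imputation_result")
}

test_that("imputation accuracy is the mean per-animal correlation", {
  true <- rbind(A1 = c(0L, 1L, 2L, 1L, 0L), A2 = c(2L, 1L, 0L, 1L, 2L))
  colnames(true) <- paste0("s", 1:5)
  # perfect imputation
  r1 <- imputation_accuracy(true, toy_result(true, true * 1.0))
  expect_equal(r1$overall_r, 1.0)
  # variance-preserving flip: every per-animal r = -1
  r2 <- imputation_accuracy(true, toy_result(true, 2 - true))
  expect_equal(r2$per_animal$r, c(-1, -1))
  expect_equal(r2$overall_r, -1)
  # one-animal worked example against a direct Pearson computation
  imp <- rbind(A1 = c(0, 1, 1, 1, 0), A2 = c(2, 1, 0, 1, 2))
  colnames(imp) <- paste0("s", 1:5)
  r3 <- imputation_accuracy(true, toy_result(true, imp),
                            genotype_mode = "dosage")
  expect_equal(r3$per_animal$r[1], cor(c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0)))
  # zero-variance animals are excluded and counted
  true4 <- rbind(A1 = c(0L, 1L, 2L), A2 = c(1L, 1L, 1L))
  colnames(true4) <- paste0("s", 1:3)
  imp4 <- rbind(A1 = c(0, 1, 2), A2 = c(1, 1, 1))
  colnames(imp4) <- paste0("s", 1:3)
  r4 <- imputation_accuracy(true4, toy_result(true4, imp4))
  expect_equal(r4$n_undefined_animals, 1L)
  expect_equal(r4$overall_r, 1.0)
  expect_error(
    imputation_accuracy(true, toy_result(true, imp,
                                         mask = matrix(FALSE, 2, 5))),
    "masked")
  # relabeling animals and SNPs leaves the summary unchanged
  perm <- c(2, 1)
  r5 <- imputation_accuracy(true[perm, ], toy_result(true[perm, ], imp[perm, ]),
                            genotype_mode = "dosage")
  expect_equal(r5$overall_r, r3$overall_r)
})

test_that("MAF binning and the per-animal histogram summarize correctly", {
  fx <- fix_imputed()
  acc <- imputation_accuracy(fx$pop$genotypes, fx$result)
  curve <- maf_binned_accuracy(acc)
  expect_true(all(curve$n_snps[!is.na(curve$mean_r)] > 0))
  expect_equal(sum(curve$n_snps), sum(!is.na(acc$per_snp$r)))
  # one wide bin swallows everything
  one <- maf_binned_accuracy(acc, bin_width = 0.5)
  expect_equal(sum(!is.na(one$mean_r)), 1L)
  # all SNPs at one MAF occupy a single bin
  rep_one <- acc
  rep_one$per_snp$maf <- 0.27
  c1 <- maf_binned_accuracy(rep_one)
  expect_equal(sum(c1$n_snps > 0), 1L)

  h <- per_animal_distribution(acc)
  expect_equal(sum(h$histogram$count), sum(!is.na(acc$per_animal$r)))
  # degenerate distribution: single occupied bin at r = 1
  perf <- acc
  perf$per_animal$r <- rep(1, nrow(perf$per_animal))
  hp <- per_animal_distribution(perf)
  expect_equal(sum(hp$histogram$count > 0), 1L)
  expect_equal(hp$histogram$bin_low[hp$histogram$count > 0], 0.95)
})

test_that("sparse panels skew the per-animal accuracy distribution left", {
  pop <- fix_pop()
  des <- panel_design(pop$map, pop$pedigree, "MD", mask_fraction = 0.99,
                      prop_ld = 1)
  res <- impute_population(apply_mask(pop$genotypes, des),
                           pop$pedigree, pop$map)
  acc <- imputation_accuracy(pop$genotypes, res)
  expect_lt(per_animal_distribution(acc)$skewness, 0)
  # accuracy rises with MAF under a sparse panel
  curve <- maf_binned_accuracy(acc)
  ok <- !is.na(curve$mean_r)
  expect_gt(cor(curve$bin_mid[ok], curve$mean_r[ok], method = "spearman"), 0)
})

test_that("relative improvement reproduces the printed comparisons", {
  expect_equal(relative_improvement(0.60, 0.48)$percent_rounded, 25)
  expect_equal(relative_improvement(0.58, 0.48)$percent_rounded, 21)
  expect_equal(relative_improvement(0.37, 0.37)$percent, 0)
  expect_error(relative_improvement(0.5, 0), "acc_b")
})

test_that("the cost model matches the arithmetic of the design", {
  cm <- genotyping_cost(n_parents = 89, n_offspring = 624,
                        n_ld_offspring = 468)
  expect_equal(cm$total_all_full, 713 * 40)
  expect_equal(cm$total_imputation_design, 89 * 40 + 156 * 40 + 468 * 5)
  expect_equal(cm$percent_saving,
               100 * (1 - (89 * 40 + 156 * 40 + 468 * 5) / (713 * 40)))
  expect_equal(round(cm$percent_saving, 1), 57.4)
  # equal prices: no saving
  cm0 <- genotyping_cost(n_parents = 10, n_offspring = 100,
                         n_ld_offspring = 50, price_ld = 40)
  expect_equal(cm0$percent_saving, 0)
  # all offspring cheap, no parents: saving is the price ratio
  cm1 <- genotyping_cost(n_parents = 0, n_offspring = 100,
                         n_ld_offspring = 100)
  expect_equal(cm1$percent_saving, 100 * (1 - 5 / 40))
})

test_that("the scenario runner covers the full grid", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 200, n_sires = 6,
                    n_dams = 12, n_families = 12, n_offspring = 96)
  sc <- suppressWarnings(run_scenarios(cfg, seed = 3, md_fraction = 0.4,
                                       run_prediction = FALSE))
  expect_equal(nrow(sc$imputation), 8L)
  expect_equal(nrow(dplyr::distinct(
    sc$imputation[, c("base_panel", "mask_fraction", "prop_ld")])), 8L)
  expect_true(all(is.finite(sc$imputation$mean_animal_r)))
  # report writes csv + markdown
  dir <- withr::local_tempdir()
  paths <- report_scenarios(sc, dir)
  expect_true(all(file.exists(paths)))
  got <- readr::read_csv(file.path(dir, "imputation_accuracy.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(got), 8L)
})
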