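test_that("founders are template mosaics with controlled frequencies", {
  gmap <- build_genome_map(1, 200, 2e7, seed = 3)
  # no switching: every haplotype is an exact template copy
  f0 <- simulate_founders(gmap, n_founders = 30, n_ancestral = 4,
                          mosaic_switch_per_cm = 0, seed = 3)
  pats <- unique(rbind(f0$h1, f0$h2))
  expect_lte(nrow(pats), 4L)
  # degenerate MAF range pins template frequencies at 0.5
  f5 <- simulate_founders(gmap, 20, n_ancestral = 10,
                          maf_range = c(0.5, 0.5), seed = 3)
  expect_true(all(f5$template_freq == 0.5))
})

test_that("founder LD decays with genetic distance", {
  gmap <- build_genome_map(1, 120, 5e7, seed = 4)
  f <- simulate_founders(gmap, n_founders = 500, n_ancestral = 2,
                         mosaic_switch_per_cm = 0.3, seed = 4)
  H <- rbind(f$h1, f$h2)
  set.seed(4)
  pairs <- cbind(sample(120, 400, TRUE), sample(120, 400, TRUE))
  pairs <- pairs[pairs[, 1] < pairs[, 2], ]
  d <- gmap$pos_cm[pairs[, 2]] - gmap$pos_cm[pairs[, 1]]
  r2 <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(cor(H[, pairs[i, 1]], H[, pairs[i, 2]]))^2
  }, numeric(1))
  ok <- !is.na(r2)
  expect_lt(cor(d[ok], r2[ok], method = "spearman"), 0)
})

test_that("realized founder MAF respects the QC floor", {
  gmap <- build_genome_map(2, 400, 5e7, seed = 5)
  f <- simulate_founders(gmap, n_founders = 89, maf_range = c(0.05, 0.5),
                         seed = 5)
  expect_gte(mean(f$realized_maf >= 0.05), 0.99)
})

test_that("pedigree structure matches the nuclear-family design", {
  ped <- make_pedigree(seed = 1)
  off <- ped[ped$generation == "offspring", ]
  expect_equal(nrow(off), 624L)
  expect_equal(length(unique(off$family_id)), 59L)
  # each family is one (sire, dam) pair; each dam used once
  fam <- unique(off[, c("sire", "dam", "family_id")])
  expect_equal(nrow(fam), 59L)
  expect_equal(anyDuplicated(fam$dam), 0L)
  # 30 sires round-robin over 59 families: usage in {1, 2}
  expect_true(all(table(fam$sire) %in% 1:2))
  ped59 <- make_pedigree(n_sires = 59, seed = 1)
  fam59 <- unique(ped59[ped59$generation == "offspring", c("sire", "family_id")])
  expect_true(all(table(fam59$sire) == 1L))
  expect_error(make_pedigree(n_sires = 60), "n_sires")
})

test_that("meiosis follows a Poisson no-interference model", {
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)
  # zero-length chromosome: no crossovers, gamete equals one haplotype
  g <- drop_gamete(h1, h2, rep(0, 50), seed = 1)
  expect_true(all(g$alleles == h1) || all(g$alleles == h2))
  expect_equal(length(unique(g$origin)), 1L)

  # 100 cM chromosome: mean crossover count ~ Poisson(1)
  pos <- seq(0, 100, length.out = 20)
  set.seed(11)
  counts <- replicate(10000,
    drop_gamete(h1[1:20], h2[1:20], pos)$n_crossovers)
  expect_lt(abs(mean(counts) - 1), 3 * sd(counts) / sqrt(10000))
  # chi-square goodness of fit against Poisson(1), alpha = 0.01
  brk <- c(0, 1, 2, 3)
  obs <- c(table(factor(pmin(counts, 3), levels = 0:3)))
  pp <- c(dpois(0:2, 1), 1 - ppois(2, 1))
  pval <- chisq.test(obs, p = pp)$p.value
  expect_gt(pval, 0.01)
})

test_that("gamete alleles always come from the parent", {
  set.seed(2)
  h1 <- rbinom(40, 1, 0.5); h2 <- rbinom(40, 1, 0.5)
  pos <- sort(runif(40, 0, 80))
  for (i in 1:20) {
    g <- drop_gamete(h1, h2, pos)
    expect_true(all(g$alleles == ifelse(g$origin == 1, h1, h2)))
  }
})

test_that("simulated populations are Mendelian-consistent and deterministic", {
  pop <- fix_pop()
  expect_identical(pop$genotypes, pop$h1 + pop$h2)
  ped <- pop$pedigree
  off <- ped[ped$generation == "offspring", ]
  # offspring gametes equal the recorded parental haplotype at every site
  for (i in c(1, 50, 160)) {
    oid <- off$id[i]
    sire_h <- ifelse(pop$origin_pat[oid, ] == 1, pop$h1[off$sire[i], ],
                     pop$h2[off$sire[i], ])
    expect_identical(unname(pop$h1[oid, ]), as.integer(sire_h))
  }
  # no impossible trios anywhere
  G <- pop$genotypes
  for (i in seq_len(nrow(off))) {
    go <- G[off$id[i], ]; gs <- G[off$sire[i], ]; gd <- G[off$dam[i], ]
    smin <- as.integer(gs == 2); smax <- as.integer(gs >= 1)
    dmin <- as.integer(gd == 2); dmax <- as.integer(gd >= 1)
    expect_true(all(go >= smin + dmin & go <= smax + dmax))
  }
  # offspring allele frequencies track parental frequencies
  par_ids <- ped$id[ped$generation == "founder"]
  pf <- colMeans(G[par_ids, ]) / 2
  of <- colMeans(G[off$id, ]) / 2
  expect_lt(max(abs(pf - of)), 4 * sqrt(max(pf * (1 - pf)) / (2 * nrow(off))) + 0.05)
  # bitwise determinism
  pop2 <- simulate_population(pop$config, seed = 42)
  expect_identical(pop$genotypes, pop2$genotypes)
  expect_identical(pop$origin_pat, pop2$origin_pat)
})

test_that("trait simulation hits the configured genetic architecture", {
  cfg <- sim_config(n_chrom = 1, snps_per_chrom = 300, n_sires = 25,
                    n_dams = 100, n_families = 100, n_offspring = 2000)
  pop <- simulate_population(cfg, seed = 6)
  tr <- simulate_traits(pop, h2_weight = 0.5, seed = 6)
  # realized additive variance is calibrated exactly
  expect_equal(var(tr$true_bv_weight), 0.5, tolerance = 1e-10)
  # regression of phenotype on true BV has slope ~ 1
  lat <- (tr$weight - pop$config$weight_mean_g) / pop$config$weight_sd_g
  fit <- lm(lat ~ tr$true_bv_weight + tr$sex)
  slope <- coef(fit)[["tr$true_bv_weight"]]
  se <- summary(fit)$coefficients["tr$true_bv_weight", 2]
  expect_lt(abs(slope - 1), 3 * se)
  # sex effect only shifts males
  expect_gt(mean(lat[tr$sex == "M"]), mean(lat[tr$sex == "F"]))
  # near-zero heritability: breeding values carry almost no variance
  tr0 <- simulate_traits(pop, h2_lice = 1e-6, seed = 6)
  expect_lt(var(tr0$true_bv_lice), 1e-5)
  # lice counts are non-negative and positively skewed on the observed scale
  expect_true(all(tr$lice_count >= 0))
  expect_gt(oracle_skewness(tr$lice_count), 0.5)
})

test_that("transform_counts reduces skewness via the power grid", {
  set.seed(8)
  x <- rexp(5000, 1 / 20)
  out <- transform_counts(x)
  expect_lt(abs(oracle_skewness(out$transformed)), 0.5)
  expect_true(out$lambda >= -2 && out$lambda <= 2)
  # already symmetric input does not get worse
  z <- rnorm(2000, 50, 5)
  outz <- transform_counts(z)
  expect_lte(abs(oracle_skewness(outz$transformed)),
             abs(oracle_skewness(z)) + 1e-8)
  # degenerate input passes through with a warning
  expect_warning(res0 <- transform_counts(rep(0, 10)), "constant")
  expect_identical(res0$transformed, rep(0, 10))
  expect_equal(res0$lambda, 1)
  expect_error(transform_counts(c(-1, 2)), "non-negative")
})
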