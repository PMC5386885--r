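make_trio_ped <- function(n_off = 1) {
  tibble::tibble(
    id = c("S1", "D1", sprintf("O%d", seq_len(n_off))),
    sire = c(NA, NA, rep("S1", n_off)),
    dam = c(NA, NA, rep("D1", n_off)),
    sex = c("M", "F", rep("M", n_off)),
    generation = c("founder", "founder", rep("offspring", n_off)),
    family_id = c(NA, NA, rep("F1", n_off)))
}

test_that("mendelian_fill fills only forced genotypes", {
  ped <- make_trio_ped()
  G <- rbind(S1 = c(0L, 0L, 2L, 1L, 0L),
             D1 = c(0L, 2L, 2L, 0L, 1L),
             O1 = rep(NA_integer_, 5))
  colnames(G) <- paste0("s", 1:5)
  filled <- mendelian_fill(G, ped)
  expect_identical(unname(filled["O1", ]), c(0L, 1L, 2L, NA, NA))
})

test_that("transmissions are recorded only when logically forced", {
  ped <- make_trio_ped()
  G <- rbind(S1 = c(1L, 1L, 1L, 0L, 1L),
             D1 = c(1L, 2L, 1L, 2L, 1L),
             O1 = c(0L, 1L, 2L, 1L, 1L))
  colnames(G) <- paste0("s", 1:5)
  tr <- infer_transmissions(G, ped)
  expect_identical(unname(tr$sire["O1", ]), c(0L, 0L, 1L, 0L, NA))
  expect_identical(unname(tr$dam["O1", ]), c(0L, 1L, 1L, 1L, NA))
  # inconsistent trio site is skipped and counted
  G2 <- G; G2["O1", 4] <- 2L  # sire 0 cannot give allele 1
  tr2 <- infer_transmissions(G2, ped)
  expect_identical(tr2$sire["O1", 4][[1]], NA_integer_)
  expect_gte(tr2$n_inconsistent, 1L)
})

test_that("parent phasing follows majority vote with cis ties", {
  gmap <- tibble::tibble(chrom = "chr1", snp_id = paste0("s", 1:4),
                         pos_bp = c(1e6, 2e6, 3e6, 4e6),
                         pos_cm = c(1, 2, 3, 4))
  ped <- make_trio_ped(8)
  kids <- sprintf("O%d", 1:8)
  # sire het at all 4 SNPs, dam homozygous 0 -> dam transmits 0, offspring
  # genotype equals the sire-transmitted allele
  hapA <- c(0L, 0L, 0L, 0L); hapB <- c(1L, 1L, 1L, 1L)
  trans_hap <- rbind(hapA, hapA, hapA, hapB, hapB, hapA, hapB, hapA)
  G <- rbind(S1 = rep(1L, 4), D1 = rep(0L, 4),
             matrix(trans_hap, 8, 4, dimnames = list(kids, NULL)))
  colnames(G) <- gmap$snp_id
  tr <- infer_transmissions(G, ped)
  ph <- phase_parent("S1", G, tr, ped, gmap)
  expect_true(all(ph$phase_known))
  # all-cis transmissions: one haplotype all 0s, the other all 1s
  expect_true(identical(ph$h1, hapA) || identical(ph$h1, hapB))
  expect_identical(ph$h1 + ph$h2, rep(1L, 4))

  # 6 cis vs 2 trans votes at a site pair -> cis wins
  trans_hap2 <- trans_hap
  trans_hap2[1:2, 2] <- 1L  # two recombinants between s1 and s2
  G2 <- G; G2[kids, ] <- trans_hap2
  ph2 <- phase_parent("S1", G2, infer_transmissions(G2, ped), ped, gmap)
  expect_true(identical(ph2$h1, hapA) || identical(ph2$h1, hapB))

  # homozygous parent: trivially phased everywhere
  phd <- phase_parent("D1", G, tr, ped, gmap)
  expect_true(all(phd$phase_known))
  expect_identical(phd$h1, rep(0L, 4))
  expect_identical(phd$h2, rep(0L, 4))
})

test_that("origin HMM matches exhaustive path enumeration", {
  set.seed(21)
  for (case in 1:12) {
    n <- sample(3:6, 1)
    pos <- sort(runif(n, 0, 60))
    freq <- runif(n, 0.1, 0.9)
    rand_phase <- function() {
      g <- sample(0:2, n, replace = TRUE)
      h1 <- ifelse(g == 2, 1L, ifelse(g == 0, 0L, rbinom(n, 1, 0.5)))
      h2 <- g - h1
      known <- ifelse(g == 1, runif(n) < 0.7, TRUE)
      # occasionally drop the genotype entirely
      drop <- runif(n) < 0.15
      h1[drop] <- NA; h2[drop] <- NA; known[drop] <- FALSE
      list(h1 = as.integer(h1), h2 = as.integer(h2), phase_known = known)
    }
    sp <- rand_phase(); dp <- rand_phase()
    obs <- sample(c(0:2, NA), n, replace = TRUE)
    if (all(is.na(obs))) obs[1] <- 1L
    eps <- sample(c(0.001, 0.01, 0.05), 1)
    got <- origin_hmm(obs, sp, dp, pos, error_rate = eps, freq = freq)
    want <- enum_origin_posterior(obs, sp, dp, pos, eps, freq)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_lt(max(abs(rowSums(got) - 1)), 1e-9)
  }
})

test_that("origin HMM limiting cases behave", {
  # no observed markers: uniform posterior with a warning
  sp <- phase_from_haps(c(0, 1), c(1, 0))
  dp <- phase_from_haps(c(0, 0), c(1, 1))
  expect_warning(
    post <- origin_hmm(c(NA, NA), sp, dp, c(0, 10), freq = c(0.5, 0.5)),
    "no observed")
  expect_true(all(post == 0.25))
  # zero recombination distance with zero error: state carries over exactly
  sp2 <- phase_from_haps(c(0, 0), c(1, 1))
  dp2 <- phase_from_haps(c(0, 0), c(0, 0))
  # obs genotype 2 at site 1 forces sire hap 2 (allele 1), dam either
  post2 <- origin_hmm(c(1L, NA), sp2, dp2, c(5, 5), error_rate = 0,
                      freq = c(0.5, 0.5))
  expect_equal(post2[2, ], post2[1, ], tolerance = 1e-12)
  expect_equal(sum(post2[2, 3:4]), 1, tolerance = 1e-12)
  expect_error(origin_hmm(c(1L, 1L), sp2, dp2, c(0, 1), error_rate = 0.7),
               "error_rate")
})

test_that("dosages combine origins, phases and frequencies correctly", {
  # both parents homozygous 0: dosage 0 regardless of posterior
  sp <- phase_from_haps(c(0, 0), c(0, 0))
  dp <- phase_from_haps(c(0, 0), c(0, 0))
  post <- matrix(runif(8), 2, 4); post <- post / rowSums(post)
  dos <- impute_dosages(post, sp, dp, freq = c(0.3, 0.3))
  expect_equal(dos$dosage, c(0, 0))
  expect_equal(dos$most_likely, c(0L, 0L))
  expect_equal(dos$p0 + dos$p1 + dos$p2, c(1, 1), tolerance = 1e-12)

  # certain state with fully phased parents: integer dosage equal to truth
  sp2 <- phase_from_haps(c(1, 0), c(0, 1))
  dp2 <- phase_from_haps(c(1, 1), c(0, 0))
  post2 <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE)  # (s1,m1)
  dos2 <- impute_dosages(post2, sp2, dp2, freq = c(0.5, 0.5))
  expect_equal(dos2$dosage, c(2, 1))  # s1+m1 alleles: (1+1, 0+1)
  expect_equal(dos2$most_likely, c(2L, 1L))

  # unknown parental genotype marginalizes to the population frequency
  spu <- list(h1 = c(NA_integer_), h2 = c(NA_integer_), phase_known = FALSE)
  dpu <- phase_from_haps(0, 0)
  postu <- matrix(0.25, 1, 4)
  dosu <- impute_dosages(postu, spu, dpu, freq = 0.3)
  expect_equal(dosu$dosage, 0.3)  # paternal gamete Bernoulli(0.3), dam 0
})

test_that("population imputation is accurate, bounded and deterministic", {
  fx <- fix_imputed()
  res <- fx$result
  # posterior sanity on all masked cells
  cells <- res$mask
  expect_true(all(abs((res$p0 + res$p1 + res$p2)[cells] - 1) < 1e-9))
  expect_true(all(res$dosage[cells] >= 0 & res$dosage[cells] <= 2))
  expect_true(all(res$most_likely[cells] %in% 0:2))
  expect_length(res$failures, 0)
  # favourable design: high accuracy
  acc <- imputation_accuracy(fx$pop$genotypes, res, genotype_mode = "dosage")
  expect_gt(acc$overall_r, 0.85)
  # deterministic
  res2 <- impute_population(fx$masked, fx$pop$pedigree, fx$pop$map)
  expect_identical(res$dosage, res2$dosage)
})

test_that("zero-recombination fully informative families impute exactly", {
  # one chromosome of 0 cM: no recombination; sire haplotypes distinct
  n <- 12
  gmap <- tibble::tibble(chrom = "chr1", snp_id = paste0("s", 1:n),
                         pos_bp = seq_len(n), pos_cm = rep(0, n))
  class(gmap) <- c("genome_map", class(gmap))
  ped <- make_trio_ped(6)
  set.seed(31)
  s1 <- rbinom(n, 1, 0.5); s2 <- 1L - s1   # sire fully heterozygous
  d1 <- rbinom(n, 1, 0.5); d2 <- d1        # dam homozygous everywhere
  kids <- sprintf("O%d", 1:6)
  hp <- rbind(s1, s1, s2, s2, s1, s2)
  hm <- rbind(d1, d2, d1, d2, d2, d1)
  G <- rbind(S1 = as.integer(s1 + s2), D1 = as.integer(d1 + d2),
             matrix(as.integer(hp + hm), 6, n, dimnames = list(kids, NULL)))
  colnames(G) <- gmap$snp_id
  truth <- G
  # mask half the sites in O1 and O2
  mask <- matrix(FALSE, 8, n, dimnames = dimnames(G))
  mask[c("O1", "O2"), seq(2, n, by = 2)] <- TRUE
  Gm <- G; Gm[mask] <- NA_integer_
  res <- impute_population(list(genotypes = Gm, mask = mask), ped, gmap,
                           error_rate = 0)
  got <- res$most_likely[c("O1", "O2"), seq(2, n, by = 2)]
  expect_identical(unname(got), unname(truth[c("O1", "O2"), seq(2, n, by = 2)]))
  expect_true(all(abs(res$dosage[res$mask] -
                        truth[c("O1", "O2"), ][res$mask]) < 1e-6))
})

test_that("full-density sibs raise imputation accuracy of LD offspring", {
  # the 75% LD / 25% full scenario must beat 100% LD on matched populations
  wins <- 0L
  for (rep_i in 1:5) {
    cfg <- sim_config(n_chrom = 2, snps_per_chrom = 250, n_sires = 8,
                      n_dams = 16, n_families = 16, n_offspring = 128)
    pop <- simulate_population(cfg, seed = 500 + rep_i)
    acc_for <- function(prop_ld) {
      des <- panel_design(pop$map, pop$pedigree, "HD", mask_fraction = 0.99,
                          prop_ld = prop_ld)
      masked <- apply_mask(pop$genotypes, des)
      res <- impute_population(masked, pop$pedigree, pop$map)
      imputation_accuracy(pop$genotypes, res,
                          genotype_mode = "dosage")$overall_r
    }
    if (acc_for(0.75) > acc_for(1.0)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
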