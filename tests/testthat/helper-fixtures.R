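# Shared simulated fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A mid-sized population reused by panel/imputation/accuracy tests.
fix_pop <- function() {
  fixture("pop", function() {
    cfg <- sim_config(n_chrom = 2, snps_per_chrom = 300, n_sires = 10,
                      n_dams = 20, n_families = 20, n_offspring = 160)
    simulate_population(cfg, seed = 42)
  })
}

# A favourable-design imputation run on fix_pop (HD base, 90% masked,
# 75% offspring at LD).
fix_imputed <- function() {
  fixture("imputed", function() {
    pop <- fix_pop()
    des <- panel_design(pop$map, pop$pedigree, "HD", mask_fraction = 0.90,
                        prop_ld = 0.75)
    masked <- apply_mask(pop$genotypes, des)
    res <- impute_population(masked, pop$pedigree, pop$map)
    list(pop = pop, design = des, masked = masked, result = res)
  })
}

# Simple deterministic parent_phase builders for HMM unit tests.
phase_from_haps <- function(h1, h2, known = NULL) {
  list(h1 = as.integer(h1), h2 = as.integer(h2),
       phase_known = known %||% rep(TRUE, length(h1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
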