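#' Default simulation configuration
#'
#' The default settings emulate the study design this package targets: a
#' two-generation commercial salmon population of 59 nuclear families from
#' 30 sires and 59 dams with ~624 offspring, a multi-chromosome map with
#' intermediate-frequency SNPs (post-QC array-like), LD among founder
#' haplotypes, and two polygenic traits (a positively skewed lice count with
#' h2 = 0.22 and body weight in grams with h2 = 0.50, sex as fixed effect).
#'
#' @param ... Named overrides for any configuration entry.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chrom = 5L, snps_per_chrom = 1000L, chrom_length_bp = 1e8,
    cm_per_mb = 1.0,
    n_ancestral = 10L, mosaic_switch_per_cm = 0.05, maf_range = c(0.05, 0.5),
    n_sires = 30L, n_dams = 59L, n_families = 59L, n_offspring = 624L,
    offspring_per_family = NULL,
    n_qtl = 300L, h2_lice = 0.22, h2_weight = 0.50, sex_effect = 0.2,
    weight_mean_g = 500, weight_sd_g = 100,
    lice_log_mean = log(25), lice_log_sd = 0.6
  )
  over <- list(...)
  assert_that(all(names(over) %in% names(cfg)),
              paste("unknown config entries:",
                    paste(setdiff(names(over), names(cfg)), collapse = ", ")))
  cfg[names(over)] <- over
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a phased two-generation population
#'
#' Composes the map builder, founder simulator, pedigree builder and meiosis
#' model into a full population with simulation truth retained: phased
#' haplotypes for every individual and, for offspring, the parental origin
#' (haplotype 1 or 2) of every transmitted allele.
#'
#' @param config A [sim_config()] list.
#' @param seed Master integer seed; all stages derive sub-streams from it.
#'
#' @return A list of class `phased_pop`: `map` (genome_map), `pedigree`
#'   (salm_pedigree), `h1`/`h2` (individual x SNP 0/1 haplotype matrices;
#'   haplotype 1 is the paternally inherited one for offspring),
#'   `origin_pat`/`origin_mat` (offspring x SNP matrices of 1/2 parental
#'   haplotype origins), and `genotypes` (individual x SNP 0/1/2).
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  map <- build_genome_map(config$n_chrom, config$snps_per_chrom,
                          config$chrom_length_bp, config$cm_per_mb, seed)
  ped <- make_pedigree(config$n_sires, config$n_dams, config$n_families,
                       config$offspring_per_family, config$n_offspring, seed)
  founders <- dplyr::filter(ped, .data$generation == "founder")
  fh <- simulate_founders(map, nrow(founders), config$n_ancestral,
                          config$mosaic_switch_per_cm, config$maf_range, seed)
  n_snp <- nrow(map)
  all_ids <- ped$id
  h1 <- matrix(0L, length(all_ids), n_snp, dimnames = list(all_ids, map$snp_id))
  h2 <- h1
  h1[founders$id, ] <- fh$h1
  h2[founders$id, ] <- fh$h2

  off <- pedigree_offspring(ped)
  origin_pat <- matrix(0L, nrow(off), n_snp, dimnames = list(off$id, map$snp_id))
  origin_mat <- origin_pat
  cidx <- chrom_index(map)

  with_seed(derive_seed(seed, "meiosis"), {
    for (i in seq_len(nrow(off))) {
      sire <- off$sire[i]; dam <- off$dam[i]; oid <- off$id[i]
      for (idx in cidx) {
        g_p <- drop_gamete(h1[sire, idx], h2[sire, idx], map$pos_cm[idx])
        g_m <- drop_gamete(h1[dam, idx], h2[dam, idx], map$pos_cm[idx])
        h1[oid, idx] <- g_p$alleles
        h2[oid, idx] <- g_m$alleles
        origin_pat[oid, idx] <- g_p$origin
        origin_mat[oid, idx] <- g_m$origin
      }
    }
  })
  structure(list(map = map, pedigree = ped, h1 = h1, h2 = h2,
                 origin_pat = origin_pat, origin_mat = origin_mat,
                 genotypes = h1 + h2, config = config, seed = seed),
            class = "phased_pop")
}

#' @export
print.phased_pop <- function(x, ...) {
  off <- sum(x$pedigree$generation == "offspring")
  cat("<phased_pop> ", nrow(x$pedigree) - off, " founders + ", off,
      " offspring in ", length(unique(stats::na.omit(x$pedigree$family_id))),
      " families; ", nrow(x$map), " SNPs on ",
      length(unique(x$map$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}
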