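#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Founder haplotypes are built as mosaics of a small set of ancestral
#' template haplotypes (a Li-Stephens-style copying model). Template allele
#' frequencies are drawn inside `maf_range`, so sites segregate at
#' intermediate frequency as they would after array QC, and the mosaic
#' copying induces LD that decays with genetic distance.
#'
#' @param map A `genome_map`.
#' @param n_founders Number of founder individuals (two haplotypes each).
#' @param n_ancestral Number of ancestral template haplotypes per chromosome
#'   (>= 2; default 10).
#' @param mosaic_switch_per_cm Template switch rate per centimorgan along a
#'   copied haplotype (default 0.05). Zero yields exact template copies.
#' @param maf_range Length-2 numeric, target allele-frequency range for the
#'   templates; must lie within \[0.05, 0.5\].
#' @param seed Integer seed.
#'
#' @return List with `h1` and `h2`: `n_founders x nrow(map)` 0/1 matrices
#'   (rows named F001...), and `template_freq`: per-SNP allele-1 frequency
#'   across templates, plus `realized_maf` across founder haplotypes.
#' @export
simulate_founders <- function(map, n_founders, n_ancestral = 10L,
                              mosaic_switch_per_cm = 0.05,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  assert_that(n_ancestral >= 2, "`n_ancestral` must be >= 2")
  assert_that(length(maf_range) == 2 && maf_range[1] >= 0.05 - 1e-12 &&
                maf_range[2] <= 0.5 + 1e-12 && maf_range[1] <= maf_range[2],
              "`maf_range` must lie within [0.05, 0.5]")
  n_snp <- nrow(map)
  ids <- sprintf("F%03d", seq_len(n_founders))
  h1 <- matrix(0L, n_founders, n_snp, dimnames = list(ids, map$snp_id))
  h2 <- h1
  tmpl_freq <- numeric(n_snp)

  with_seed(derive_seed(seed, "founders"), {
    for (idx in chrom_index(map)) {
      n_c <- length(idx)
      cm <- map$pos_cm[idx]
      # templates: allele-1 carried by round(f * n_ancestral) templates,
      # clamped so every site stays polymorphic among templates
      f <- runif(n_c, maf_range[1], maf_range[2])
      carriers <- pmin(pmax(round(f * n_ancestral), 1L), n_ancestral - 1L)
      templates <- matrix(0L, n_ancestral, n_c)
      for (j in seq_len(n_c)) {
        templates[sample.int(n_ancestral, carriers[j]), j] <- 1L
      }
      tmpl_freq[idx] <- carriers / n_ancestral
      copy_one <- function() {
        src <- mosaic_sources(cm, n_ancestral, mosaic_switch_per_cm)
        templates[cbind(src, seq_len(n_c))]
      }
      for (i in seq_len(n_founders)) {
        h1[i, idx] <- copy_one()
        h2[i, idx] <- copy_one()
      }
    }
  })
  af <- (colSums(h1) + colSums(h2)) / (2 * n_founders)
  list(h1 = h1, h2 = h2, template_freq = tmpl_freq,
       realized_maf = pmin(af, 1 - af))
}

# Template index at each SNP for one mosaic haplotype: switch events are
# Poisson along the cM axis; at each event a template is redrawn uniformly.
mosaic_sources <- function(cm, n_ancestral, rate_per_cm) {
  n <- length(cm)
  cur <- sample.int(n_ancestral, 1L)
  if (rate_per_cm <= 0 || n == 1L) return(rep(cur, n))
  span <- cm[n] - cm[1]
  n_switch <- rpois(1L, rate_per_cm * span)
  if (n_switch == 0L) return(rep(cur, n))
  at <- sort(runif(n_switch, cm[1], cm[n]))
  seg <- findInterval(cm, at)  # 0..n_switch
  states <- c(cur, sample.int(n_ancestral, n_switch, replace = TRUE))
  states[seg + 1L]
}
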