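# Transmitted-allele probability for each parental haplotype at each site:
# the haplotype allele where the phase is resolved, 0.5 for a heterozygous
# site with unresolved phase (alleles known, assignment unknown), and the
# population allele frequency where the parent genotype itself is missing.
transmit_prob <- function(phase, freq) {
  p1 <- as.numeric(phase$h1)
  p2 <- as.numeric(phase$h2)
  unres <- !phase$phase_known & !is.na(p1)
  p1[unres] <- 0.5
  p2[unres] <- 0.5
  miss <- is.na(p1)
  p1[miss] <- freq[miss]
  p2[miss] <- freq[miss]
  cbind(p1, p2, deparse.level = 0)
}

# Haldane recombination fraction between adjacent positions (cM).
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Posterior inheritance origins for one offspring on one chromosome
#'
#' Forward-backward over the 4-state inheritance-origin chain (which of the
#' sire's and dam's haplotypes the offspring's two gametes copy). State
#' switches between adjacent SNPs follow per-gamete Haldane recombination
#' fractions; emissions are the probability of the observed offspring
#' genotype given the transmitted-allele distributions implied by the
#' parental phases, with a per-allele genotyping error `error_rate`.
#' Missing offspring genotypes contribute flat emissions, so posteriors at
#' masked SNPs are interpolated through the chain.
#'
#' @param obs_geno Offspring genotype vector on this chromosome (0/1/2,
#'   `NA` at unobserved/masked SNPs).
#' @param sire_phase,dam_phase `parent_phase` components restricted to this
#'   chromosome (lists with `h1`, `h2`, `phase_known`).
#' @param pos_cm Genetic positions (cM) of the chromosome's SNPs.
#' @param error_rate Per-allele genotyping error in \[0, 0.5) (default
#'   0.001).
#' @param freq Population allele frequencies for the chromosome's SNPs
#'   (used where a parental allele is unknown).
#' @return Matrix `n x 4` of posterior state probabilities, columns
#'   `(s1,m1), (s1,m2), (s2,m1), (s2,m2)`; rows sum to 1.
#' @export
origin_hmm <- function(obs_geno, sire_phase, dam_phase, pos_cm,
                       error_rate = 0.001, freq = NULL) {
  assert_that(error_rate >= 0 && error_rate < 0.5,
              "`error_rate` must be in [0, 0.5)")
  n <- length(obs_geno)
  if (is.null(freq)) freq <- rep(0.5, n)
  if (!any(!is.na(obs_geno))) {
    warning("no observed markers on chromosome: returning uniform posterior")
    return(matrix(0.25, n, 4))
  }
  pp <- transmit_prob(sire_phase, freq)  # n x 2, sire haplotypes
  pm <- transmit_prob(dam_phase, freq)
  eps <- error_rate
  emis <- matrix(1, n, 4)
  obs <- which(!is.na(obs_geno))
  k <- 0L
  for (s in 1:2) for (m in 1:2) {
    k <- k + 1L
    qp <- eps + pp[obs, s] * (1 - 2 * eps)
    qm <- eps + pm[obs, m] * (1 - 2 * eps)
    g <- obs_geno[obs]
    e <- numeric(length(obs))
    e[g == 0] <- ((1 - qp) * (1 - qm))[g == 0]
    e[g == 1] <- (qp * (1 - qm) + (1 - qp) * qm)[g == 1]
    e[g == 2] <- (qp * qm)[g == 2]
    emis[obs, k] <- e
  }
  r <- haldane_r(diff(pos_cm))
  fb_posterior(emis, r, r)
}

#' Genotype posteriors and dosages from origin posteriors
#'
#' Combines the inheritance-origin posterior with the parental phases:
#' the probability each gamete carries allele 1 is the posterior-weighted
#' transmitted-allele probability of the corresponding parental haplotypes
#' (falling back to 0.5 for unresolved heterozygous phases and to the
#' population frequency for missing parental genotypes). The two gametes
#' are combined independently into a genotype posterior.
#'
#' @param posterior `n x 4` origin posterior from [origin_hmm()].
#' @param sire_phase,dam_phase Parental phases for the same SNPs.
#' @param freq Population allele frequencies for the same SNPs.
#' @param sites Optional integer indices to report (default all).
#' @return Tibble with `site`, `p0`, `p1`, `p2` (genotype posterior),
#'   `dosage` (`p1 + 2*p2`), `most_likely`.
#' @export
impute_dosages <- function(posterior, sire_phase, dam_phase, freq,
                           sites = NULL) {
  n <- nrow(posterior)
  if (is.null(sites)) sites <- seq_len(n)
  pp <- transmit_prob(sire_phase, freq)
  pm <- transmit_prob(dam_phase, freq)
  pat1 <- pmin(pmax((posterior[, 1] + posterior[, 2]) * pp[, 1] +
                      (posterior[, 3] + posterior[, 4]) * pp[, 2], 0), 1)
  mat1 <- pmin(pmax((posterior[, 1] + posterior[, 3]) * pm[, 1] +
                      (posterior[, 2] + posterior[, 4]) * pm[, 2], 0), 1)
  p0 <- (1 - pat1) * (1 - mat1)
  p2 <- pat1 * mat1
  p1 <- pat1 * (1 - mat1) + (1 - pat1) * mat1
  gp <- cbind(p0, p1, p2)
  ml <- max.col(gp, ties.method = "first") - 1L
  dosage <- pat1 + mat1  # = p1 + 2 p2, exact and bounded in [0, 2]
  tibble::tibble(site = sites, p0 = p0[sites], p1 = p1[sites],
                 p2 = p2[sites], dosage = dosage[sites],
                 most_likely = ml[sites])
}
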