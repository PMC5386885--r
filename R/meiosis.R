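#' Drop one gamete through meiosis on a single chromosome
#'
#' Crossover counts are Poisson with mean equal to the chromosome's genetic
#' length in Morgans and crossover positions are uniform on the cM scale
#' (no interference, i.e. a Haldane model). The gamete copies the currently
#' active parental haplotype at each SNP; the origin vector records which
#' haplotype (1 or 2) was active.
#'
#' @param parent_h1,parent_h2 0/1 allele vectors for the parent's two
#'   haplotypes on this chromosome (equal length).
#' @param pos_cm SNP genetic positions (cM), non-decreasing.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (the population simulator calls this inside its own stream).
#'
#' @return List with `alleles` (0/1 gamete), `origin` (1/2 per SNP) and
#'   `n_crossovers` (the realized Poisson draw; crossovers falling between
#'   the same pair of adjacent SNPs may be invisible in `origin`).
#' @export
drop_gamete <- function(parent_h1, parent_h2, pos_cm, seed = NULL) {
  run <- function() {
    n <- length(pos_cm)
    span_m <- (pos_cm[n] - pos_cm[1]) / 100  # Morgans
    start <- sample.int(2L, 1L)
    n_xo <- if (span_m > 0) rpois(1L, span_m) else 0L
    if (n_xo == 0L) {
      origin <- rep(start, n)
    } else {
      at <- sort(runif(n_xo, pos_cm[1], pos_cm[n]))
      seg <- findInterval(pos_cm, at)
      # seg = 0 before the first crossover; each crossover flips the haplotype
      origin <- ((start - 1L + seg) %% 2L) + 1L
    }
    alleles <- ifelse(origin == 1L, parent_h1, parent_h2)
    list(alleles = as.integer(alleles), origin = as.integer(origin),
         n_crossovers = n_xo)
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "gamete"), run())
}
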