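#' Phase a parent's haplotypes from offspring transmissions
#'
#' Heuristic long-range phasing for the half-sib design: homozygous sites
#' are trivially phased; heterozygous sites carrying at least one
#' transmission record ("informative" sites) are chained in map order, and
#' for each consecutive informative pair every offspring with records at
#' both sites votes *cis* (same allele transmitted at both, pattern 00/11)
#' or *trans* (01/10). The relative phase follows the majority, with ties
#' broken towards cis (the fewest-recombination explanation). Heterozygous
#' sites with no transmission records at all keep an arbitrary phase with
#' `phase_known = FALSE`. A broken link (no offspring informative at both
#' sites of a consecutive pair) starts a new phase segment: sites inside a
#' linked segment are `phase_known = TRUE` with orientation consistent
#' within the segment, while the orientation *between* segments is
#' arbitrary -- to the downstream inheritance HMM a mis-oriented segment
#' simply looks like a state switch at the boundary.
#'
#' @param parent_id Parent individual id.
#' @param genotypes Individual x SNP matrix (parent genotyped at its full
#'   panel).
#' @param transmissions A `transmissions` object from
#'   [infer_transmissions()].
#' @param pedigree Pedigree tibble (to find the parent's offspring).
#' @param map A `genome_map`.
#' @return List of class `parent_phase` with `h1`, `h2` (0/1 allele vectors
#'   over all SNPs, `NA` where the parent genotype is missing) and
#'   `phase_known` (logical per SNP).
#' @export
phase_parent <- function(parent_id, genotypes, transmissions, pedigree, map) {
  off <- pedigree_offspring(pedigree)
  is_sire <- parent_id %in% off$sire
  tmat <- if (is_sire) transmissions$sire else transmissions$dam
  kids <- off$id[(if (is_sire) off$sire else off$dam) == parent_id]
  tmat <- tmat[kids, , drop = FALSE]
  g <- genotypes[parent_id, ]

  n <- length(g)
  h1 <- rep(NA_integer_, n); h2 <- h1
  known <- rep(FALSE, n)
  hom <- !is.na(g) & g != 1L
  h1[hom] <- h2[hom] <- g[hom] %/% 2L
  known[hom] <- TRUE
  het <- which(!is.na(g) & g == 1L)
  h1[het] <- 0L; h2[het] <- 1L  # default arbitrary orientation

  for (idx in chrom_index(map)) {
    hs <- intersect(idx, het)
    if (length(hs) == 0L) next
    informative <- hs[colSums(!is.na(tmat[, hs, drop = FALSE])) > 0L]
    if (length(informative) == 0L) next
    ori <- 0L
    seg_start <- 1L  # index into `informative` of the current segment head
    seg_known <- logical(length(informative))
    if (length(informative) > 1L) {
      for (k in 2L:length(informative)) {
        i <- informative[k - 1L]; j <- informative[k]
        ti <- tmat[, i]; tj <- tmat[, j]
        both <- !is.na(ti) & !is.na(tj)
        n_votes <- sum(both)
        if (n_votes == 0L) {
          ori <- 0L  # new segment, arbitrary orientation
          seg_start <- k
          next
        }
        cis <- sum(ti[both] == tj[both])
        if (n_votes - cis > cis) ori <- 1L - ori
        seg_known[seg_start:k] <- TRUE  # segment has >= 2 linked sites
        if (ori == 1L) { h1[j] <- 1L; h2[j] <- 0L }
      }
    }
    known[informative] <- seg_known
  }
  structure(list(parent_id = parent_id, h1 = h1, h2 = h2, phase_known = known),
            class = "parent_phase")
}
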