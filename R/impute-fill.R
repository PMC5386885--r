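#' Deterministic Mendelian fill of masked offspring genotypes
#'
#' Pre-pass of the imputation pipeline: a masked offspring genotype is
#' filled only where the parents force it (both parents 0 -> 0, both 2 ->
#' 2, one 0 and one 2 -> 1); everything else stays missing.
#'
#' @param genotypes Individual x SNP 0/1/2 matrix with `NA` for missing.
#' @param pedigree Pedigree tibble.
#' @return The genotype matrix with forced cells filled.
#' @export
mendelian_fill <- function(genotypes, pedigree) {
  off <- pedigree_offspring(pedigree)
  out <- genotypes
  for (i in seq_len(nrow(off))) {
    oid <- off$id[i]
    go <- out[oid, ]
    miss <- is.na(go)
    if (!any(miss)) next
    gs <- genotypes[off$sire[i], ]
    gd <- genotypes[off$dam[i], ]
    forced <- miss & !is.na(gs) & !is.na(gd) &
      ((gs == 0 & gd == 0) | (gs == 2 & gd == 2) |
         (gs + gd == 2 & gs != 1))
    # both 0 -> 0; both 2 -> 2; {0,2} -> 1
    out[oid, forced] <- (gs[forced] + gd[forced]) %/% 2L
  }
  out
}

#' Infer unambiguously transmitted parental alleles from trio genotypes
#'
#' For each offspring and SNP where the trio genotypes logically force the
#' allele a parent transmitted, the transmission is recorded: offspring 0
#' means both parents transmitted 0; offspring 2 means both transmitted 1;
#' a heterozygous offspring with one homozygous parent forces the other
#' parent's transmitted allele. Mendelian-inconsistent sites are skipped
#' and counted.
#'
#' @param genotypes Individual x SNP 0/1/2 matrix (`NA` missing); offspring
#'   rows at their panel density.
#' @param pedigree Pedigree tibble.
#' @return List of class `transmissions`: `sire` and `dam`, offspring x SNP
#'   integer matrices of transmitted alleles (`NA` where ambiguous), and
#'   `n_inconsistent`, the number of skipped trio-site combinations.
#' @export
infer_transmissions <- function(genotypes, pedigree) {
  off <- pedigree_offspring(pedigree)
  n_snp <- ncol(genotypes)
  t_s <- matrix(NA_integer_, nrow(off), n_snp,
                dimnames = list(off$id, colnames(genotypes)))
  t_d <- t_s
  n_bad <- 0L
  for (i in seq_len(nrow(off))) {
    go <- genotypes[off$id[i], ]
    gs <- genotypes[off$sire[i], ]
    gd <- genotypes[off$dam[i], ]
    bad <- trio_impossible(go, gs, gd)
    bad[is.na(bad)] <- FALSE
    n_bad <- n_bad + sum(bad)
    ok <- !is.na(go) & !bad
    ts <- rep(NA_integer_, n_snp); td <- ts
    ts[ok & go == 0] <- 0L; td[ok & go == 0] <- 0L
    ts[ok & go == 2] <- 1L; td[ok & go == 2] <- 1L
    het <- ok & go == 1
    ts[het & !is.na(gd) & gd == 0] <- 1L; td[het & !is.na(gd) & gd == 0] <- 0L
    ts[het & !is.na(gd) & gd == 2] <- 0L; td[het & !is.na(gd) & gd == 2] <- 1L
    ts[het & !is.na(gs) & gs == 0] <- 0L; td[het & !is.na(gs) & gs == 0] <- 1L
    ts[het & !is.na(gs) & gs == 2] <- 1L; td[het & !is.na(gs) & gs == 2] <- 0L
    t_s[i, ] <- ts
    t_d[i, ] <- td
  }
  structure(list(sire = t_s, dam = t_d, n_inconsistent = n_bad),
            class = "transmissions")
}
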