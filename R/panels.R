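#' Quality-control filter for SNP genotypes
#'
#' Applies the standard array-QC rules for pedigreed populations: SNPs are
#' removed when they show any Mendelian error in a parent-offspring trio,
#' minor allele frequency below `maf_min`, or a missing-genotype proportion
#' above `max_missing`.
#'
#' @param genotypes Individual x SNP matrix coded 0/1/2 with `NA` for
#'   missing; rownames are individual ids matching the pedigree.
#' @param pedigree A pedigree tibble (`id`, `sire`, `dam`, ...).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_missing Maximum missing proportion (default 0.03).
#'
#' @return List with `report` (tibble: `snp_id`, `maf`, `missing_rate`,
#'   `mendel_error_count`, `kept`) and `genotypes` (the filtered matrix).
#' @export
qc_filter <- function(genotypes, pedigree, maf_min = 0.05, max_missing = 0.03) {
  assert_that(all(genotypes %in% c(0L, 1L, 2L, NA)),
              "`genotypes` must be coded 0/1/2 with NA for missing")
  off <- pedigree_offspring(pedigree)
  off <- off[off$id %in% rownames(genotypes) &
               off$sire %in% rownames(genotypes) &
               off$dam %in% rownames(genotypes), ]
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  missing_rate <- colMeans(is.na(genotypes))
  mendel <- mendel_error_counts(genotypes, off)
  kept <- maf >= maf_min & missing_rate <= max_missing & mendel == 0L
  kept[is.na(kept)] <- FALSE
  report <- tibble::tibble(
    snp_id = colnames(genotypes), maf = unname(maf),
    missing_rate = unname(missing_rate),
    mendel_error_count = unname(mendel), kept = unname(kept)
  )
  if (!any(kept)) {
    stop(sprintf(
      "all SNPs removed by QC (maf<%g: %d, missing>%g: %d, mendelian: %d)",
      maf_min, sum(maf < maf_min, na.rm = TRUE), max_missing,
      sum(missing_rate > max_missing), sum(mendel > 0)), call. = FALSE)
  }
  list(report = report, genotypes = genotypes[, kept, drop = FALSE])
}

# Per-SNP count of trios whose genotypes are Mendelian-impossible.
mendel_error_counts <- function(genotypes, off) {
  n_snp <- ncol(genotypes)
  counts <- integer(n_snp)
  if (nrow(off) == 0L) return(setNames(counts, colnames(genotypes)))
  for (i in seq_len(nrow(off))) {
    go <- genotypes[off$id[i], ]
    gs <- genotypes[off$sire[i], ]
    gd <- genotypes[off$dam[i], ]
    bad <- trio_impossible(go, gs, gd)
    counts <- counts + as.integer(bad & !is.na(bad))
  }
  setNames(counts, colnames(genotypes))
}

# Vectorized: is (offspring, sire, dam) impossible under Mendelian transmission?
trio_impossible <- function(go, gs, gd) {
  # allele a parent can transmit: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  s_min <- as.integer(gs == 2); s_max <- as.integer(gs >= 1)
  d_min <- as.integer(gd == 2); d_max <- as.integer(gd >= 1)
  bad <- go < (s_min + d_min) | go > (s_max + d_max)
  bad[is.na(go) | is.na(gs) | is.na(gd)] <- NA
  bad
}

#' Select an evenly spaced SNP subset by physical position
#'
#' Realizes a low-density panel: a global target of `round(keep_fraction *
#' N)` SNPs is apportioned across chromosomes proportionally to their SNP
#' counts (largest-remainder), and within each chromosome an equidistant
#' grid of ideal bp positions between the first and last SNP is laid down,
#' each grid point taking the nearest not-yet-used SNP (ties to the lower
#' position).
#'
#' @param map A `genome_map` (or tibble with `chrom`, `snp_id`, `pos_bp`).
#' @param base_snp_ids Optional character vector restricting the base panel
#'   (default: all SNPs in `map`).
#' @param keep_fraction Fraction of the base panel to keep, in (0, 1\].
#'
#' @return Character vector of selected SNP ids, in map order.
#' @examples
#' gmap <- build_genome_map(2, 200, 5e7, seed = 1)
#' length(select_evenly_spaced(gmap, keep_fraction = 0.1))
#' @export
select_evenly_spaced <- function(map, base_snp_ids = NULL, keep_fraction) {
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "`keep_fraction` must be in (0, 1]")
  base <- if (is.null(base_snp_ids)) map else
    map[map$snp_id %in% base_snp_ids, , drop = FALSE]
  n_total <- nrow(base)
  k_global <- round(keep_fraction * n_total)
  if (keep_fraction == 1) return(base$snp_id)
  chroms <- unique(base$chrom)
  n_per <- vapply(chroms, function(cc) sum(base$chrom == cc), integer(1))
  k_per <- largest_remainder(k_global * n_per / n_total, k_global)
  if (any(k_per == 0L)) {
    warning("some chromosomes receive 0 SNPs at this keep_fraction")
  }
  picked <- unlist(purrr::map2(chroms, k_per, function(cc, k_c) {
    if (k_c == 0L) return(character(0))
    sub <- base[base$chrom == cc, ]
    pos <- sub$pos_bp
    ideal <- if (k_c == 1L) (pos[1] + pos[length(pos)]) / 2 else
      seq(pos[1], pos[length(pos)], length.out = k_c)
    used <- logical(length(pos))
    sel <- integer(k_c)
    for (i in seq_len(k_c)) {
      d <- abs(pos - ideal[i])
      d[used] <- Inf
      j <- which.min(d)  # which.min takes the first (lower bp) on ties
      sel[i] <- j
      used[j] <- TRUE
    }
    sub$snp_id[sort(sel)]
  }))
  map$snp_id[map$snp_id %in% picked]
}

# Integer apportionment: floor the quotas, hand out the remainder to the
# largest fractional parts (ties broken by order).
largest_remainder <- function(quota, total, cap = NULL) {
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    take <- ord[seq_len(rem)]
    base[take] <- base[take] + 1
  } else if (rem < 0) {
    ord <- order(quota - base)
    give <- ord[seq_len(-rem)]
    base[give] <- base[give] - 1
  }
  if (!is.null(cap)) {
    over <- which(base > cap)
    for (i in over) {
      excess <- base[i] - cap[i]
      base[i] <- cap[i]
      room <- which(base < cap)
      room <- room[order(cap[room] - base[room], decreasing = TRUE)]
      for (j in room) {
        if (excess == 0) break
        add <- min(excess, cap[j] - base[j])
        base[j] <- base[j] + add
        excess <- excess - add
      }
    }
  }
  as.integer(base)
}

#' Choose which offspring carry the low-density panel
#'
#' Distributes the low-density assignments evenly across nuclear families:
#' every family contributes close to `prop_ld` of its offspring, with
#' largest-remainder adjustment so the global count equals
#' `round(prop_ld * n_offspring)` exactly.
#'
#' @param pedigree A pedigree tibble.
#' @param prop_ld Proportion of offspring assigned to the LD panel, (0, 1].
#' @param seed Optional seed; when given, the offspring chosen within a
#'   family are sampled, otherwise the first by sorted id are taken.
#'
#' @return Character vector of offspring ids assigned to the LD panel.
#' @export
assign_offspring_panels <- function(pedigree, prop_ld, seed = NULL) {
  assert_that(prop_ld > 0 && prop_ld <= 1, "`prop_ld` must be in (0, 1]")
  off <- pedigree_offspring(pedigree)
  fams <- split(off$id, off$family_id)
  sizes <- lengths(fams)
  target <- round(prop_ld * nrow(off))
  k_per <- largest_remainder(prop_ld * sizes, target, cap = sizes)
  pick <- function(ids, k) {
    ids <- sort(ids)
    if (k >= length(ids)) return(ids)
    if (is.null(seed)) head(ids, k) else sample(ids, k)
  }
  if (!is.null(seed)) {
    return(with_seed(derive_seed(seed, "panel_assign"),
                     unname(unlist(purrr::map2(fams, k_per, pick)))))
  }
  unname(unlist(purrr::map2(fams, k_per, pick)))
}

#' Construct a panel design (a Table-1-style masking scenario)
#'
#' @param map A `genome_map`.
#' @param pedigree A pedigree tibble.
#' @param base_panel Label for the base panel ("HD" or "MD").
#' @param base_snp_ids SNP ids making up the base panel (default all).
#' @param mask_fraction Fraction of base-panel genotypes masked in LD
#'   offspring (e.g. 0.90 or 0.99).
#' @param prop_ld Proportion of offspring genotyped at low density.
#' @param seed Optional seed for offspring selection.
#' @return A list of class `panel_design` with `ld_snp_ids` (the retained
#'   evenly spaced SNPs), `offspring_ld_ids`, `base_snp_ids`,
#'   `mask_fraction` and `scenario_label`.
#' @export
panel_design <- function(map, pedigree, base_panel = "HD",
                         base_snp_ids = NULL, mask_fraction = 0.99,
                         prop_ld = 0.75, seed = NULL) {
  assert_that(mask_fraction > 0 && mask_fraction < 1,
              "`mask_fraction` must be in (0, 1)")
  base_snp_ids <- base_snp_ids %||% map$snp_id
  ld <- select_evenly_spaced(map, base_snp_ids, 1 - mask_fraction)
  off_ld <- assign_offspring_panels(pedigree, prop_ld, seed)
  structure(list(
    base_panel = base_panel, base_snp_ids = base_snp_ids,
    mask_fraction = mask_fraction, prop_ld = prop_ld,
    ld_snp_ids = ld, offspring_ld_ids = off_ld,
    scenario_label = sprintf("%s/%d%%masked/%d%%LD", base_panel,
                             round(100 * mask_fraction), round(100 * prop_ld))
  ), class = "panel_design")
}

#' Mask genotypes according to a panel design
#'
#' For each offspring on the low-density panel, genotypes at base-panel SNPs
#' outside the LD subset are set to missing. Parents and offspring keeping
#' the full base panel are untouched.
#'
#' @param genotypes Individual x SNP 0/1/2 matrix (full base panel).
#' @param design A `panel_design`.
#' @return List of class `masked_genotypes` with `genotypes` (masked matrix)
#'   and `mask` (logical matrix, `TRUE` where a cell was masked).
#' @export
apply_mask <- function(genotypes, design) {
  assert_that(all(design$offspring_ld_ids %in% rownames(genotypes)),
              "design offspring ids must be rows of `genotypes`")
  mask <- matrix(FALSE, nrow(genotypes), ncol(genotypes),
                 dimnames = dimnames(genotypes))
  masked_snps <- setdiff(intersect(design$base_snp_ids, colnames(genotypes)),
                         design$ld_snp_ids)
  mask[design$offspring_ld_ids, masked_snps] <- TRUE
  out <- genotypes
  out[mask] <- NA_integer_
  structure(list(genotypes = out, mask = mask), class = "masked_genotypes")
}

#' Restore masked genotypes from the source matrix
#'
#' @param masked A `masked_genotypes` object.
#' @param source The original unmasked matrix.
#' @return The un-masked genotype matrix.
#' @export
unmask <- function(masked, source) {
  out <- masked$genotypes
  out[masked$mask] <- source[masked$mask]
  out
}
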