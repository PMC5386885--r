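# Restrict a parent_phase to a set of SNP indices.
slice_phase <- function(phase, idx) {
  list(h1 = phase$h1[idx], h2 = phase$h2[idx],
       phase_known = phase$phase_known[idx])
}

#' Impute masked offspring genotypes for a whole population
#'
#' The two-generation imputation pipeline: deterministic Mendelian fill,
#' transmission inference from trio genotypes, majority-vote phasing of
#' each parent from its offspring's transmitted alleles, and a per-offspring
#' inheritance-origin HMM whose posteriors are combined with the parental
#' phases into genotype posteriors at masked SNPs. A second iteration
#' (default) uses confident origin posteriors to resolve transmissions that
#' were ambiguous from genotypes alone (both parents heterozygous) and
#' re-phases the parents before the final imputation, which is why
#' including a proportion of fully genotyped offspring strengthens the
#' phasing and lifts accuracy for their low-density sibs.
#'
#' @param masked A `masked_genotypes` object from [apply_mask()] (parents at
#'   their full base panel, offspring at low or full density).
#' @param pedigree Pedigree tibble.
#' @param map A `genome_map` covering the matrix columns.
#' @param error_rate Per-allele genotyping error for the HMM emissions
#'   (default 0.001).
#' @param iterations Phase/impute iterations (default 2).
#' @param freq Optional population allele frequencies (default: computed
#'   from all non-missing calls in the masked matrix).
#' @param origin_confidence Posterior margin required before an origin is
#'   used to resolve an ambiguous transmission in re-phasing (default 0.95).
#'
#' @return A list of class `imputation_result` with offspring x SNP
#'   matrices `dosage`, `p0`, `p1`, `p2`, `most_likely` (rows are the
#'   offspring that had masked cells; entries are `NA` outside masked
#'   cells), the corresponding `mask`, `freq`, and `failures` (named list
#'   of per-offspring errors, normally empty).
#' @export
impute_population <- function(masked, pedigree, map, error_rate = 0.001,
                              iterations = 2L, freq = NULL,
                              origin_confidence = 0.95) {
  G <- masked$genotypes
  mask <- masked$mask
  filled <- mendelian_fill(G, pedigree)
  if (is.null(freq)) freq <- unname(colMeans(filled, na.rm = TRUE) / 2)
  freq[is.na(freq)] <- 0.5
  off <- pedigree_offspring(pedigree)
  parents <- unique(c(off$sire, off$dam))
  cidx <- chrom_index(map)
  trans <- infer_transmissions(filled, pedigree)
  target <- off$id[rowSums(mask[off$id, , drop = FALSE]) > 0L]

  phases <- NULL
  rephase <- function() {
    setNames(lapply(parents, phase_parent, genotypes = filled,
                    transmissions = trans, pedigree = pedigree, map = map),
             parents)
  }

  posterior_for <- function(oid, idx) {
    i <- match(oid, off$id)
    origin_hmm(filled[oid, idx],
               slice_phase(phases[[off$sire[i]]], idx),
               slice_phase(phases[[off$dam[i]]], idx),
               map$pos_cm[idx], error_rate, freq[idx])
  }

  if (iterations > 1L) {
    for (iter in seq_len(iterations - 1L)) {
      phases <- rephase()
      # resolve transmissions left ambiguous by genotypes alone
      for (i in seq_len(nrow(off))) {
        oid <- off$id[i]
        sp <- phases[[off$sire[i]]]
        dp <- phases[[off$dam[i]]]
        for (idx in cidx) {
          g <- filled[oid, idx]
          amb <- which(!is.na(g) & is.na(trans$sire[i, idx]))
          if (length(amb) == 0L) next
          post <- suppressWarnings(posterior_for(oid, idx))
          pat1 <- post[, 1] + post[, 2]
          mat1 <- post[, 1] + post[, 3]
          dm_known <- dp$phase_known[idx] & !is.na(dp$h1[idx])
          sr_known <- sp$phase_known[idx] & !is.na(sp$h1[idx])
          for (j in amb) {
            site <- idx[j]
            if (dm_known[j] && (mat1[j] > origin_confidence ||
                                mat1[j] < 1 - origin_confidence)) {
              m_allele <- if (mat1[j] > 0.5) dp$h1[site] else dp$h2[site]
              t_cand <- g[j] - m_allele
              if (t_cand %in% c(0L, 1L)) {
                trans$sire[i, site] <- t_cand
                trans$dam[i, site] <- m_allele
                next
              }
            }
            if (sr_known[j] && (pat1[j] > origin_confidence ||
                                pat1[j] < 1 - origin_confidence)) {
              p_allele <- if (pat1[j] > 0.5) sp$h1[site] else sp$h2[site]
              t_cand <- g[j] - p_allele
              if (t_cand %in% c(0L, 1L)) {
                trans$dam[i, site] <- t_cand
                trans$sire[i, site] <- p_allele
              }
            }
          }
        }
      }
    }
  }
  phases <- rephase()

  n_snp <- ncol(G)
  dim_names <- list(target, colnames(G))
  dosage <- matrix(NA_real_, length(target), n_snp, dimnames = dim_names)
  p0 <- dosage; p1 <- dosage; p2 <- dosage
  most_likely <- matrix(NA_integer_, length(target), n_snp,
                        dimnames = dim_names)
  failures <- list()
  for (oid in target) {
    res <- tryCatch({
      for (idx in cidx) {
        msk <- which(mask[oid, idx])
        if (length(msk) == 0L) next
        post <- suppressWarnings(posterior_for(oid, idx))
        i <- match(oid, off$id)
        dos <- impute_dosages(post, slice_phase(phases[[off$sire[i]]], idx),
                              slice_phase(phases[[off$dam[i]]], idx),
                              freq[idx], sites = msk)
        cols <- idx[msk]
        dosage[oid, cols] <- dos$dosage
        p0[oid, cols] <- dos$p0
        p1[oid, cols] <- dos$p1
        p2[oid, cols] <- dos$p2
        most_likely[oid, cols] <- dos$most_likely
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[[oid]] <- res
  }
  if (length(failures) > 0L) {
    warning("imputation failed for ", length(failures), " offspring")
  }
  structure(list(dosage = dosage, p0 = p0, p1 = p1, p2 = p2,
                 most_likely = most_likely,
                 mask = mask[target, , drop = FALSE],
                 freq = freq, phases = phases, failures = failures),
            class = "imputation_result")
}

#' Fill masked cells of a genotype matrix with imputed values
#'
#' @param masked A `masked_genotypes` object.
#' @param result The matching `imputation_result`.
#' @param mode `"dosage"` (default, variance-preserving expected allele
#'   counts) or `"most_likely"` (hard genotype calls).
#' @return A complete numeric genotype matrix.
#' @export
imputed_genotypes <- function(masked, result, mode = c("dosage", "most_likely")) {
  mode <- match.arg(mode)
  out <- masked$genotypes * 1.0
  src <- if (mode == "dosage") result$dosage else result$most_likely
  for (oid in rownames(src)) {
    cells <- result$mask[oid, ]
    out[oid, cells] <- src[oid, cells]
  }
  # any cells still missing (e.g. failed families) fall back to 2 * freq
  still <- is.na(out)
  if (any(still)) out[still] <- (2 * result$freq)[col(out)[still]]
  out
}
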