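#' Build a two-generation nuclear-family pedigree
#'
#' Mirrors a sib-testing breeding design: each dam founds exactly one nuclear
#' family and sires are reused round-robin across families, so sire usage
#' counts differ by at most one (e.g. 30 sires over 59 families gives 29
#' sires with two families and one with one).
#'
#' @param n_sires Number of sires (<= `n_families`). Default 30.
#' @param n_dams,n_families Number of dams / families; each dam is used once,
#'   so these must be equal. Default 59.
#' @param offspring_per_family Either a single total handled elsewhere or an
#'   integer vector of family sizes (length `n_families`). Default draws a
#'   multinomial split of `n_offspring` across families.
#' @param n_offspring Total offspring when `offspring_per_family` is NULL.
#'   Default 624.
#' @param seed Integer seed (family-size draw and sex assignment).
#'
#' @return A tibble of class `salm_pedigree` with columns `id`, `sire`,
#'   `dam`, `sex` ("M"/"F"), `generation` ("founder"/"offspring"),
#'   `family_id`. Founders have `NA` parents.
#' @export
make_pedigree <- function(n_sires = 30L, n_dams = 59L, n_families = 59L,
                          offspring_per_family = NULL, n_offspring = 624L,
                          seed = 1L) {
  assert_that(n_families == n_dams, "each dam founds one family: `n_families` must equal `n_dams`")
  assert_that(n_sires <= n_families, "`n_sires` must be <= `n_families`")
  sire_ids <- sprintf("S%03d", seq_len(n_sires))
  dam_ids <- sprintf("D%03d", seq_len(n_dams))
  fam_ids <- sprintf("FAM%02d", seq_len(n_families))
  fam_sire <- sire_ids[((seq_len(n_families) - 1L) %% n_sires) + 1L]

  with_seed(derive_seed(seed, "pedigree"), {
    if (is.null(offspring_per_family)) {
      offspring_per_family <- as.integer(
        stats::rmultinom(1L, n_offspring, rep(1 / n_families, n_families))
      )
    }
    assert_that(length(offspring_per_family) == n_families,
                "`offspring_per_family` must have one entry per family")
    n_off <- sum(offspring_per_family)
    founders <- tibble::tibble(
      id = c(sire_ids, dam_ids),
      sire = NA_character_, dam = NA_character_,
      sex = c(rep("M", n_sires), rep("F", n_dams)),
      generation = "founder",
      family_id = NA_character_
    )
    offspring <- tibble::tibble(
      id = sprintf("O%04d", seq_len(n_off)),
      sire = rep(fam_sire, offspring_per_family),
      dam = rep(dam_ids, offspring_per_family),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = "offspring",
      family_id = rep(fam_ids, offspring_per_family)
    )
    out <- dplyr::bind_rows(founders, offspring)
    class(out) <- c("salm_pedigree", class(out))
    out
  })
}

pedigree_offspring <- function(pedigree) {
  dplyr::filter(pedigree, .data$generation == "offspring")
}
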