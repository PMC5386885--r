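#' Simulate polygenic traits on a phased population
#'
#' Two traits are generated for the offspring generation on a standardized
#' latent scale: breeding values are sums of Normal QTL effects at SNPs
#' sampled from the map, rescaled so the realized additive variance equals
#' the target heritability, with independent Normal residuals of variance
#' `1 - h2` and a fixed sex effect. Lice counts are observed through an
#' exponential link of the latent value (inducing the positive skew typical
#' of parasite counts); body weight is reported in grams as a linear
#' rescaling of its latent value.
#'
#' @param pop A `phased_pop`.
#' @param n_qtl Number of QTL (1..number of SNPs). Default from the
#'   population's config.
#' @param h2_lice,h2_weight Narrow-sense heritabilities in (0,1); defaults
#'   0.22 and 0.50.
#' @param sex_effect Additive fixed effect (latent SD units) added to males.
#' @param seed Integer seed.
#'
#' @return A tibble of class `trait_table`: `id`, `sex`, `lice_count`
#'   (observed scale, >= 0), `lice_transformed` (skew-minimizing power
#'   transform of `lice_count`, see [transform_counts()]), `weight` (grams),
#'   `true_bv_lice`, `true_bv_weight` (latent scale), plus `h2_lice`,
#'   `h2_weight` attributes and the chosen transform exponent
#'   (`attr(, "lice_lambda")`).
#' @export
simulate_traits <- function(pop, n_qtl = NULL, h2_lice = 0.22,
                            h2_weight = 0.50, sex_effect = 0.2, seed = 1L) {
  cfg <- pop$config %||% sim_config()
  n_qtl <- n_qtl %||% cfg$n_qtl
  n_snp <- nrow(pop$map)
  assert_that(n_qtl >= 1 && n_qtl <= n_snp,
              "`n_qtl` must be between 1 and the number of mapped SNPs")
  assert_that(h2_lice > 0 && h2_lice < 1 && h2_weight > 0 && h2_weight < 1,
              "heritabilities must lie in (0,1)")
  off <- pedigree_offspring(pop$pedigree)
  G <- pop$genotypes[off$id, , drop = FALSE]

  with_seed(derive_seed(seed, "traits"), {
    latent_for <- function(h2) {
      qtl <- sample.int(n_snp, n_qtl)
      eff <- rnorm(n_qtl)
      bv <- as.numeric(scale(G[, qtl, drop = FALSE] %*% eff, scale = FALSE))
      v <- var(bv)
      bv <- if (v > 0) bv * sqrt(h2 / v) else bv  # realized var(BV) = h2
      e <- rnorm(nrow(off), 0, sqrt(1 - h2))
      list(bv = bv, y = sex_effect * (off$sex == "M") + bv + e)
    }
    lat_lice <- latent_for(h2_lice)
    lat_wt <- latent_for(h2_weight)
    counts <- pmax(exp(cfg$lice_log_mean + cfg$lice_log_sd * lat_lice$y) - 1, 0)
    tr <- transform_counts(counts)
    out <- tibble::tibble(
      id = off$id, sex = off$sex,
      lice_count = counts,
      lice_transformed = tr$transformed,
      weight = cfg$weight_mean_g + cfg$weight_sd_g * lat_wt$y,
      true_bv_lice = lat_lice$bv,
      true_bv_weight = lat_wt$bv
    )
    attr(out, "h2_lice") <- h2_lice
    attr(out, "h2_weight") <- h2_weight
    attr(out, "lice_lambda") <- tr$lambda
    class(out) <- c("trait_table", class(out))
    out
  })
}

#' Skew-minimizing power transform for count data
#'
#' Applies a Box-Cox-family transform to `values + 1`, choosing the exponent
#' lambda on the grid \[-2, 2\] (step 0.05) that minimizes the absolute
#' sample skewness of the transformed values. Used to normalize positively
#' skewed parasite counts before mixed-model analysis.
#'
#' @param values Non-negative numeric vector.
#' @return List with `transformed` (numeric vector) and `lambda` (chosen
#'   exponent; `lambda = 0` denotes the log transform). Constant input is
#'   returned unchanged with `lambda = 1` and a warning.
#' @examples
#' transform_counts(rexp(200, 1 / 20))$lambda
#' @export
transform_counts <- function(values) {
  assert_that(all(values >= 0), "`values` must be non-negative")
  if (length(unique(values)) <= 1L) {
    warning("constant input: returning values unchanged with lambda = 1")
    return(list(transformed = values, lambda = 1))
  }
  x1 <- values + 1
  grid <- seq(-2, 2, by = 0.05)
  bc <- function(lambda) {
    if (abs(lambda) < 1e-12) log(x1) else (x1^lambda - 1) / lambda
  }
  skews <- vapply(grid, function(l) abs(sample_skewness(bc(l))), numeric(1))
  lambda <- grid[which.min(skews)]
  list(transformed = bc(lambda), lambda = lambda)
}
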