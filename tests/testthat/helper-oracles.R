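# Independent oracles used to validate the package's core computations.
# These deliberately re-derive everything from first principles (loops,
# enumeration, Monte Carlo) and share no code with the implementation.

# Exhaustive-path posterior for the 4-state inheritance HMM. States are
# (sire hap, dam hap) in the order (1,1),(1,2),(2,1),(2,2). Emissions are
# recomputed here from the genotype-observation model: each transmitted
# allele is Bernoulli(prob implied by the parental phase), observed alleles
# flip independently with probability eps.
enum_origin_posterior <- function(obs_geno, sire_phase, dam_phase, pos_cm,
                                  eps, freq) {
  n <- length(obs_geno)
  hap_prob <- function(phase, hap, j) {
    h <- if (hap == 1) phase$h1[j] else phase$h2[j]
    if (is.na(h)) return(freq[j])
    if (!phase$phase_known[j] && phase$h1[j] != phase$h2[j]) return(0.5)
    as.numeric(h)
  }
  emit <- function(j, s, m) {
    if (is.na(obs_geno[j])) return(1)
    qp <- eps + hap_prob(sire_phase, s, j) * (1 - 2 * eps)
    qm <- eps + hap_prob(dam_phase, m, j) * (1 - 2 * eps)
    switch(obs_geno[j] + 1L,
           (1 - qp) * (1 - qm),
           qp * (1 - qm) + (1 - qp) * qm,
           qp * qm)
  }
  r_s <- 0.5 * (1 - exp(-2 * diff(pos_cm) / 100))
  r_m <- r_s
  states <- cbind(s = c(1L, 1L, 2L, 2L), m = c(1L, 2L, 1L, 2L))
  post <- matrix(0, n, 4)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  for (pi in seq_len(nrow(paths))) {
    path <- paths[pi, ]
    pr <- 0.25 * emit(1L, states[path[1], "s"], states[path[1], "m"])
    if (n > 1) {
      for (t in 2:n) {
        same_s <- states[path[t], "s"] == states[path[t - 1], "s"]
        same_m <- states[path[t], "m"] == states[path[t - 1], "m"]
        pr <- pr * (if (same_s) 1 - r_s[t - 1] else r_s[t - 1]) *
          (if (same_m) 1 - r_m[t - 1] else r_m[t - 1]) *
          emit(t, states[path[t], "s"], states[path[t], "m"])
      }
    }
    for (t in seq_len(n)) post[t, path[t]] <- post[t, path[t]] + pr
  }
  sweep(post, 1L, rowSums(post), "/")
}

# Element-by-element VanRaden method-1 GRM.
loop_grm <- function(geno, p = NULL) {
  if (is.null(p)) p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(geno)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_along(p)) {
        acc <- acc + (geno[i, k] - 2 * p[k]) * (geno[j, k] - 2 * p[k])
      }
      G[i, j] <- acc / denom
    }
  }
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

# Monte-Carlo identity-by-descent relationships by gene dropping.
# Founders get unique allele labels; every offspring draws one of each
# parent's two alleles per replicate. a_ij = 2 * P(random allele of i is
# IBD to random allele of j), estimated as the mean over the four
# allele-slot combinations.
gene_drop_relationship <- function(pedigree, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  ids <- pedigree$id
  n <- length(ids)
  sire <- match(pedigree$sire, ids)
  dam <- match(pedigree$dam, ids)
  a1 <- matrix(0L, n, n_drops)
  a2 <- a1
  next_allele <- 0L
  # pedigree rows must be parents-before-offspring for this simple pass
  for (i in seq_len(n)) {
    if (is.na(sire[i]) && is.na(dam[i])) {
      a1[i, ] <- next_allele + 1L
      a2[i, ] <- next_allele + 2L
      next_allele <- next_allele + 2L
    } else {
      pick_s <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick_s, a1[sire[i], ], a2[sire[i], ])
      pick_d <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick_d, a1[dam[i], ], a2[dam[i], ])
    }
  }
  # a_ij = 2 * f_ij; on the diagonal the self-comparisons contribute the
  # base 1 and the cross-slot comparisons the inbreeding F, giving 1 + F.
  pair_rel <- function(i, j) {
    2 * mean(c(a1[i, ] == a1[j, ], a1[i, ] == a2[j, ],
               a2[i, ] == a1[j, ], a2[i, ] == a2[j, ]))
  }
  list(pair = pair_rel, ids = ids)
}

# Dense generalized-least-squares solution of the animal model:
# b = (X' V^-1 X)^-1 X' V^-1 y,  a = sigma_a2 K Z' V^-1 (y - X b).
gls_solution <- function(y, X, Z, K, sigma_a2, sigma_e2) {
  V <- Z %*% K %*% t(Z) * sigma_a2 + diag(sigma_e2, length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sigma_a2 * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}

# Sample skewness, re-derived for test use.
oracle_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
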