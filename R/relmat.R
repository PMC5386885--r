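new_relmat <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind), class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat("<relmat:", x$kind, "> ", length(x$ids), " x ", length(x$ids),
      ", mean diagonal ", round(mean(diag(x$values)), 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.relmat <- function(x, ...) x$values

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_j * (1 - p_j)))` with `Z` the genotype matrix
#' centered by twice the allele frequency. Accepts real-valued dosages in
#' \[0, 2\], so imputed expected allele counts can be used directly.
#'
#' @param genotypes Individual x SNP matrix of genotypes or dosages in
#'   \[0, 2\], no missing values.
#' @param allele_freqs Optional per-SNP allele frequencies; default computed
#'   from the supplied individuals. Monomorphic SNPs (p of 0 or 1) are
#'   excluded with a warning.
#' @return A `relmat` of kind `"grm"`.
#' @examples
#' G <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
#' compute_grm(G)
#' @export
compute_grm <- function(genotypes, allele_freqs = NULL) {
  assert_that(!anyNA(genotypes), "`genotypes` must have no missing values")
  p <- allele_freqs %||% unname(colMeans(genotypes) / 2)
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNPs excluded from the GRM")
    genotypes <- genotypes[, poly, drop = FALSE]
    p <- p[poly]
  }
  assert_that(ncol(genotypes) >= 1, "no polymorphic SNPs left for the GRM")
  Z <- sweep(genotypes, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  new_relmat(tcrossprod(Z) / denom, rownames(genotypes), "grm")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A recursively in parents-before-offspring order:
#' `A[i,i] = 1 + F_i` with inbreeding `F_i = A[sire, dam] / 2`, and
#' `A[i,j] = (A[j, sire(i)] + A[j, dam(i)]) / 2`.
#'
#' @param pedigree Tibble with `id`, `sire`, `dam` (`NA` for unknown
#'   parents). Any order; sorted internally, cycles rejected.
#' @return A `relmat` of kind `"nrm"`.
#' @export
compute_nrm <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  sire <- match(pedigree$sire, ids)
  dam <- match(pedigree$dam, ids)
  # topological order: repeatedly admit individuals whose parents are placed
  placed <- is.na(sire) & is.na(dam)
  ord <- which(placed)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (is.na(sire) | placed[ifelse(is.na(sire), 1L, sire)]) &
                     (is.na(dam) | placed[ifelse(is.na(dam), 1L, dam)]))
    if (length(ready) == 0L) stop("cyclic pedigree", call. = FALSE)
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  A <- matrix(0, n, n)
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    rel_s <- if (is.na(s)) 0 else A[s, ]
    rel_d <- if (is.na(d)) 0 else A[d, ]
    row <- (rel_s + rel_d) / 2
    A[i, ] <- row
    A[, i] <- row
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  new_relmat(A, ids, "nrm")
}

#' Invert a relationship matrix with ridge regularization
#'
#' Adds `ridge * I` (escalating tenfold when needed, up to `max_ridge`)
#' whenever the smallest eigenvalue falls below the ridge, then inverts via
#' a Cholesky factorization.
#'
#' @param x A `relmat` or square symmetric matrix.
#' @param ridge Starting ridge (default 1e-6).
#' @param max_ridge Largest ridge tried before giving up (default 1e-2).
#' @return The inverse matrix, with attribute `"ridge"` recording the value
#'   applied (0 when none was needed).
#' @export
regularized_inverse <- function(x, ridge = 1e-6, max_ridge = 1e-2) {
  M <- if (inherits(x, "relmat")) x$values else x
  assert_that(nrow(M) == ncol(M) && max(abs(M - t(M))) < 1e-8,
              "`x` must be square symmetric")
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  r <- ridge
  repeat {
    applied <- if (ev_min >= r) 0 else r
    Mr <- if (applied > 0) M + diag(applied, nrow(M)) else M
    ch <- tryCatch(chol(Mr), error = function(e) NULL)
    if (!is.null(ch)) {
      inv <- chol2inv(ch)
      dimnames(inv) <- dimnames(M)
      attr(inv, "ridge") <- applied
      if (applied > 0) {
        message("ridge of ", applied, " applied before inversion")
      }
      return(inv)
    }
    if (r >= max_ridge) stop("matrix singular even after ridge escalation",
                             call. = FALSE)
    r <- r * 10
  }
}
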