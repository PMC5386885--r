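#' Solve the single-trait animal-model mixed-model equations
#'
#' For `y = X b + Z a + e` with `var(a) = K * sigma_a2` and
#' `var(e) = I * sigma_e2`, solves
#' `[[X'X, X'Z], [Z'X, Z'Z + K^-1 * lambda]] [b; a] = [X'y; Z'y]` with
#' `lambda = sigma_e2 / sigma_a2`. Animals present in `K` but without
#' records (e.g. a validation set) receive predictions through the
#' relationship structure.
#'
#' @param y Phenotype vector (one record per phenotyped animal).
#' @param X Fixed-effect incidence matrix (`length(y)` rows).
#' @param animal_ids Animal id for each record (must appear in `K`).
#' @param K A `relmat` (or matrix with dimnames) covering all animals.
#' @param sigma_a2,sigma_e2 Variance components (> 0).
#' @param K_inverse Optional pre-computed inverse of `K` (from
#'   [regularized_inverse()]).
#' @return List with `b` (fixed-effect solutions) and `a` (named breeding
#'   values for every animal in `K`).
#' @export
solve_mme <- function(y, X, animal_ids, K, sigma_a2, sigma_e2,
                      K_inverse = NULL) {
  Km <- if (inherits(K, "relmat")) K$values else K
  ids <- rownames(Km)
  assert_that(all(animal_ids %in% ids), "all `animal_ids` must appear in `K`")
  assert_that(sigma_a2 > 0 && sigma_e2 > 0, "variance components must be > 0")
  X <- as.matrix(X)
  n <- length(y); q <- length(ids); p <- ncol(X)
  Z <- matrix(0, n, q, dimnames = list(NULL, ids))
  Z[cbind(seq_len(n), match(animal_ids, ids))] <- 1
  Kinv <- K_inverse %||% regularized_inverse(Km)
  lambda <- sigma_e2 / sigma_a2
  M <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Kinv * lambda))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e),
         call. = FALSE)
  })
  list(b = sol[seq_len(p)], a = setNames(sol[p + seq_len(q)], ids))
}

#' EM-REML variance components for the animal model
#'
#' Estimates `sigma_a2` and `sigma_e2` for `y = X b + a + e`,
#' `var(a) = K sigma_a2`, by expectation-maximization REML. Internally the
#' iteration works in the eigenbasis of `K` (one decomposition up front),
#' which makes each EM step linear in `n`; the updates are the classical
#' ones, `sigma_a2 <- (a' K^-1 a + sigma_e2 * tr(K^-1 C_aa)) / q` and
#' `sigma_e2 <- y' e_hat / (n - p)`.
#'
#' @param y Phenotype vector for the phenotyped animals.
#' @param X Fixed-effect incidence matrix.
#' @param K Relationship matrix (a `relmat` or matrix) for exactly the
#'   phenotyped animals, in `y` order.
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 5000); non-convergence
#'   returns the last iterate with `converged = FALSE` and a warning.
#' @param init Optional starting heritability (default 0.3).
#' @return Object of class `animal_model`: list with `sigma_a2`,
#'   `sigma_e2`, `h2`, `b`, `converged`, `iterations`.
#' @export
em_reml <- function(y, X, K, tol = 1e-6, max_iter = 5000L, init = 0.3) {
  Km <- if (inherits(K, "relmat")) K$values else K
  n <- length(y)
  assert_that(n >= 10, "need at least 10 records")
  assert_that(nrow(Km) == n, "`K` must match the phenotyped animals")
  X <- as.matrix(X)
  p <- qr(X)$rank
  ee <- eigen(Km, symmetric = TRUE)
  d <- pmax(ee$values, 1e-8)
  U <- ee$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vy <- var(y)
  sa <- init * vy; se <- (1 - init) * vy
  converged <- FALSE
  XtX <- crossprod(Xt)  # = X'X
  iter <- 0L
  b <- NULL
  for (iter in seq_len(max_iter)) {
    lambda <- se / sa
    w <- lambda / (d + lambda)          # rotated (I - W) diagonal
    WX <- Xt * w
    bmat <- tryCatch(solve(crossprod(Xt, WX), crossprod(WX, yt)),
                     error = function(e) stop("singular GLS system", call. = FALSE))
    b <- drop(bmat)
    r <- yt - drop(Xt %*% b)
    at <- (d / (d + lambda)) * r        # rotated BLUP a-hat
    aKa <- sum(at^2 / d)
    # tr(K^-1 C_aa) via Woodbury on the rotated coefficient matrix
    m <- 1 + lambda / d
    Ainv <- 1 / m
    AB <- Xt * Ainv
    Gmat <- solve(XtX - crossprod(Xt, AB))
    BG <- AB %*% Gmat
    corr <- rowSums(BG * AB)
    trKC <- sum(Ainv / d) + sum(corr / d)
    ehat <- r - at                       # rotated residual y - Xb - a
    se_new <- (sum(yt * ehat) ) / (n - p)
    se_new <- max(se_new, 1e-10)
    sa_new <- max((aKa + se * trKC) / n, 1e-10)
    if (abs(sa_new - sa) < tol * max(sa, 1e-12) &&
        abs(se_new - se) < tol * max(se, 1e-12)) {
      sa <- sa_new; se <- se_new
      converged <- TRUE
      break
    }
    sa <- sa_new; se <- se_new
  }
  if (!converged) warning("EM-REML did not converge in ", max_iter,
                          " iterations")
  structure(list(sigma_a2 = sa, sigma_e2 = se, h2 = sa / (sa + se),
                 b = b, converged = converged, iterations = iter),
            class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat("<animal_model> sigma_a2 = ", signif(x$sigma_a2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", h2 = ", round(x$h2, 3),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Nonoverlapping cross-validation folds
#'
#' @param ids Character vector of offspring ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the permutation.
#' @return Tibble of class `fold_plan` with columns `id` and `fold`; fold
#'   sizes differ by at most one.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  assert_that(k >= 2, "`k` must be >= 2")
  assert_that(length(ids) >= k, "need at least `k` ids")
  with_seed(derive_seed(seed, "folds"), {
    perm <- sample(ids)
    sizes <- diff(floor(seq(0, length(ids), length.out = k + 1)))
    fold <- rep(seq_len(k), times = sizes)
    out <- tibble::tibble(id = perm, fold = fold)
    out <- out[order(match(out$id, ids)), ]
    class(out) <- c("fold_plan", class(out))
    out
  })
}

#' Cross-validated genomic (or pedigree) prediction accuracy
#'
#' For each fold, variance components are estimated on the training records
#' (or a supplied heritability is used), the mixed-model equations are
#' solved with validation phenotypes withheld, and the fold's accuracy is
#' the correlation between predicted breeding values and validation
#' phenotypes pre-adjusted for the training-estimated fixed effects,
#' divided by `h` (the square root of the training heritability).
#'
#' @param phenotypes Tibble with columns `id`, the phenotype named by
#'   `trait`, and the fixed-effect columns referenced by `fixed`.
#' @param trait Name of the phenotype column.
#' @param K A `relmat` covering all offspring (and optionally parents).
#' @param folds A `fold_plan` from [make_folds()].
#' @param fixed Character vector of fixed-effect column names (default
#'   `"sex"`); an intercept is always included.
#' @param h2 Optional fixed heritability; when `NULL` (default) EM-REML is
#'   run per fold on the training records.
#' @param method Label stored with the result (e.g. "GBLUP_true").
#' @return Tibble of class `cv_accuracy` with one row per fold: `fold`,
#'   `n_valid`, `h2_train`, `r`, `accuracy`; mean accuracy in
#'   `attr(, "mean_accuracy")`.
#' @export
cross_validate <- function(phenotypes, trait, K, folds, fixed = "sex",
                           h2 = NULL, method = "GBLUP") {
  Km <- if (inherits(K, "relmat")) K$values else K
  ids <- rownames(Km)
  assert_that(all(phenotypes$id %in% ids),
              "all phenotyped animals must appear in `K`")
  y_all <- phenotypes[[trait]]
  X_all <- stats::model.matrix(
    stats::reformulate(c("1", fixed)), data = phenotypes)
  Kinv <- regularized_inverse(Km)
  rows <- purrr::map(sort(unique(folds$fold)), function(f) {
    valid_ids <- folds$id[folds$fold == f]
    if (length(valid_ids) < 5L) stop("fold ", f, " has fewer than 5 records")
    tr_rows <- which(!phenotypes$id %in% valid_ids)
    va_rows <- which(phenotypes$id %in% valid_ids)
    y_tr <- y_all[tr_rows]
    X_tr <- X_all[tr_rows, , drop = FALSE]
    train_ids <- phenotypes$id[tr_rows]
    if (is.null(h2)) {
      fit <- suppressWarnings(
        em_reml(y_tr, X_tr, Km[train_ids, train_ids]))
      h2_f <- fit$h2
      sa <- fit$sigma_a2; se <- fit$sigma_e2
    } else {
      h2_f <- h2
      vy <- var(y_tr)
      sa <- h2 * vy; se <- (1 - h2) * vy
    }
    sol <- solve_mme(y_tr, X_tr, train_ids, Km, sa, se, K_inverse = Kinv)
    y_adj <- y_all[va_rows] - drop(X_all[va_rows, , drop = FALSE] %*% sol$b)
    r <- suppressWarnings(cor(sol$a[phenotypes$id[va_rows]], y_adj))
    tibble::tibble(fold = f, n_valid = length(va_rows), h2_train = h2_f,
                   r = r, accuracy = if (h2_f > 0) r / sqrt(h2_f) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "method") <- method
  attr(out, "trait") <- trait
  attr(out, "mean_accuracy") <- mean(out$accuracy, na.rm = TRUE)
  class(out) <- c("cv_accuracy", class(out))
  out
}
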