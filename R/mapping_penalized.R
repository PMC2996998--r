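# Lasso / elastic-net locus scoring.  The L1 path is computed by glmnet
# (coordinate descent); the naive elastic net with a fixed ridge penalty
# lambda2 is obtained by the augmented-data construction
# (X* = rbind(X, sqrt(lambda2) I), y* = c(y, 0)), and the path is indexed by
# the L1-norm fraction s = ||beta||_1 / max ||beta||_1, selected on a fixed
# grid by seeded k-fold cross-validation with an imposed minimum of 0.5.

# coefficients along the L1 path at a target norm fraction s, by linear
# interpolation between path knots (the lasso path is piecewise linear)
.path_beta_at_s <- function(betas, l1, s) {
  l1max <- l1[length(l1)]
  if (l1max == 0) return(betas[, 1] * 0)
  target <- s * l1max
  if (target >= l1[length(l1)]) return(betas[, ncol(betas)])
  j <- findInterval(target, l1)           # l1 is non-decreasing
  if (j == 0L) return(betas[, 1] * (target / max(l1[1], .Machine$double.eps)))
  lo <- l1[j]; hi <- l1[j + 1]
  w <- if (hi > lo) (target - lo) / (hi - lo) else 0
  betas[, j] * (1 - w) + betas[, j + 1] * w
}

# full L1 path on standardized data; returns list(betas = p x k matrix with
# l1 norms non-decreasing left to right, l1 = norms).  When the (augmented)
# design has full column rank the path is anchored at the exact least-squares
# solution (lambda1 = 0), so s = 1 recovers OLS/ridge exactly.
.penalized_path <- function(Xs, yc, lambda2) {
  p <- ncol(Xs)
  if (lambda2 > 0) {
    Xa <- rbind(Xs, diag(sqrt(lambda2), p))
    ya <- c(yc, rep(0, p))
  } else {
    Xa <- Xs; ya <- yc
  }
  fit <- glmnet::glmnet(Xa, ya, alpha = 1, standardize = FALSE,
                        intercept = FALSE, nlambda = 200,
                        lambda.min.ratio = 1e-4)
  betas <- as.matrix(fit$beta)
  full_rank <- nrow(Xa) >= p && qr(Xa)$rank == p
  if (full_rank) {
    bols <- qr.coef(qr(Xa), ya)
    betas <- cbind(betas, bols)
  }
  l1 <- colSums(abs(betas))
  ord <- order(l1)
  list(betas = betas[, ord, drop = FALSE], l1 = l1[ord])
}

#' Penalized-regression locus scores (lasso / elastic net)
#'
#' Solves the naive elastic-net problem
#' `min ||y - X b||^2 + lambda2 ||b||^2 + lambda1 ||b||_1` along an L1 path
#' and scores each marker with `|b|` at the L1-norm fraction
#' `s = ||b||_1 / max ||b||_1` chosen from the grid `{0.5, 0.55, ..., 1}` by
#' k-fold cross-validated mean squared error. `lambda2 = 0` gives the lasso,
#' `lambda2 = 1` the elastic net used throughout the benchmarks. Predictors
#' are standardized internally and coefficients are reported on the
#' standardized scale.
#'
#' @param trait Numeric trait vector.
#' @param genotypes A [genotype_matrix()].
#' @param lambda2 Ridge penalty (0 = lasso, 1 = elastic net).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param s_min Lower bound of the s grid (default 0.5).
#' @param seed Integer seed for the fold assignment.
#' @param trait_id Trait identifier recorded in the profile.
#' @return A [score_profile()] with method `"LASSO"` or `"ENET"`; the
#'   selected `s` is recorded in `meta$s`.
#' @export
map_penalized <- function(trait, genotypes, lambda2 = 0, cv_folds = 10,
                          s_min = 0.5, seed = 1, trait_id = "trait") {
  X <- genotypes$values
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(trait) == n, n >= cv_folds, lambda2 >= 0)
  method <- if (lambda2 == 0) "LASSO" else "ENET"
  if (stats::var(trait) == 0) {
    warning("zero-variance trait: all-zero coefficient profile")
    return(score_profile(trait_id, method, numeric(p), genotypes$markers))
  }
  s_grid <- seq(s_min, 1, by = 0.05)

  standardize <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[sdv == 0] <- 1                  # constant markers keep coefficient 0
    list(X = sweep(sweep(M, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
  }

  # seeded round-robin fold assignment after a shuffle
  set.seed(seed)
  fold <- rep_len(seq_len(cv_folds), n)[order(sample.int(n))]

  cv_mse <- matrix(NA_real_, cv_folds, length(s_grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    st <- standardize(X[tr, , drop = FALSE])
    ytr <- trait[tr] - mean(trait[tr])
    path <- .penalized_path(st$X, ytr, lambda2)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, st$mu), 2, st$sd, "/")
    yte <- trait[!tr] - mean(trait[tr])
    for (j in seq_along(s_grid)) {
      b <- .path_beta_at_s(path$betas, path$l1, s_grid[j])
      cv_mse[f, j] <- mean((yte - Xte %*% b)^2)
    }
  }
  s_sel <- s_grid[which.min(colMeans(cv_mse))]

  st <- standardize(X)
  path <- .penalized_path(st$X, trait - mean(trait), lambda2)
  b <- .path_beta_at_s(path$betas, path$l1, s_sel)
  score_profile(trait_id, method, abs(b), genotypes$markers,
                meta = list(s = s_sel, lambda2 = lambda2, seed = seed))
}
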