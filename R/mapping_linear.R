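# Single-marker regression (Haley-Knott at marker locations) and a
# simplified marker-based composite interval mapping with forward-selected
# cofactors.

# residual sum of squares of y regressed on columns of X plus an intercept
.rss <- function(y, X = NULL) {
  if (is.null(X) || ncol(X) == 0L) return(sum((y - mean(y))^2))
  fit <- stats::lm.fit(cbind(1, X), y)
  sum(fit$residuals^2)
}

LOD_RSS_FLOOR <- 1e-10   # RSS1 floored at this fraction of RSS0; caps LOD at (n/2)*10

#' Haley-Knott regression LOD profile
#'
#' For each marker, fits the single-marker linear model
#' `y = mu + beta x_m` and scores it with
#' `LOD_m = (n/2) log10(RSS0 / RSS1)`, where `RSS0` is the intercept-only
#' residual sum of squares. With genotypes observed at the markers
#' themselves, Haley-Knott regression reduces to exactly this marker
#' regression. `RSS1` is floored at `1e-10 * RSS0` so perfect fits give a
#' finite LOD of `(n/2) * 10`.
#'
#' @param trait Numeric trait vector, one value per strain.
#' @param genotypes A [genotype_matrix()].
#' @param trait_id Trait identifier recorded in the profile.
#' @return A [score_profile()] with method `"HK"`.
#' @export
map_hk <- function(trait, genotypes, trait_id = "trait") {
  X <- genotypes$values
  n <- nrow(X)
  stopifnot(length(trait) == n, n >= 3)
  yc <- trait - mean(trait)
  rss0 <- sum(yc^2)
  if (rss0 == 0) {
    warning("zero-variance trait: all-zero LOD profile")
    return(score_profile(trait_id, "HK", numeric(ncol(X)), genotypes$markers))
  }
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  rss1 <- rss0 - ifelse(sxx > 0, sxy^2 / sxx, 0)
  rss1 <- pmax(rss1, LOD_RSS_FLOOR * rss0)
  lod <- (n / 2) * log10(rss0 / rss1)
  score_profile(trait_id, "HK", pmax(lod, 0), genotypes$markers,
                meta = list(rss_floor = LOD_RSS_FLOOR))
}

# greedy forward selection of cofactor markers by largest RSS reduction;
# collinear candidates give no reduction and are never picked — if nothing
# useful remains we stop early with a warning
.forward_cofactors <- function(y, X, n_cofactors) {
  chosen <- integer(0)
  rss_cur <- .rss(y)
  for (step in seq_len(n_cofactors)) {
    cand <- setdiff(seq_len(ncol(X)), chosen)
    red <- vapply(cand, function(j)
      rss_cur - .rss(y, X[, c(chosen, j), drop = FALSE]), numeric(1))
    best <- which.max(red)
    if (red[best] <= 1e-12 * rss_cur) {
      warning("cofactor selection stopped early: remaining markers collinear ",
              "or uninformative")
      break
    }
    chosen <- c(chosen, cand[best])
    rss_cur <- rss_cur - red[best]
  }
  chosen
}

#' Composite interval mapping LOD profile (marker-based)
#'
#' A simplified composite interval mapping: background cofactor markers are
#' chosen once per trait by greedy forward selection, and each marker is then
#' tested with the cofactors as covariates, excluding any cofactor within
#' `window_bp` of the tested marker on the same chromosome (and the tested
#' marker itself). `LOD_m = (n/2) log10(RSS_reduced / RSS_full)` compares the
#' models with and without the tested marker. With `n_cofactors = 0` this is
#' identical to [map_hk()].
#'
#' @param trait Numeric trait vector.
#' @param genotypes A [genotype_matrix()].
#' @param n_cofactors Number of background markers (default 3).
#' @param window_bp Exclusion window around the tested marker (default 10 Mb).
#' @param trait_id Trait identifier recorded in the profile.
#' @return A [score_profile()] with method `"CIM"`.
#' @export
map_cim <- function(trait, genotypes, n_cofactors = 3, window_bp = 1e7,
                    trait_id = "trait") {
  X <- genotypes$values
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(trait) == n, n >= 3, n_cofactors < n - 2)
  mm <- genotypes$markers
  if (sum((trait - mean(trait))^2) == 0) {
    warning("zero-variance trait: all-zero LOD profile")
    return(score_profile(trait_id, "CIM", numeric(p), mm))
  }
  if (n_cofactors == 0L) {
    prof <- map_hk(trait, genotypes, trait_id)
    return(score_profile(trait_id, "CIM", prof$scores, mm, meta = prof$meta))
  }
  cof <- .forward_cofactors(trait, X, n_cofactors)
  lod <- numeric(p)
  for (m in seq_len(p)) {
    near <- mm$chromosome[cof] == mm$chromosome[m] &
      abs(mm$position_bp[cof] - mm$position_bp[m]) <= window_bp
    keep <- cof[!near & cof != m]
    rss_red <- .rss(trait, X[, keep, drop = FALSE])
    rss_full <- .rss(trait, X[, c(m, keep), drop = FALSE])
    rss_full <- max(rss_full, LOD_RSS_FLOOR * rss_red)
    lod[m] <- max((n / 2) * log10(rss_red / rss_full), 0)
  }
  score_profile(trait_id, "CIM", lod, mm,
                meta = list(cofactors = paste(mm$marker_id[cof], collapse = ","),
                            window_bp = window_bp))
}
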