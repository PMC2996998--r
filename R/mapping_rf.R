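# Random Forest eQTL mapping: forests of regression trees on marker
# genotypes, three importance measures (permutation importance RFPI, RSS
# importance RFRSS, selection frequency RFSF), and the null-forest bias
# estimation that turns the raw selection frequency into the bias-corrected
# RFSF score.  Forests are grown by the randomForest package; the bias
# model and correction are implemented here.

#' Random Forest configuration
#'
#' @param n_trees Number of trees (default 5000).
#' @param mtry Markers tried per split; default `floor(p/3)` resolved at fit
#'   time when `NULL`.
#' @param nodesize A node is split only while its sample count exceeds
#'   `nodesize` (default 5); setting `nodesize = n` stops growth after the
#'   root split.
#' @param seed Integer seed making the fit deterministic.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 5000, mtry = NULL, nodesize = 5, seed = 1) {
  stopifnot(n_trees >= 1, nodesize >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "rf_config")
}

.resolve_mtry <- function(config, p) {
  m <- config$mtry %||% max(1L, floor(p / 3))
  if (m < 1 || m > p) stop_fatal("mtry must be in [1, p]")
  as.integer(m)
}

#' Fit a regression forest on marker genotypes
#'
#' Grows `n_trees` regression trees on bootstrap samples of the strains; at
#' each node a random `mtry`-subset of markers is scanned for the best
#' variance-reducing binary split. Deterministic given `config$seed`.
#'
#' @param trait Numeric trait vector.
#' @param genotypes A [genotype_matrix()].
#' @param config An [rf_config()].
#' @return A `fitted_forest` wrapping the underlying forest, the
#'   configuration, and the marker map.
#' @export
fit_rf <- function(trait, genotypes, config = rf_config()) {
  X <- genotypes$values
  stopifnot(length(trait) == nrow(X), nrow(X) >= 2)
  mtry <- .resolve_mtry(config, ncol(X))
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = X, y = trait, ntree = config$n_trees, mtry = mtry,
    nodesize = config$nodesize, importance = TRUE,
    keep.forest = TRUE, keep.inbag = TRUE)
  structure(list(rf = rf, config = config, mtry = mtry,
                 markers = genotypes$markers),
            class = "fitted_forest")
}

#' @export
print.fitted_forest <- function(x, ...) {
  cat(sprintf("fitted_forest: %d trees, mtry %d, nodesize %d, %d markers\n",
              x$config$n_trees, x$mtry, x$config$nodesize, nrow(x$markers)))
  invisible(x)
}

#' Number of internal (split) nodes in a fitted forest
#' @param forest A [fit_rf()] result.
#' @return Integer count over all trees.
#' @export
n_internal_nodes <- function(forest) {
  sum(forest$rf$forest$nodestatus == -3)
}

#' Per-tree node counts of a fitted forest
#' @param forest A [fit_rf()] result.
#' @return Integer vector (length `n_trees`) of total nodes per tree; stump
#'   forests have 3 nodes per tree (root plus two leaves).
#' @export
tree_sizes <- function(forest) forest$rf$forest$ndbigtree

#' Extract the three Random Forest importance measures
#'
#' * `RFPI`: unscaled permutation importance — the mean over trees of the
#'   increase in out-of-bag MSE when the marker's out-of-bag values are
#'   permuted (one permutation per tree and marker, seeded by the fit seed);
#'   trees that never split on the marker contribute 0.
#' * `RFRSS`: total RSS decrease over all splits on the marker, divided by
#'   the number of trees.
#' * `RFSF_raw`: number of internal-node splits using the marker across the
#'   forest, divided by the number of trees.
#'
#' @param forest A [fit_rf()] result.
#' @return List with numeric vectors `rfpi`, `rfrss`, `rfsf_raw` aligned to
#'   the marker map.
#' @export
rf_importances <- function(forest) {
  rf <- forest$rf
  nt <- forest$config$n_trees
  rfpi <- as.numeric(randomForest::importance(rf, type = 1, scale = FALSE))
  rfrss <- as.numeric(randomForest::importance(rf, type = 2)) / nt
  rfsf <- as.numeric(randomForest::varUsed(rf, count = TRUE)) / nt
  list(rfpi = rfpi, rfrss = rfrss, rfsf_raw = rfsf)
}

#' Estimate the null-model selection-frequency bias
#'
#' Under the null hypothesis of no trait-genotype association, selection
#' frequency is biased: markers with low correlation to other markers are
#' over-selected and markers in linkage disequilibrium under-selected. The
#' bias is estimated by fitting many small forests (default 500 forests of
#' 10 trees, i.e. 5000 trees in total, matching the size of a study forest)
#' with the study genotypes as predictors and an independent standard
#' Gaussian trait per forest, pooling the per-marker selection frequencies,
#' and recording each marker's deviation from the mean as its correction.
#'
#' @param genotypes The same [genotype_matrix()] used for the real traits.
#' @param n_forests Number of null forests (default 500).
#' @param trees_per_forest Trees per null forest (default 10).
#' @param config [rf_config()] whose `mtry`/`nodesize` the null forests
#'   reuse.
#' @param seed Integer seed.
#' @return A `null_selection_model` with `null_freq`, `mean_null`,
#'   `correction` (zero-mean) and `provenance`.
#' @export
estimate_sf_bias <- function(genotypes, n_forests = 500, trees_per_forest = 10,
                             config = rf_config(), seed = 1) {
  X <- genotypes$values
  n <- nrow(X); p <- ncol(X)
  total_trees <- n_forests * trees_per_forest
  if (total_trees < 100)
    warning("fewer than 100 null trees: correction will be unstable")
  mtry <- .resolve_mtry(config, p)
  counts <- numeric(p)
  for (f in seq_len(n_forests)) {
    set.seed(derive_seed(seed, "null_forest", f))
    y <- stats::rnorm(n)
    rf <- randomForest::randomForest(
      x = X, y = y, ntree = trees_per_forest, mtry = mtry,
      nodesize = config$nodesize, importance = FALSE, keep.forest = TRUE)
    counts <- counts + randomForest::varUsed(rf, count = TRUE)
  }
  null_freq <- counts / total_trees
  structure(list(null_freq = null_freq, mean_null = mean(null_freq),
                 correction = null_freq - mean(null_freq),
                 markers = genotypes$markers,
                 provenance = list(n_forests = n_forests,
                                   trees_per_forest = trees_per_forest,
                                   mtry = mtry, nodesize = config$nodesize,
                                   seed = seed)),
            class = "null_selection_model")
}

#' @export
print.null_selection_model <- function(x, ...) {
  cat(sprintf(paste0("null_selection_model: %d markers, %d x %d null trees, ",
                     "mean null frequency %.4f\n"),
              length(x$null_freq), x$provenance$n_forests,
              x$provenance$trees_per_forest, x$mean_null))
  invisible(x)
}

#' Bias-corrected selection frequency (RFSF)
#'
#' Subtracts the per-marker correction (deviation of the null selection
#' frequency from its mean) from the observed raw selection frequencies.
#' Corrected scores may be negative.
#'
#' @param rfsf_raw Raw selection frequencies from [rf_importances()].
#' @param null_model An [estimate_sf_bias()] result on the same marker map.
#' @param markers The [marker_map()] the scores align to.
#' @param trait_id Trait identifier.
#' @return A [score_profile()] with method `"RFSF"`.
#' @export
rfsf_corrected <- function(rfsf_raw, null_model, markers,
                           trait_id = "trait") {
  if (length(rfsf_raw) != length(null_model$correction))
    stop_fatal("selection frequency and correction vectors differ in length")
  score_profile(trait_id, "RFSF", rfsf_raw - null_model$correction, markers,
                meta = list(mean_null = null_model$mean_null))
}

#' Map one trait with Random Forests
#'
#' Convenience wrapper: fits the forest and returns all three importance
#' profiles. The RFSF profile is bias-corrected with `null_model` (fitted on
#' the same genotypes); without one only the raw selection frequency is
#' returned, labelled RFSF with `meta$corrected = FALSE`.
#'
#' @param trait Numeric trait vector.
#' @param genotypes A [genotype_matrix()].
#' @param config An [rf_config()].
#' @param null_model Optional [estimate_sf_bias()] result.
#' @param trait_id Trait identifier.
#' @return Named list of [score_profile()]s: `RFPI`, `RFRSS`, `RFSF`.
#' @export
map_rf <- function(trait, genotypes, config = rf_config(), null_model = NULL,
                   trait_id = "trait") {
  forest <- fit_rf(trait, genotypes, config)
  imp <- rf_importances(forest)
  mm <- genotypes$markers
  rfsf <- if (is.null(null_model)) {
    score_profile(trait_id, "RFSF", imp$rfsf_raw, mm,
                  meta = list(corrected = FALSE))
  } else {
    rfsf_corrected(imp$rfsf_raw, null_model, mm, trait_id)
  }
  list(RFPI = score_profile(trait_id, "RFPI", imp$rfpi, mm),
       RFRSS = score_profile(trait_id, "RFRSS", imp$rfrss, mm),
       RFSF = rfsf)
}
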