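# Synthetic recombinant-inbred panels and simulated expression traits:
# additive and AND-epistatic genetic models on binary genotypes, a ladder of
# Gaussian noise levels scaled to the trait mean, and the worst-rank
# simulation study comparing mapping methods.

#' Simulate a recombinant-inbred genotype panel
#'
#' Each strain's chromosome is an independent two-state Markov chain along
#' the marker positions: the first marker is Bernoulli(0.5) and the switch
#' probability between adjacent markers is
#' `min(1 - exp(-recomb_per_bp * distance), 0.5)` — a Haldane-style map with
#' the doubled recombination fraction of inbred-line map expansion, capped
#' at free recombination. Alleles are therefore balanced (about 50/50 at
#' every marker) and nearby markers are in linkage disequilibrium that
#' decays with distance.
#'
#' @param n_strains Number of strains (>= 2).
#' @param chromosomes List of `c(n_markers, length_bp)` pairs, one per
#'   chromosome.
#' @param recomb_per_bp Recombination intensity per bp (e.g. 5e-8).
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with markers evenly spaced per chromosome.
#' @export
simulate_ri_genotypes <- function(n_strains, chromosomes, recomb_per_bp,
                                  seed = 1) {
  stopifnot(n_strains >= 2, length(chromosomes) >= 1)
  set.seed(seed)
  ids <- character(0); chrs <- character(0); pos <- integer(0)
  for (c_i in seq_along(chromosomes)) {
    nm <- chromosomes[[c_i]][1]; len <- chromosomes[[c_i]][2]
    stopifnot(nm >= 1)
    p_i <- as.integer(round(seq(1, len, length.out = nm)))
    p_i <- sort(unique(p_i))
    chrs <- c(chrs, rep(paste0("chr", c_i), length(p_i)))
    pos <- c(pos, p_i)
    ids <- c(ids, sprintf("m_c%d_%04d", c_i, seq_along(p_i)))
  }
  mm <- marker_map(ids, chrs, pos)
  p <- nrow(mm)
  vals <- matrix(0, n_strains, p)
  col0 <- 0L
  for (c_i in seq_along(chromosomes)) {
    idx <- which(mm$chromosome == paste0("chr", c_i))
    d <- diff(mm$position_bp[idx])
    p_switch <- pmin(1 - exp(-recomb_per_bp * d), 0.5)
    g <- matrix(0, n_strains, length(idx))
    g[, 1] <- stats::rbinom(n_strains, 1, 0.5)
    if (length(idx) > 1) for (j in 2:length(idx)) {
      flip <- stats::rbinom(n_strains, 1, p_switch[j - 1])
      g[, j] <- ifelse(flip == 1, 1 - g[, j - 1], g[, j - 1])
    }
    vals[, idx] <- g
    col0 <- col0 + length(idx)
  }
  genotype_matrix(sprintf("S%03d", seq_len(n_strains)), mm, vals)
}

#' Define a simulated trait model
#'
#' A trait is `baseline + sum(coef * x_m)` over additive terms plus
#' `sum(coef * AND(x_set))` over epistatic terms (logical AND of the binary
#' genotypes, 1 = TRUE), with Gaussian noise whose standard deviation is
#' `noise_pct`% of the noiseless trait mean.
#'
#' @param additive Data frame with columns `marker` (column index) and
#'   `coef`, or NULL.
#' @param epistatic List of `list(markers = <indices>, coef = <real>)`, or
#'   NULL.
#' @param baseline Baseline trait value (default 9).
#' @param noise_pct Noise standard deviation as percent of the noiseless
#'   trait mean.
#' @return A `trait_model_spec`.
#' @export
trait_model_spec <- function(additive = NULL, epistatic = NULL, baseline = 9,
                             noise_pct = 0) {
  stopifnot(noise_pct >= 0)
  causal <- unique(c(additive$marker,
                     unlist(lapply(epistatic, `[[`, "markers"))))
  if (!length(causal)) stop_fatal("trait model needs at least one causal marker")
  structure(list(baseline = baseline, additive = additive,
                 epistatic = epistatic, noise_pct = noise_pct,
                 causal = sort(causal)),
            class = "trait_model_spec")
}

#' Simulate a trait from a model specification
#'
#' @param spec A [trait_model_spec()].
#' @param genotypes A [genotype_matrix()].
#' @param seed Integer seed for the noise draw.
#' @return Numeric trait vector with attribute `causal` (marker ids).
#' @export
simulate_trait <- function(spec, genotypes, seed = 1) {
  X <- genotypes$values
  if (any(spec$causal < 1 | spec$causal > ncol(X)))
    stop_fatal("causal marker index out of range")
  y0 <- rep(spec$baseline, nrow(X))
  if (!is.null(spec$additive))
    for (i in seq_len(nrow(spec$additive)))
      y0 <- y0 + spec$additive$coef[i] * X[, spec$additive$marker[i]]
  for (term in spec$epistatic)
    y0 <- y0 + term$coef * apply(X[, term$markers, drop = FALSE], 1, min)
  if (mean(y0) <= 0) stop_fatal("noiseless trait mean <= 0: noise scale undefined")
  set.seed(seed)
  y <- y0 + stats::rnorm(length(y0), 0, (spec$noise_pct / 100) * mean(y0))
  attr(y, "causal") <- genotypes$markers$marker_id[spec$causal]
  y
}

#' Worst rank of the causal markers in a score profile
#'
#' Markers are ranked by score descending; tied scores all receive the worst
#' rank of their tie group. Returns the maximum rank over the causal set.
#'
#' @param profile A [score_profile()].
#' @param causal Character vector of causal marker ids.
#' @return Integer worst rank.
#' @export
worst_rank <- function(profile, causal) {
  if (!length(causal)) stop_fatal("empty causal set")
  idx <- match(causal, profile$markers$marker_id)
  if (anyNA(idx)) stop_fatal("causal marker not in profile")
  ranks <- rank(-profile$scores, ties.method = "max")
  max(ranks[idx])
}

#' Default trait model generators
#'
#' Named list of model generators, each taking a vector of causal marker
#' indices and a noise level and returning a [trait_model_spec()]:
#' `single` (one locus, coefficient 1); `two_epistatic` (two loci, additive
#' 0.25 each plus AND coefficient 1); `three_additive` (0.25 each);
#' `three_epistatic` (additive 0.25 each plus three-way AND coefficient 1);
#' `eight_locus` (two strong loci, coefficient 1, and six weak, 0.25,
#' all additive — used by the tree-depth investigations).
#'
#' @return Named list; each element has `n_loci` and `build(loci,
#'   noise_pct)`.
#' @export
default_models <- function() {
  add <- function(loci, coefs) data.frame(marker = loci, coef = coefs)
  list(
    single = list(n_loci = 1, build = function(loci, noise_pct)
      trait_model_spec(add(loci, 1), noise_pct = noise_pct)),
    two_epistatic = list(n_loci = 2, build = function(loci, noise_pct)
      trait_model_spec(add(loci, c(0.25, 0.25)),
                       list(list(markers = loci, coef = 1)),
                       noise_pct = noise_pct)),
    three_additive = list(n_loci = 3, build = function(loci, noise_pct)
      trait_model_spec(add(loci, rep(0.25, 3)), noise_pct = noise_pct)),
    three_epistatic = list(n_loci = 3, build = function(loci, noise_pct)
      trait_model_spec(add(loci, rep(0.25, 3)),
                       list(list(markers = loci, coef = 1)),
                       noise_pct = noise_pct)),
    eight_locus = list(n_loci = 8, build = function(loci, noise_pct)
      trait_model_spec(add(loci, c(1, 1, rep(0.25, 6))),
                       noise_pct = noise_pct))
  )
}

#' Draw causal marker indices for a simulated trait
#'
#' Uniform draw without replacement, rejecting configurations with two loci
#' within `min_spacing` map positions of each other (prevents degenerate
#' overlapping models). Uses the current RNG state.
#'
#' @param p Number of markers.
#' @param n_loci Number of causal loci.
#' @param min_spacing Minimum index spacing (default 10).
#' @return Integer vector of marker indices.
#' @export
draw_causal_loci <- function(p, n_loci, min_spacing = 10) {
  repeat {
    loci <- sample.int(p, n_loci)
    if (n_loci == 1 || min(diff(sort(loci))) >= min_spacing) return(loci)
  }
}

#' Map one trait with a named method
#'
#' Dispatch helper used by the simulation study, the benchmark harnesses and
#' the pipeline. RF-based methods fit one forest and extract the requested
#' importance; `RFSF` requires `null_model` for bias correction.
#'
#' @param method One of `HK, CIM, LASSO, ENET, RFPI, RFRSS, RFSF`.
#' @param trait Numeric trait vector.
#' @param genotypes A [genotype_matrix()].
#' @param rf_cfg [rf_config()] for the RF methods.
#' @param null_model [estimate_sf_bias()] result (RFSF only).
#' @param seed Seed for seeded methods (penalized CV, RF).
#' @param trait_id Trait identifier.
#' @return A [score_profile()].
#' @export
map_trait <- function(method, trait, genotypes, rf_cfg = rf_config(),
                      null_model = NULL, seed = 1, trait_id = "trait") {
  switch(method,
    HK = map_hk(trait, genotypes, trait_id),
    CIM = map_cim(trait, genotypes, trait_id = trait_id),
    LASSO = map_penalized(trait, genotypes, lambda2 = 0, seed = seed,
                          trait_id = trait_id),
    ENET = map_penalized(trait, genotypes, lambda2 = 1, seed = seed,
                         trait_id = trait_id),
    RFPI = , RFRSS = , RFSF = {
      cfg <- rf_cfg; cfg$seed <- seed
      map_rf(trait, genotypes, cfg, null_model, trait_id)[[method]]
    },
    stop_fatal("unknown mapping method '", method, "'"))
}

#' Run the worst-rank simulation study
#'
#' For each trait model, replicate and noise level, causal markers are drawn
#' afresh, a trait is simulated, every requested method maps it, and the
#' worst rank of the causal set is recorded. The per-cell summary is the
#' median worst rank over replicates; a cell succeeds when that median is
#' within the top-percentile set size `k = ceiling((1 - pct/100) * p)`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param models Subset of [default_models()] (default: the four main
#'   models).
#' @param methods Character vector of method names.
#' @param noise_levels Percent-of-trait-mean noise ladder (default 2.5 to 20
#'   in steps of 2.5).
#' @param n_reps Replicates per cell (default 50).
#' @param seed Master seed; per-replicate seeds are derived.
#' @param rf_cfg [rf_config()] for RF methods.
#' @param null_model Optional precomputed [estimate_sf_bias()]; computed
#'   once here when RFSF is requested without one.
#' @param pct Top-percentile cutoff (default 99).
#' @return A `simulation_study_result` data frame with columns `model`,
#'   `method`, `noise_pct`, `median_worst_rank`, `success`, `n_reps`, plus
#'   attribute `ranks` holding the full replicate-level ranks.
#' @export
run_simulation_study <- function(genotypes,
                                 models = default_models()[c("single",
                                   "two_epistatic", "three_additive",
                                   "three_epistatic")],
                                 methods = c("HK", "RFSF"),
                                 noise_levels = seq(2.5, 20, by = 2.5),
                                 n_reps = 50, seed = 1,
                                 rf_cfg = rf_config(), null_model = NULL,
                                 pct = 99) {
  p <- nrow(genotypes$markers)
  k <- max(1L, ceiling((1 - pct / 100) * p - 1e-9))
  rf_methods <- intersect(methods, c("RFPI", "RFRSS", "RFSF"))
  bad <- setdiff(methods, c("HK", "CIM", "LASSO", "ENET", "RFPI", "RFRSS",
                            "RFSF"))
  if (length(bad)) stop_fatal("unknown method name '", bad[1], "'")
  if ("RFSF" %in% methods && is.null(null_model))
    null_model <- estimate_sf_bias(genotypes, config = rf_cfg,
                                   seed = derive_seed(seed, "sf_bias"))
  ranks <- list()
  for (model_name in names(models)) {
    model <- models[[model_name]]
    for (rep_i in seq_len(n_reps)) {
      set.seed(derive_seed(seed, "loci", model_name, rep_i))
      loci <- draw_causal_loci(p, model$n_loci)
      for (noise in noise_levels) {
        spec <- model$build(loci, noise)
        y <- simulate_trait(spec, genotypes,
                            seed = derive_seed(seed, "trait", model_name,
                                               rep_i, noise))
        causal <- attr(y, "causal")
        prof_rf <- if (length(rf_methods)) {
          cfg <- rf_cfg
          cfg$seed <- derive_seed(seed, "rf", model_name, rep_i, noise)
          map_rf(y, genotypes, cfg, null_model)
        }
        for (method in methods) {
          prof <- if (method %in% rf_methods) prof_rf[[method]] else
            map_trait(method, y, genotypes,
                      seed = derive_seed(seed, "map", method, model_name,
                                         rep_i, noise))
          ranks[[length(ranks) + 1L]] <-
            data.frame(model = model_name, method = method,
                       noise_pct = noise, rep = rep_i,
                       worst_rank = worst_rank(prof, causal))
        }
      }
    }
  }
  ranks <- do.call(rbind, ranks)
  agg <- stats::aggregate(worst_rank ~ model + method + noise_pct, ranks,
                          stats::median)
  names(agg)[4] <- "median_worst_rank"
  agg$success <- agg$median_worst_rank <= k
  agg$n_reps <- n_reps
  agg <- agg[order(agg$model, agg$method, agg$noise_pct), ]
  rownames(agg) <- NULL
  attr(agg, "ranks") <- ranks
  attr(agg, "k") <- k
  class(agg) <- c("simulation_study_result", "data.frame")
  agg
}
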