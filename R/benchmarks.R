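# Knowledge-driven benchmarks for eQTL score profiles: cis-eQTL proportion,
# pathway enrichment of top-scoring loci (hypergeometric, min over pathways,
# empirical-null corrected, summarized by a one-sided KS statistic against
# the uniform distribution), mutant loss-of-function enrichment, and
# between-method overlap of top-percentile sets.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with `N` items, `K` successes and `n`
#' draws (evaluated in log space by [stats::phyper()]).
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_p <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(n, K))
    stop_fatal("hypergeometric parameters out of bounds")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Kolmogorov-Smirnov test against the uniform distribution
#'
#' `D = sup_x (ECDF(x) - x)`: how much faster the sample accumulates than
#' uniform. The p-value is the asymptotic one-sided form `exp(-2 n D^2)`.
#'
#' @param x Values in (0, 1], at least 5.
#' @return List with `D` and `ks_p`.
#' @export
ks_uniform <- function(x) {
  stopifnot(length(x) >= 5, all(x > 0), all(x <= 1))
  n <- length(x)
  D <- max(c(0, seq_len(n) / n - sort(x)))
  list(D = D, ks_p = min(1, exp(-2 * n * D^2)))
}

# one-sided two-sample KS: D = sup_x (F_null(x) - F_obs(x)), i.e. evidence
# that the observed sample accumulates slower (is stochastically larger)
ks_two_sample_greater <- function(obs, null) {
  pts <- sort(unique(c(obs, null)))
  f_obs <- vapply(pts, function(v) mean(obs <= v), numeric(1))
  f_null <- vapply(pts, function(v) mean(null <= v), numeric(1))
  D <- max(c(0, f_null - f_obs))
  n1 <- length(obs); n2 <- length(null)
  list(D = D, ks_p = min(1, exp(-2 * D^2 * n1 * n2 / (n1 + n2))))
}

#' cis-eQTL proportion
#'
#' A trait has a recovered cis-eQTL when any marker of its top-percentile
#' set lies on the target gene's chromosome within `window_bp` of the gene
#' midpoint (500 kb is the conventional mouse window, 50 kb the yeast one).
#'
#' @param profiles List of [score_profile()]s, one per trait.
#' @param gene_of_trait Named character vector trait id -> gene id.
#' @param genes [gene_annotation()] table.
#' @param window_bp Window around the gene midpoint.
#' @param pct Top-percentile cutoff (default 99).
#' @return A `cis_report`: per-trait flags, the proportion over evaluated
#'   traits, and the count of traits excluded for missing annotation.
#' @export
cis_proportion <- function(profiles, gene_of_trait, genes, window_bp,
                           pct = 99) {
  stopifnot(window_bp > 0)
  flags <- logical(0); evaluated <- character(0); n_excluded <- 0L
  for (prof in profiles) {
    gene <- gene_of_trait[[prof$trait_id]]
    row <- match(gene, genes$gene_id)
    if (is.null(gene) || is.na(row)) { n_excluded <- n_excluded + 1L; next }
    sel <- top_percentile(prof, pct)
    mm <- prof$markers
    idx <- match(sel, mm$marker_id)
    hit <- any(mm$chromosome[idx] == genes$chromosome[row] &
                 abs(mm$position_bp[idx] - genes$midpoint_bp[row]) <= window_bp)
    flags <- c(flags, hit); evaluated <- c(evaluated, prof$trait_id)
  }
  structure(list(cis = stats::setNames(flags, evaluated),
                 proportion = if (length(flags)) mean(flags) else NA_real_,
                 window_bp = window_bp, n_excluded = n_excluded),
            class = "cis_report")
}

# markers mapped-to by a pathway's genes, optionally excluding the trait's
# own gene (default: excluded, so cis hits do not trivially count)
.pathway_markers <- function(genes_in_pw, trait_gene, gene2marker,
                             include_self = FALSE) {
  if (!include_self) genes_in_pw <- setdiff(genes_in_pw, trait_gene)
  unique(unname(gene2marker[intersect(genes_in_pw, names(gene2marker))]))
}

# min-over-pathways hypergeometric enrichment for one selected marker set
.enrichment_min_p <- function(selected, pw_list, trait_gene, gene2marker, N,
                              include_self = FALSE) {
  ps <- numeric(0)
  for (pw in pw_list) {
    pw_markers <- .pathway_markers(pw, trait_gene, gene2marker, include_self)
    K <- length(pw_markers)
    if (K == 0) next                          # all pathway genes beyond 5 Mb
    k <- length(intersect(selected, pw_markers))
    ps <- c(ps, hypergeom_upper_p(k, K, length(selected), N))
  }
  if (!length(ps)) NA_real_ else min(ps)
}

#' Pathway enrichment P value for one trait
#'
#' Tests the trait's top-percentile marker set for enrichment of markers
#' mapping (nearest marker within 5 Mb) to genes in the same pathway as the
#' target gene. With several pathways, all are tested and the minimum P is
#' returned. The population is all markers in the map; the trait's own gene
#' is excluded from the pathway's marker set unless `include_self`.
#'
#' @param profile A [score_profile()].
#' @param trait_gene Gene id of the mapped expression trait.
#' @param pathways A `pathway_collection` from [read_gmt()].
#' @param gene2marker Mapping from [map_genes_to_markers()].
#' @param pct Top-percentile cutoff (default 99).
#' @param include_self Count the trait's own gene in the pathway marker set?
#' @return Minimum hypergeometric upper-tail P, or `NA` when the trait's
#'   gene is in no pathway (or every pathway maps to zero markers).
#' @export
pathway_enrichment_per_trait <- function(profile, trait_gene, pathways,
                                         gene2marker, pct = 99,
                                         include_self = FALSE) {
  pw_list <- pathways[vapply(pathways, function(g) trait_gene %in% g,
                             logical(1))]
  if (!length(pw_list)) return(NA_real_)
  selected <- top_percentile(profile, pct)
  .enrichment_min_p(selected, pw_list, trait_gene, gene2marker,
                    nrow(profile$markers), include_self)
}

#' TF-centric pathway enrichment P value for one trait
#'
#' Variant connecting the target not to its own pathways but to the pathways
#' of its known transcription factors: the tested set is the union of
#' pathways containing any TF of the target gene, with the minimum P over
#' them.
#'
#' @inheritParams pathway_enrichment_per_trait
#' @param tf_map Named list from [read_tf_map()] (target -> TFs).
#' @return Minimum P, or `NA` when no TF (or no TF pathway) is available.
#' @export
tf_pathway_enrichment_per_trait <- function(profile, trait_gene, tf_map,
                                            pathways, gene2marker, pct = 99,
                                            include_self = FALSE) {
  tfs <- tf_map[[trait_gene]]
  if (is.null(tfs) || !length(tfs)) return(NA_real_)
  pw_list <- pathways[vapply(pathways, function(g) any(tfs %in% g),
                             logical(1))]
  if (!length(pw_list)) return(NA_real_)
  selected <- top_percentile(profile, pct)
  .enrichment_min_p(selected, pw_list, trait_gene, gene2marker,
                    nrow(profile$markers), include_self)
}

#' Empirical-null correction of enrichment P values
#'
#' Even with random scores, the min-over-pathways hypergeometric P deviates
#' from uniform, so raw P values are corrected against an empirical null:
#' for each trait, `n_null_per_trait` standard-Gaussian score profiles are
#' drawn on the same marker map, the identical enrichment test (same
#' pathways, same min rule) is run, and the pooled null P values convert
#' each observed P to the add-one-smoothed rank
#' `(1 + #\{null <= raw\}) / (1 + M)`.
#'
#' @param raw_ps Named numeric vector of observed per-trait P values.
#' @param contexts List (parallel to `raw_ps`) of per-trait contexts, each
#'   `list(trait_gene = , tfs_of = NULL)`; traits keep their own pathway
#'   context under the null.
#' @param pathways,gene2marker,markers Shared enrichment inputs.
#' @param n_null_per_trait Null replicates per trait (default 1).
#' @param seed Integer seed for the Gaussian score draws.
#' @param pct,include_self Passed through to the enrichment test.
#' @param tf_map Optional TF map; when given the null replicates run the
#'   TF-centric variant.
#' @return List with `corrected` (named vector) and `null_ps` (the pooled
#'   null distribution).
#' @export
empirical_null_correct <- function(raw_ps, contexts, pathways, gene2marker,
                                   markers, n_null_per_trait = 1, seed = 1,
                                   pct = 99, include_self = FALSE,
                                   tf_map = NULL) {
  p <- nrow(markers)
  null_ps <- numeric(0)
  for (i in seq_along(contexts)) {
    for (r in seq_len(n_null_per_trait)) {
      set.seed(derive_seed(seed, "null_scores", i, r))
      prof <- score_profile(paste0("null", i), "EXTERNAL", stats::rnorm(p),
                            markers)
      np <- if (is.null(tf_map))
        pathway_enrichment_per_trait(prof, contexts[[i]]$trait_gene, pathways,
                                     gene2marker, pct, include_self)
      else
        tf_pathway_enrichment_per_trait(prof, contexts[[i]]$trait_gene,
                                        tf_map, pathways, gene2marker, pct,
                                        include_self)
      if (!is.na(np)) null_ps <- c(null_ps, np)
    }
  }
  M <- length(null_ps)
  if (M == 0) stop_fatal("empirical null is empty")
  corrected <- vapply(raw_ps, function(rp)
    if (is.na(rp)) NA_real_ else (1 + sum(null_ps <= rp)) / (1 + M),
    numeric(1))
  list(corrected = corrected, null_ps = null_ps)
}

#' Pathway-enrichment summary for a set of trait profiles
#'
#' Runs the per-trait enrichment test (plain or TF-centric), corrects the P
#' values against the empirical null, and summarizes the corrected
#' distribution with the one-sided KS statistic against uniform.
#'
#' @param profiles List of [score_profile()]s.
#' @param gene_of_trait Named character vector trait id -> gene id.
#' @param pathways,gene2marker,markers Shared enrichment inputs.
#' @param tf_map Optional [read_tf_map()] result; switches on the TF-centric
#'   variant.
#' @param pct,include_self,n_null_per_trait,seed See
#'   [empirical_null_correct()].
#' @return An `enrichment_summary`: per-trait `raw_p`/`corrected_p`, `D`,
#'   `ks_p`, `n_traits` (evaluated) and `n_skipped`.
#' @export
pathway_enrichment_summary <- function(profiles, gene_of_trait, pathways,
                                       gene2marker, markers, tf_map = NULL,
                                       pct = 99, include_self = FALSE,
                                       n_null_per_trait = 1, seed = 1) {
  raw <- numeric(0); contexts <- list()
  for (prof in profiles) {
    gene <- gene_of_trait[[prof$trait_id]]
    rp <- if (is.null(tf_map))
      pathway_enrichment_per_trait(prof, gene, pathways, gene2marker, pct,
                                   include_self)
    else
      tf_pathway_enrichment_per_trait(prof, gene, tf_map, pathways,
                                      gene2marker, pct, include_self)
    raw[prof$trait_id] <- rp
    contexts[[length(contexts) + 1L]] <- list(trait_gene = gene)
  }
  keep <- !is.na(raw)
  corr <- empirical_null_correct(raw[keep], contexts[keep], pathways,
                                 gene2marker, markers, n_null_per_trait,
                                 seed, pct, include_self, tf_map)
  ks <- if (sum(keep) >= 5) ks_uniform(corr$corrected) else {
    warning("fewer than 5 evaluable traits: KS summary undefined")
    list(D = NA_real_, ks_p = NA_real_)
  }
  structure(list(raw_p = raw, corrected_p = corr$corrected,
                 null_ps = corr$null_ps, D = ks$D, ks_p = ks$ks_p,
                 n_traits = sum(keep), n_skipped = sum(!keep)),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(paste0("enrichment_summary: %d traits (%d skipped), ",
                     "D = %.3f, one-sided KS P = %.3g\n"),
              x$n_traits, x$n_skipped, x$D, x$ks_p))
  invisible(x)
}

#' Mutant loss-of-function enrichment
#'
#' For each trait, markers in the top-percentile set that are the mapped
#' (nearest within 5 Mb) marker of an experimentally repressed regulator
#' contribute the maximum `|log2 ratio|` of that regulator on the trait's
#' gene; values are aggregated over traits. The null repeats the collection
#' with each trait's scores randomly permuted across markers. The one-sided
#' two-sample KS test asks whether the observed values are stochastically
#' larger than the null (`D = sup(F_null - F_obs)`).
#'
#' @param profiles List of [score_profile()]s.
#' @param gene_of_trait Named character vector trait id -> gene id.
#' @param mutant A `mutant_effect_table` from [read_mutant_table()].
#' @param gene2marker Mapping from [map_genes_to_markers()] covering the
#'   regulator genes.
#' @param pct Top-percentile cutoff.
#' @param n_null Null permutations per trait (default 1).
#' @param seed Integer seed.
#' @return A `mutant_enrichment_result` with `observed`, `null`, `D`,
#'   `ks_p`.
#' @export
mutant_enrichment <- function(profiles, gene_of_trait, mutant, gene2marker,
                              pct = 99, n_null = 1, seed = 1) {
  if (nrow(mutant) == 0L) stop_fatal("mutant table is empty")
  regs <- unique(mutant$regulator)
  reg_marker <- gene2marker[intersect(regs, names(gene2marker))]
  marker_regs <- split(names(reg_marker), unname(reg_marker))
  ratio_key <- stats::setNames(mutant$log2_ratio,
                               paste(mutant$regulator, mutant$target,
                                     sep = "\x1f"))
  collect_one <- function(selected, target_gene) {
    hit_regs <- unique(unlist(marker_regs[intersect(selected,
                                                    names(marker_regs))]))
    if (!length(hit_regs)) return(NULL)
    vals <- ratio_key[paste(hit_regs, target_gene, sep = "\x1f")]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NULL)
    max(abs(vals))
  }
  observed <- numeric(0); null <- numeric(0)
  for (prof in profiles) {
    gene <- gene_of_trait[[prof$trait_id]]
    v <- collect_one(top_percentile(prof, pct), gene)
    if (!is.null(v)) observed <- c(observed, v)
    for (r in seq_len(n_null)) {
      set.seed(derive_seed(seed, "mutant_null", prof$trait_id, r))
      perm <- prof
      perm$scores <- sample(prof$scores)
      v <- collect_one(top_percentile(perm, pct), gene)
      if (!is.null(v)) null <- c(null, v)
    }
  }
  if (!length(observed) || !length(null))
    stop_fatal("mutant enrichment found no marker-regulator hits ",
               "(observed: ", length(observed), ", null: ", length(null), ")")
  ks <- ks_two_sample_greater(observed, null)
  structure(list(observed = observed, null = null, D = ks$D,
                 ks_p = ks$ks_p), class = "mutant_enrichment_result")
}

#' @export
print.mutant_enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("mutant_enrichment: %d observed vs %d null values, ",
                     "D = %.3f, one-sided KS P = %.3g\n"),
              length(x$observed), length(x$null), x$D, x$ks_p))
  invisible(x)
}

#' Between-method overlap of top-percentile sets
#'
#' Per trait and method pair, `100 * |A intersect B| / ((|A| + |B|) / 2)`,
#' averaged over traits. With the fixed-size top sets used throughout, this
#' mean-size-normalized overlap is monotonically related to the Jaccard
#' index.
#'
#' @param profile_sets Named list (method -> list of per-trait marker-id
#'   sets, same traits per method).
#' @return Symmetric matrix of mean overlap percentages.
#' @export
method_overlap <- function(profile_sets) {
  methods <- names(profile_sets)
  n_traits <- length(profile_sets[[1]])
  out <- matrix(NA_real_, length(methods), length(methods),
                dimnames = list(methods, methods))
  for (a in seq_along(methods)) for (b in seq_len(a)) {
    vals <- numeric(0)
    for (t in seq_len(n_traits)) {
      A <- profile_sets[[a]][[t]]; B <- profile_sets[[b]][[t]]
      if (!length(A) || !length(B)) next
      vals <- c(vals, 100 * length(intersect(A, B)) /
                  ((length(A) + length(B)) / 2))
    }
    out[a, b] <- out[b, a] <- if (length(vals)) mean(vals) else NA_real_
  }
  out
}
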