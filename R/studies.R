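# Orchestrated investigations: the tree-depth ladder (how forest depth
# affects the three RF importance measures under the cis and pathway
# benchmarks) and the strain-subsampling harness.

#' Subset a genotype matrix by strain indices
#' @param geno A [genotype_matrix()].
#' @param idx Integer strain indices.
#' @export
subset_strains <- function(geno, idx) {
  genotype_matrix(geno$strains[idx], geno$markers,
                  geno$values[idx, , drop = FALSE])
}

#' Subset an expression matrix by strain indices
#' @param expr An [expression_matrix()].
#' @param idx Integer strain indices.
#' @export
subset_strains_expr <- function(expr, idx) {
  expression_matrix(expr$strains[idx], expr$traits, expr$gene_of_trait,
                    expr$values[idx, , drop = FALSE])
}

# map every trait of an expression matrix with one method
.map_all_traits <- function(method, expression, genotypes, rf_cfg, null_model,
                            seed) {
  lapply(expression$traits, function(tr)
    map_trait(method, expression$values[, tr], genotypes, rf_cfg, null_model,
              seed = derive_seed(seed, "map", method, tr), trait_id = tr))
}

# cis proportion + pathway D for a list of profiles
.bench_pair <- function(profiles, expression, genes, pathways, gene2marker,
                        markers, cis_window, pct, n_null_per_trait, seed) {
  cis <- cis_proportion(profiles, expression$gene_of_trait, genes,
                        cis_window, pct)
  enr <- pathway_enrichment_summary(profiles, expression$gene_of_trait,
                                    pathways, gene2marker, markers,
                                    pct = pct,
                                    n_null_per_trait = n_null_per_trait,
                                    seed = seed)
  list(cis_proportion = cis$proportion, pathway_D = enr$D,
       pathway_ks_p = enr$ks_p)
}

#' Tree-depth study for the RF importance measures
#'
#' Refits forests over a ladder of `nodesize` values (deeper trees for
#' smaller nodesize; `nodesize = n` stops after the root split), recomputes
#' RFPI / RFRSS / RFSF per trait — RFSF re-bias-corrected with a
#' matching-nodesize null — and evaluates the cis-proportion and
#' pathway-enrichment benchmarks at each depth. Improvements are reported
#' against the largest nodesize (stump) baseline.
#'
#' @param expression An [expression_matrix()].
#' @param genotypes A [genotype_matrix()].
#' @param genes,pathways Benchmark annotation inputs.
#' @param nodesizes Ladder of nodesize values (default 5, 15, 29, 57, 114,
#'   capped at the strain count).
#' @param rf_cfg Base [rf_config()] (trees, mtry).
#' @param cis_window cis window in bp.
#' @param pct Top-percentile cutoff.
#' @param null_forests,null_trees Null-model size per nodesize.
#' @param n_null_per_trait Null replicates per trait in the enrichment
#'   correction (raise for smoother nulls on small trait sets).
#' @param seed Integer master seed.
#' @return Data frame `nodesize x measure` with benchmark values and
#'   `cis_improvement` / `D_improvement` columns relative to the largest
#'   nodesize.
#' @export
tree_depth_study <- function(expression, genotypes, genes, pathways,
                             nodesizes = c(5, 15, 29, 57, 114),
                             rf_cfg = rf_config(), cis_window = 5e5,
                             pct = 99, null_forests = 500, null_trees = 10,
                             n_null_per_trait = 1, seed = 1) {
  n <- length(genotypes$strains)
  if (any(nodesizes > n)) stop_fatal("nodesize larger than strain count")
  gene2marker <- map_genes_to_markers(genes, genotypes$markers)
  measures <- c("RFPI", "RFRSS", "RFSF")
  rows <- list()
  for (ns in sort(nodesizes, decreasing = TRUE)) {
    cfg <- rf_cfg; cfg$nodesize <- as.integer(ns)
    null_ns <- estimate_sf_bias(genotypes, null_forests, null_trees, cfg,
                                seed = derive_seed(seed, "depth_null", ns))
    profs <- list(RFPI = list(), RFRSS = list(), RFSF = list())
    for (tr in expression$traits) {
      cfg$seed <- derive_seed(seed, "depth_rf", ns, tr)
      trio <- map_rf(expression$values[, tr], genotypes, cfg, null_ns, tr)
      for (m in measures) profs[[m]][[length(profs[[m]]) + 1L]] <- trio[[m]]
    }
    for (m in measures) {
      # null seeded per nodesize only: the same empirical-null draws serve
      # all three measures, so between-measure comparisons are paired
      b <- .bench_pair(profs[[m]], expression, genes, pathways, gene2marker,
                       genotypes$markers, cis_window, pct, n_null_per_trait,
                       derive_seed(seed, "depth_enr", ns))
      rows[[length(rows) + 1L]] <- data.frame(
        nodesize = ns, measure = m, cis_proportion = b$cis_proportion,
        pathway_D = b$pathway_D)
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$nodesize == max(nodesizes), ]
  out$cis_improvement <- out$cis_proportion -
    base$cis_proportion[match(out$measure, base$measure)]
  out$D_improvement <- out$pathway_D -
    base$pathway_D[match(out$measure, base$measure)]
  out[order(out$nodesize, out$measure), ]
}

#' Strain-subsampling study
#'
#' Draws nested strain subsets of decreasing size (each smaller subset
#' contained in the larger, seeded), re-maps every trait with each method at
#' each size, and recomputes the cis-proportion and pathway-enrichment
#' benchmarks.
#'
#' @param genotypes,expression Full data.
#' @param sizes Strictly decreasing subset sizes (each >= 5; a size equal to
#'   the full strain count reproduces the full-data benchmark).
#' @param methods Character vector of mapping method names.
#' @param genes,pathways Benchmark annotation inputs.
#' @param rf_cfg [rf_config()] for RF methods.
#' @param cis_window,pct Benchmark parameters.
#' @param null_forests,null_trees RFSF null-model size per subset.
#' @param seed Integer master seed.
#' @return Data frame `size x method` with `cis_proportion`, `pathway_D`;
#'   the strain order used is attached as attribute `strain_order`.
#' @export
subsample_study <- function(genotypes, expression, sizes, methods,
                            genes, pathways, rf_cfg = rf_config(),
                            cis_window = 5e5, pct = 99, null_forests = 500,
                            null_trees = 10, seed = 1) {
  n <- length(genotypes$strains)
  stopifnot(all(diff(sizes) < 0) || length(sizes) == 1, max(sizes) <= n)
  if (any(sizes < 5)) stop_fatal("subset size below 5")
  set.seed(derive_seed(seed, "subsample_order"))
  ord <- sample.int(n)
  gene2marker <- map_genes_to_markers(genes, genotypes$markers)
  rows <- list()
  for (s in sizes) {
    idx <- sort(ord[seq_len(s)])
    g_s <- subset_strains(genotypes, idx)
    e_s <- subset_strains_expr(expression, idx)
    null_s <- if (any(c("RFSF") %in% methods))
      estimate_sf_bias(g_s, null_forests, null_trees, rf_cfg,
                       seed = derive_seed(seed, "sub_null", s))
    for (method in methods) {
      profs <- .map_all_traits(method, e_s, g_s, rf_cfg, null_s,
                               derive_seed(seed, "sub_map", s))
      b <- .bench_pair(profs, e_s, genes, pathways, gene2marker,
                       g_s$markers, cis_window, pct, 1,
                       derive_seed(seed, "sub_enr", s, method))
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, method = method, cis_proportion = b$cis_proportion,
        pathway_D = b$pathway_D)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "strain_order") <- ord
  out
}
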