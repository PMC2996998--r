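# Synthetic fixture generator: a complete input bundle (genotypes,
# expression traits with planted cis/trans/epistatic regulation, gene
# annotations, pathways containing the planted regulators, TF->target map,
# and a mutant loss-of-function table consistent with the planted
# regulation) so that every mapping method and benchmark can run with no
# external data.

#' Specify a synthetic fixture
#'
#' @param n_strains Strains in the panel.
#' @param chromosomes List of `c(n_markers, length_bp)` per chromosome.
#' @param recomb_per_bp Recombination intensity (see
#'   [simulate_ri_genotypes()]).
#' @param n_genes Genes (one expression trait each).
#' @param fraction_cis Fraction of traits driven by their own gene's nearest
#'   marker.
#' @param n_regulators Planted regulator genes driving the trans traits.
#' @param n_trans_regulators Regulators per trans trait (default 1; larger
#'   values build polygenic traits with several weak trans effects).
#' @param trans_cis_anchor Give each trans trait an additional cis effect
#'   (`cis_effect`) at its own gene, so trans effects sit beneath another
#'   locus as they do in polygenic expression traits.
#' @param trans_decoy_effect When positive, each trans trait also carries a
#'   strong effect at a random unannotated marker — a trans "hotspot"
#'   outside the pathway/TF annotation, so annotated (and cis) loci are the
#'   weaker, conditional part of the signal.
#' @param n_epistatic Trans traits that additionally carry an AND
#'   interaction between two regulator loci.
#' @param n_pathways Total pathways; one per regulator contains the
#'   regulator and its targets, the rest are random.
#' @param pathway_size Genes per pathway.
#' @param cis_effect,trans_effect,epistatic_effect Planted additive / AND
#'   coefficients; `trans_effect` may be a vector, recycled over the
#'   regulators of each trans trait (e.g. `c(1, 0.3)` for one strong and
#'   one weak regulator).
#' @param mutant_log2,background_log2 `|log2 ratio|` for planted
#'   (regulator, target) pairs vs random background pairs.
#' @param noise_pct Trait noise (percent of noiseless mean).
#' @param baseline Baseline trait value.
#' @param seed Integer master seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_strains = 100,
                         chromosomes = rep(list(c(60, 1e8)), 5),
                         recomb_per_bp = 3e-8, n_genes = 60,
                         fraction_cis = 0.5, n_regulators = 5,
                         n_trans_regulators = 1, trans_cis_anchor = FALSE,
                         trans_decoy_effect = 0,
                         n_epistatic = 0, n_pathways = 8, pathway_size = 10,
                         cis_effect = 1, trans_effect = 1,
                         epistatic_effect = 1, mutant_log2 = 3,
                         background_log2 = 0.1, noise_pct = 5, baseline = 9,
                         seed = 1) {
  if (n_regulators > n_genes) stop_fatal("more regulators than genes")
  if (n_trans_regulators > n_regulators)
    stop_fatal("more regulators per trait than planted regulators")
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic input bundle
#'
#' Genotypes come from [simulate_ri_genotypes()]; every gene is placed
#' uniformly on the genome and mapped to its nearest marker. cis traits are
#' driven by their own gene's nearest marker; trans traits by a planted
#' regulator's nearest marker (the regulators are assigned round-robin), a
#' subset additionally carrying an AND interaction between two regulator
#' loci. Each regulator shares a pathway with all of its targets; the
#' remaining pathways are random, and every gene belongs to at least one
#' pathway. The TF map records regulator -> target links, and the mutant
#' table assigns `|log2 ratio| = mutant_log2` to planted (regulator, target)
#' pairs against a small random background.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genotypes`, `expression`, `genes`, `pathways`,
#'   `tf_map`, `mutant`, `gene2marker`, `truth` (per-trait causal marker
#'   ids) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  geno <- simulate_ri_genotypes(spec$n_strains, spec$chromosomes,
                                spec$recomb_per_bp,
                                seed = derive_seed(spec$seed, "fx_geno"))
  mm <- geno$markers
  set.seed(derive_seed(spec$seed, "fx_genes"))
  chr_len <- vapply(spec$chromosomes, `[`, numeric(1), 2)
  g_chr <- sample(length(spec$chromosomes), spec$n_genes, replace = TRUE)
  g_start <- vapply(g_chr, function(ci)
    sample.int(max(chr_len[ci] - 2e4, 1), 1), numeric(1))
  genes <- gene_annotation(sprintf("g%03d", seq_len(spec$n_genes)),
                           paste0("chr", g_chr), g_start, g_start + 1e4)
  gene2marker <- map_genes_to_markers(genes, mm)
  stopifnot(all(genes$gene_id %in% names(gene2marker)))

  regulators <- sample(genes$gene_id, spec$n_regulators)
  n_cis <- round(spec$fraction_cis * spec$n_genes)
  non_reg <- setdiff(genes$gene_id, regulators)
  cis_genes <- sample(non_reg, min(n_cis, length(non_reg)))
  trans_genes <- setdiff(non_reg, cis_genes)

  marker_idx <- function(g) match(gene2marker[[g]], mm$marker_id)
  tf_map <- list(); mutant_rows <- list(); truth <- list()
  traits <- genes$gene_id
  yvals <- matrix(NA_real_, spec$n_strains, length(traits))
  reg_of_trans <- stats::setNames(
    rep(regulators, length.out = length(trans_genes)), trans_genes)
  epi_genes <- if (spec$n_epistatic > 0 && spec$n_regulators >= 2)
    utils::head(trans_genes, spec$n_epistatic) else character(0)

  for (j in seq_along(traits)) {
    g <- traits[j]
    if (g %in% cis_genes) {
      loci <- marker_idx(g)
      model <- trait_model_spec(data.frame(marker = loci,
                                           coef = spec$cis_effect),
                                baseline = spec$baseline,
                                noise_pct = spec$noise_pct)
    } else if (g %in% trans_genes) {
      reg1 <- reg_of_trans[[g]]
      regs <- reg1
      if (spec$n_trans_regulators > 1) {
        extra <- sample(setdiff(regulators, reg1),
                        spec$n_trans_regulators - 1)
        regs <- c(reg1, extra)
      }
      loci <- vapply(regs, marker_idx, integer(1))
      epistatic <- NULL
      if (g %in% epi_genes) {
        if (length(regs) < 2) {
          reg2 <- sample(setdiff(regulators, regs), 1)
          regs <- c(regs, reg2)
          loci <- c(loci, marker_idx(reg2))
        }
        epistatic <- list(list(markers = loci[1:2],
                               coef = spec$epistatic_effect))
      }
      tf_map[[g]] <- regs
      additive <- data.frame(marker = loci,
                             coef = rep_len(spec$trans_effect, length(loci)))
      if (spec$trans_cis_anchor)
        additive <- rbind(additive,
                          data.frame(marker = marker_idx(g),
                                     coef = spec$cis_effect))
      if (spec$trans_decoy_effect > 0)
        additive <- rbind(additive,
                          data.frame(marker = sample.int(nrow(mm), 1),
                                     coef = spec$trans_decoy_effect))
      model <- trait_model_spec(additive, epistatic,
                                baseline = spec$baseline,
                                noise_pct = spec$noise_pct)
      for (r in tf_map[[g]])
        mutant_rows[[length(mutant_rows) + 1L]] <-
          data.frame(regulator = r, target = g,
                     log2_ratio = sample(c(-1, 1), 1) * spec$mutant_log2)
    } else {                       # regulator genes: cis-driven themselves
      loci <- marker_idx(g)
      model <- trait_model_spec(data.frame(marker = loci,
                                           coef = spec$cis_effect),
                                baseline = spec$baseline,
                                noise_pct = spec$noise_pct)
    }
    yvals[, j] <- simulate_trait(model, geno,
                                 seed = derive_seed(spec$seed, "fx_trait", g))
    truth[[g]] <- mm$marker_id[model$causal]
  }

  # background: deleting a regulator perturbs every non-target gene only
  # weakly, as in a loss-of-function compendium measuring the whole genome
  set.seed(derive_seed(spec$seed, "fx_mutant_bg"))
  for (r in regulators) {
    planted <- names(tf_map)[vapply(tf_map, function(x) r %in% x, logical(1))]
    bg <- setdiff(genes$gene_id, c(r, planted))
    mutant_rows[[length(mutant_rows) + 1L]] <-
      data.frame(regulator = r, target = bg,
                 log2_ratio = stats::rnorm(length(bg), 0,
                                           spec$background_log2))
  }
  mutant <- do.call(rbind, mutant_rows)
  class(mutant) <- c("mutant_effect_table", "data.frame")

  # pathways: one per regulator containing regulator + its targets + filler,
  # then random pathways until every gene is covered and n_pathways reached
  set.seed(derive_seed(spec$seed, "fx_pathways"))
  pathways <- list()
  for (r in regulators) {
    targets <- names(tf_map)[vapply(tf_map, function(x) r %in% x, logical(1))]
    members <- unique(c(r, targets))
    filler <- setdiff(genes$gene_id, members)
    extra <- max(0, spec$pathway_size - length(members))
    pathways[[paste0("PW_", r)]] <- c(members, sample(filler,
                                                      min(extra,
                                                          length(filler))))
  }
  uncovered <- setdiff(genes$gene_id, unique(unlist(pathways)))
  i <- 0L
  while (length(pathways) < spec$n_pathways || length(uncovered)) {
    i <- i + 1L
    take <- unique(c(utils::head(uncovered, spec$pathway_size),
                     sample(genes$gene_id, spec$pathway_size)))
    pathways[[sprintf("PW_rand%02d", i)]] <-
      utils::head(take, spec$pathway_size)
    uncovered <- setdiff(uncovered, take)
    if (i > spec$n_pathways + 20) break
  }
  class(pathways) <- "pathway_collection"

  expr <- expression_matrix(geno$strains, traits,
                            stats::setNames(traits, traits), yvals)
  list(genotypes = geno, expression = expr, genes = genes,
       pathways = pathways, tf_map = structure(tf_map,
                                               class = "tf_target_map"),
       mutant = mutant, gene2marker = gene2marker, truth = truth,
       regulators = regulators, spec = spec)
}

#' Write a fixture bundle to disk
#'
#' Emits genotype TSV, expression TSV, BED gene annotations, GMT pathways,
#' TF-map TSV, mutant TSV, and a ground-truth JSON listing the causal
#' markers per trait.
#'
#' @param bundle A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.tsv"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_gene_annotations(bundle$genes, file.path(dir, "genes.bed"))
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  tf <- data.frame(
    tf = unlist(bundle$tf_map),
    target = rep(names(bundle$tf_map), lengths(bundle$tf_map)))
  utils::write.table(tf, file.path(dir, "tf_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$mutant, file.path(dir, "mutant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
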