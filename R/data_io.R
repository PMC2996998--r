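# Domain containers: marker maps, genotype/expression matrices, annotations,
# pathway sets, TF->target maps, mutant effect tables.  Coordinates are
# 1-based inclusive internally; BED input is converted at ingest.

#' Construct a marker map
#'
#' A marker map holds the genomic location of every genotyped marker. Markers
#' must be unique and, within each chromosome, sorted by physical position.
#'
#' @param marker_id Character vector of unique marker identifiers.
#' @param chromosome Character vector of chromosome names.
#' @param position_bp Integer vector of 1-based physical positions (bp).
#' @param position_cm Optional numeric genetic positions (cM).
#' @return A `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chromosome, position_bp, position_cm = NULL) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_bp <- as.integer(position_bp)
  if (anyDuplicated(marker_id)) stop_fatal("duplicate marker ids in marker map")
  if (any(position_bp < 0)) stop_fatal("negative marker positions")
  mm <- data.frame(marker_id = marker_id, chromosome = chromosome,
                   position_bp = position_bp, stringsAsFactors = FALSE)
  if (!is.null(position_cm)) mm$position_cm <- as.numeric(position_cm)
  for (chr in unique(chromosome)) {
    pos <- mm$position_bp[mm$chromosome == chr]
    if (is.unsorted(pos)) stop_fatal("markers on chromosome ", chr,
                                     " not sorted by position")
  }
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Construct a genotype matrix
#'
#' Binary recombinant-inbred genotypes (1 = BB, 0 = DD) for a strain panel.
#'
#' @param strains Character vector of strain identifiers (rows).
#' @param markers A [marker_map()] describing the columns.
#' @param values Numeric matrix (strains x markers) with entries in `{0, 1}`,
#'   or `NA` before imputation.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(strains, markers, values) {
  strains <- as.character(strains)
  values <- as.matrix(values)
  if (ncol(values) != nrow(markers))
    stop_fatal("genotype column count does not match marker map")
  if (length(strains) < 2L) stop_fatal("need at least 2 strains")
  if (nrow(values) != length(strains))
    stop_fatal("genotype row count does not match strain list")
  if (any(colSums(!is.na(values)) == 0L))
    stop_fatal("marker with all genotypes missing")
  ok <- values %in% c(0, 1) | is.na(values)
  if (!all(ok)) stop_fatal("genotype values must be 0, 1 or NA")
  dimnames(values) <- list(strains, markers$marker_id)
  structure(list(strains = strains, markers = markers, values = values),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d markers on %d chromosome(s)\n",
              length(x$strains), nrow(x$markers),
              length(unique(x$markers$chromosome))))
  invisible(x)
}

#' Construct an expression matrix
#'
#' @param strains Character vector of strain identifiers (rows), in the same
#'   order as the matching [genotype_matrix()].
#' @param traits Character vector of trait (probe/transcript) identifiers.
#' @param gene_of_trait Named character vector mapping trait id to gene id.
#' @param values Numeric matrix (strains x traits), finite.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(strains, traits, gene_of_trait, values) {
  strains <- as.character(strains); traits <- as.character(traits)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(strains), ncol(values) == length(traits))
  if (!all(is.finite(values))) stop_fatal("expression values must be finite")
  if (!all(traits %in% names(gene_of_trait)))
    stop_fatal("every trait needs a gene id")
  dimnames(values) <- list(strains, traits)
  structure(list(strains = strains, traits = traits,
                 gene_of_trait = gene_of_trait[traits], values = values),
            class = "expression_matrix")
}

#' Construct a gene annotation table
#'
#' @param gene_id,chromosome Character vectors.
#' @param start_bp,end_bp 1-based inclusive gene bounds, `start_bp <= end_bp`.
#' @return A `gene_annotation` data frame with a `midpoint_bp` column.
#' @export
gene_annotation <- function(gene_id, chromosome, start_bp, end_bp) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop_fatal("duplicate gene ids in annotation")
  start_bp <- as.integer(start_bp); end_bp <- as.integer(end_bp)
  if (any(end_bp < start_bp)) stop_fatal("gene end before start")
  ga <- data.frame(gene_id = gene_id, chromosome = as.character(chromosome),
                   start_bp = start_bp, end_bp = end_bp,
                   midpoint_bp = as.integer(floor((start_bp + end_bp) / 2)),
                   stringsAsFactors = FALSE)
  class(ga) <- c("gene_annotation", "data.frame")
  ga
}

# ---- readers ---------------------------------------------------------------

# allele code -> {0, 1, NA}; anything else is a fatal error at the caller
.decode_allele <- function(x) {
  out <- rep(NA_real_, length(x))
  x <- toupper(trimws(x))
  out[x %in% c("B", "1")] <- 1
  out[x %in% c("D", "0")] <- 0
  bad <- !(x %in% c("B", "D", "1", "0", "H", "U", "NA", ""))
  attr(out, "bad") <- which(bad)
  out
}

#' Load and align a genotype/expression dataset
#'
#' Reads a GeneNetwork-style genotype TSV (`marker_id`, `chromosome`,
#' `position_bp`, then one column per strain with codes among
#' `B/D/H/U/0/1/NA`) and an expression TSV (`trait_id`, `gene_id`, then one
#' column per strain). Strains present in both files are retained in genotype
#' file order; heterozygous/unknown calls are treated as missing and imputed
#' with the per-marker mode (ties broken toward 1); traits without a gene id
#' are dropped.
#'
#' @param genotype_path,expression_path Paths to TSV files (may be gzipped).
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `expression` ([expression_matrix()]) and `report` (counts of shared
#'   strains, imputed calls and dropped traits).
#' @export
load_dataset <- function(genotype_path, expression_path) {
  gt <- utils::read.delim(genotype_path, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chromosome", "position_bp")
  if (!all(need %in% names(gt)))
    stop_fatal("genotype file must have columns ", paste(need, collapse = ", "))
  ex <- utils::read.delim(expression_path, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("trait_id", "gene_id") %in% names(ex)))
    stop_fatal("expression file must have trait_id and gene_id columns")

  gstrains <- setdiff(names(gt), need)
  estrains <- setdiff(names(ex), c("trait_id", "gene_id"))
  shared <- gstrains[gstrains %in% estrains]
  if (length(shared) < 2L) stop_fatal("fewer than 2 strains shared between files")

  mm <- marker_map(gt$marker_id, gt$chromosome, as.integer(gt$position_bp))
  vals <- matrix(NA_real_, nrow = length(shared), ncol = nrow(mm))
  n_missing <- 0L
  for (j in seq_along(shared)) {
    dec <- .decode_allele(gt[[shared[j]]])
    if (length(attr(dec, "bad")))
      stop_fatal("unknown allele code at strain ", shared[j], ", marker ",
                 gt$marker_id[attr(dec, "bad")[1]])
    vals[j, ] <- dec
  }
  vals <- t(vals)                       # markers x strains for imputation
  n_missing <- sum(is.na(vals))
  for (i in seq_len(nrow(vals))) {
    miss <- is.na(vals[i, ])
    if (any(miss)) {
      obs <- vals[i, !miss]
      if (!length(obs)) stop_fatal("marker ", mm$marker_id[i], " entirely missing")
      vals[i, miss] <- if (sum(obs == 1) >= sum(obs == 0)) 1 else 0  # mode, ties -> 1
    }
  }
  geno <- genotype_matrix(shared, mm, t(vals))

  no_gene <- is.na(ex$gene_id) | ex$gene_id == ""
  ex_kept <- ex[!no_gene, , drop = FALSE]
  evals <- t(as.matrix(ex_kept[, shared, drop = FALSE]))
  storage.mode(evals) <- "double"
  expr <- expression_matrix(shared, ex_kept$trait_id,
                            stats::setNames(as.character(ex_kept$gene_id),
                                            ex_kept$trait_id), evals)
  report <- list(n_shared_strains = length(shared),
                 n_genotype_only = length(setdiff(gstrains, shared)),
                 n_expression_only = length(setdiff(estrains, shared)),
                 n_imputed_calls = n_missing,
                 n_traits_dropped_no_gene = sum(no_gene))
  list(genotypes = geno, expression = expr, report = report)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member gene ids.
#'
#' @param path GMT file (may be gzipped).
#' @return A named list of unique gene-id character vectors
#'   (`pathway_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_fatal("GMT line ", i, " has fewer than 3 fields")
    if (f[1] %in% names(out)) stop_fatal("duplicate pathway id '", f[1],
                                         "' at GMT line ", i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_fatal("empty pathway '", f[1], "' at GMT line ", i)
    out[[f[1]]] <- genes
  }
  structure(out, class = "pathway_collection")
}

#' Read gene annotations from BED
#'
#' BED uses 0-based half-open coordinates; they are converted to the 1-based
#' inclusive convention used throughout the package, and the gene midpoint is
#' computed on that scale.
#'
#' @param path BED file with at least chrom/start/end/name columns.
#' @return A [gene_annotation()] table.
#' @export
read_gene_annotations <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop_fatal("BED file needs chrom, start, end, name")
  start0 <- as.numeric(bed[[2]]); end0 <- as.numeric(bed[[3]])
  if (any(end0 <= start0)) stop_fatal("BED interval with end <= start")
  gene_annotation(bed[[4]], bed[[1]], start0 + 1L, end0)
}

#' Read a transcription-factor to target mapping
#'
#' @param path TSV with columns `tf` and `target`.
#' @return Named list: target gene id -> character vector of TF gene ids.
#' @export
read_tf_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(tab)))
    stop_fatal("TF map needs columns tf and target")
  split_map <- lapply(split(tab$tf, tab$target), unique)
  structure(split_map, class = "tf_target_map")
}

#' Read a mutant expression-change table
#'
#' Rows are (regulator, target, log2 expression ratio of the loss-of-function
#' mutant relative to wild type). Repeated pairs are collapsed by keeping the
#' value of largest absolute magnitude.
#'
#' @param path TSV with columns `regulator`, `target`, `log2_ratio`.
#' @return A `mutant_effect_table` data frame with one row per pair.
#' @export
read_mutant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "log2_ratio") %in% names(tab)))
    stop_fatal("mutant table needs columns regulator, target, log2_ratio")
  if (nrow(tab) == 0L) {
    warning("mutant table is empty")
    out <- tab
  } else {
    ratio <- suppressWarnings(as.numeric(tab$log2_ratio))
    if (any(is.na(ratio) | !is.finite(ratio)))
      stop_fatal("non-numeric log2_ratio at row ",
                 which(is.na(ratio) | !is.finite(ratio))[1])
    tab$log2_ratio <- ratio
    key <- paste(tab$regulator, tab$target, sep = "\x1f")
    ord <- order(key, -abs(ratio))      # per pair, largest |ratio| first
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(key[ord]), , drop = FALSE]
    out <- tab[order(tab$regulator, tab$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mutant_effect_table", "data.frame")
  out
}

#' Map genes to their nearest marker
#'
#' Each gene is assigned the same-chromosome marker minimising the distance
#' between the marker position and the gene midpoint. Genes farther than
#' `max_dist_bp` from every marker (or on chromosomes without markers) are
#' omitted. Equidistant ties go to the lower-coordinate marker.
#'
#' @param genes A [gene_annotation()] table.
#' @param markers A [marker_map()].
#' @param max_dist_bp Maximum allowed gene-to-marker distance (default 5 Mb).
#' @return Named character vector: gene id -> marker id.
#' @export
map_genes_to_markers <- function(genes, markers, max_dist_bp = 5e6) {
  out <- character(0)
  for (chr in unique(genes$chromosome)) {
    mk <- markers[markers$chromosome == chr, , drop = FALSE]
    if (!nrow(mk)) next
    gg <- genes[genes$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(gg))) {
      d <- abs(mk$position_bp - gg$midpoint_bp[i])
      best <- which(d == min(d))
      best <- best[which.min(mk$position_bp[best])]   # tie -> lower coordinate
      if (d[best] <= max_dist_bp) out[gg$gene_id[i]] <- mk$marker_id[best]
    }
  }
  out
}

# ---- writers (round-trip support for fixtures and reports) -----------------

#' Write a genotype matrix as TSV
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes <- function(geno, path) {
  tab <- data.frame(marker_id = geno$markers$marker_id,
                    chromosome = geno$markers$chromosome,
                    position_bp = geno$markers$position_bp,
                    stringsAsFactors = FALSE)
  gt <- t(geno$values)
  code <- ifelse(gt == 1, "B", "D")
  tab <- cbind(tab, as.data.frame(code, stringsAsFactors = FALSE))
  names(tab) <- c("marker_id", "chromosome", "position_bp", geno$strains)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(trait_id = expr$traits,
                    gene_id = unname(expr$gene_of_trait),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(t(expr$values)))
  names(tab) <- c("trait_id", "gene_id", expr$strains)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene annotations as BED (0-based half-open)
#' @param genes A [gene_annotation()] table.
#' @param path Output path.
#' @export
write_gene_annotations <- function(genes, path) {
  bed <- data.frame(genes$chromosome, genes$start_bp - 1L, genes$end_bp,
                    genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pathway collection as GMT
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(p)
    paste(c(p, "na", pathways[[p]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
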