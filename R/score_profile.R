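# ScoreProfile: the universal currency between mapping methods and
# benchmarks — one importance score per marker for one trait.

VALID_METHODS <- c("HK", "CIM", "LASSO", "ENET", "RFPI", "RFRSS", "RFSF",
                   "EXTERNAL")

#' Construct a per-marker score profile
#'
#' @param trait_id Trait identifier.
#' @param method One of `HK, CIM, LASSO, ENET, RFPI, RFRSS, RFSF, EXTERNAL`.
#' @param scores Numeric vector aligned to `markers` (higher = more
#'   important; may be negative for bias-corrected selection frequencies and
#'   permutation importances).
#' @param markers The [marker_map()] the scores are aligned to.
#' @param meta Optional named list of provenance (seed, config).
#' @return A `score_profile` object.
#' @export
score_profile <- function(trait_id, method, scores, markers, meta = list()) {
  method <- match.arg(method, VALID_METHODS)
  scores <- as.numeric(scores)
  if (length(scores) != nrow(markers))
    stop_fatal("score length does not match marker map")
  if (!all(is.finite(scores))) stop_fatal("non-finite scores")
  if (method %in% c("HK", "CIM", "LASSO", "ENET") && any(scores < 0))
    stop_fatal(method, " scores must be non-negative")
  structure(list(trait_id = as.character(trait_id), method = method,
                 scores = scores, markers = markers, meta = meta),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("score_profile [%s] trait %s: %d markers, max score %.4g\n",
              x$method, x$trait_id, length(x$scores), max(x$scores)))
  invisible(x)
}

#' Top-percentile marker set
#'
#' Returns the fixed-size set of `k = ceiling((1 - pct/100) * p)` top-scoring
#' markers. Ties are broken deterministically by genome order (map row
#' order: chromosome then position), so sparse profiles where many markers
#' share a score — including zero — still yield a well-defined set.
#'
#' @param profile A [score_profile()].
#' @param pct Percentile cutoff in (0, 100); default 99.
#' @return Character vector of marker ids, best score first. The attribute
#'   `all_tied` flags selections driven purely by the tie-break.
#' @export
top_percentile <- function(profile, pct = 99) {
  stopifnot(pct > 0, pct < 100)
  p <- length(profile$scores)
  k <- ceiling((1 - pct / 100) * p - 1e-9)   # guard against 0.01*p float error
  k <- max(1L, k)
  ord <- order(-profile$scores, seq_len(p))   # map row order breaks ties
  ids <- profile$markers$marker_id[ord[seq_len(k)]]
  attr(ids, "all_tied") <- length(unique(profile$scores)) == 1L
  ids
}

#' Write a score profile as TSV
#'
#' Columns `marker_id, chromosome, position_bp, score`, preceded by `#`
#' header comments recording method, trait and provenance metadata.
#'
#' @param profile A [score_profile()].
#' @param path Output path.
#' @export
write_score_profile <- function(profile, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste0("# method=", profile$method),
               paste0("# trait=", profile$trait_id),
               vapply(names(profile$meta), function(k)
                 paste0("# ", k, "=", profile$meta[[k]]), character(1))), con)
  tab <- data.frame(marker_id = profile$markers$marker_id,
                    chromosome = profile$markers$chromosome,
                    position_bp = profile$markers$position_bp,
                    score = profile$scores)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score profile written by [write_score_profile()]
#'
#' Also the import hook for external mapping tools: any TSV with the same
#' columns can enter the benchmark battery with `method = "EXTERNAL"`.
#'
#' @param path TSV path.
#' @return A [score_profile()].
#' @export
read_score_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  mm <- marker_map(tab$marker_id, tab$chromosome, tab$position_bp)
  method <- meta$method %||% "EXTERNAL"
  meta$method <- NULL; trait <- meta$trait %||% "unknown"; meta$trait <- NULL
  score_profile(trait, method, tab$score, mm, meta)
}
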