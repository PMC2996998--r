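# Shared fixtures built in code.  Panels are cached per session so the many
# tests that only need "some realistic RI panel" do not re-simulate it.

.panel_cache <- new.env(parent = emptyenv())

# small RI panel with LD (60 strains x 120 markers on 3 chromosomes)
small_panel <- function() {
  if (is.null(.panel_cache$small))
    .panel_cache$small <- simulate_ri_genotypes(
      60, rep(list(c(40, 1e8)), 3), 3e-8, seed = 42)
  .panel_cache$small
}

# hand-built genotype matrix from a 0/1 matrix, equally spaced markers
toy_geno <- function(values, chromosome = "chr1", spacing = 1e6) {
  values <- as.matrix(values)
  mm <- marker_map(sprintf("m%02d", seq_len(ncol(values))),
                   rep(chromosome, ncol(values)),
                   seq_len(ncol(values)) * spacing)
  genotype_matrix(sprintf("s%02d", seq_len(nrow(values))), mm, values)
}

# profile with given scores on an arbitrary equally spaced map
toy_profile <- function(scores, method = "EXTERNAL", trait_id = "t1") {
  mm <- marker_map(sprintf("m%03d", seq_along(scores)),
                   rep("chr1", length(scores)), seq_along(scores) * 1000)
  score_profile(trait_id, method, scores, mm)
}

# write a small genotype/expression TSV pair; returns the two paths
write_toy_dataset <- function(dir, geno_rows, expr_rows) {
  gp <- file.path(dir, "geno.tsv"); ep <- file.path(dir, "expr.tsv")
  writeLines(geno_rows, gp); writeLines(expr_rows, ep)
  c(genotypes = gp, expression = ep)
}

# independent OLS oracle: per-marker LOD by explicit normal equations
oracle_lod <- function(y, X) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(y ~ X[, j])
    rss1 <- max(sum(stats::residuals(fit)^2), 1e-10 * rss0)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}

# exhaustive hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
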