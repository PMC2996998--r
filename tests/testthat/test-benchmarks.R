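test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_p(0, 3, 4, 10), 1.0)
  expect_equal(hypergeom_upper_p(5, 5, 5, 10), 1 / choose(10, 5))
  set.seed(61)
  for (r in 1:40) {
    N <- sample(2:15, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_upper_p(k, K, n, N), oracle_hyper_upper(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_p(6, 5, 5, 10), "bounds")
})

test_that("one-sided KS against uniform matches direct ECDF algebra", {
  n <- 40
  grid <- (seq_len(n) - 0.5) / n
  expect_equal(ks_uniform(grid)$D, 0.5 / n, tolerance = 1e-12)
  point <- rep(0.001, 100)
  expect_equal(ks_uniform(point)$D, 0.999, tolerance = 1e-12)
  set.seed(62)
  for (r in 1:10) {
    x <- runif(30)
    D <- ks_uniform(x)$D
    # brute-force sup over a fine grid and at the jump points
    pts <- sort(c(x, seq(0, 1, by = 1e-4)))
    ecdf_x <- ecdf(x)
    expect_equal(D, max(0, max(ecdf_x(pts) - pts)), tolerance = 1e-12)
    # agrees with the statistic of stats::ks.test one-sided variant
    expect_equal(D, unname(suppressWarnings(
      ks.test(x, "punif", alternative = "greater")$statistic)),
      tolerance = 1e-12)
  }
})

test_that("uniform samples rarely trigger the faster-than-uniform alternative", {
  hits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    ks_uniform(runif(1000))$ks_p > 0.01
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("cis flags respect the strict distance window", {
  mm <- marker_map(c("a", "b"), "chr1", c(1e6, 2e6))
  genes <- gene_annotation(c("g_in", "g_out", "g_edge"), "chr1",
                           c(1e6, 2e6 + 5e5 + 1, 1e6 + 5e5),
                           c(1e6, 2e6 + 5e5 + 1, 1e6 + 5e5))
  profs <- list(
    score_profile("t_in", "EXTERNAL", c(1, 0), mm),    # top marker a
    score_profile("t_out", "EXTERNAL", c(1, 0), mm),   # a is > 500 kb away
    score_profile("t_edge", "EXTERNAL", c(1, 0), mm))  # exactly 500 kb
  g2t <- c(t_in = "g_in", t_out = "g_out", t_edge = "g_edge")
  rep <- cis_proportion(profs, g2t, genes, 5e5, pct = 99)
  expect_identical(unname(rep$cis), c(TRUE, FALSE, TRUE))
  expect_equal(rep$proportion, 2 / 3)
})

test_that("cis proportion matches hand enumeration on a planted toy", {
  fx <- generate_fixture(fixture_spec(n_strains = 40, n_genes = 20,
                                      fraction_cis = 1, noise_pct = 0,
                                      seed = 63,
                                      chromosomes = rep(list(c(100, 2e7)), 3)))
  profs <- lapply(fx$expression$traits, function(tr) {
    sc <- numeric(nrow(fx$genotypes$markers))
    sc[match(fx$truth[[tr]], fx$genotypes$markers$marker_id)] <- 1
    score_profile(tr, "EXTERNAL", sc, fx$genotypes$markers)
  })
  rep <- cis_proportion(profs, fx$expression$gene_of_trait, fx$genes, 5e5)
  expect_equal(rep$proportion, 1)      # every causal marker is cis-planted
})

test_that("pathway enrichment follows the min-over-pathways hypergeometric", {
  mm <- marker_map(sprintf("m%03d", 1:100), "chr1", (1:100) * 1e5)
  genes <- sprintf("g%02d", 1:50)
  g2m <- setNames(mm$marker_id[1:50], genes)   # gene i -> marker i
  prof <- score_profile("t", "EXTERNAL", c(rep(1, 1), rep(0, 99)), mm)
  sel <- top_percentile(prof)                  # {m001}
  pw <- structure(list(hit = c("g50", "g01", "g02"),
                       miss = c("g50", "g10", "g11")),
                  class = "pathway_collection")
  # trait gene g50 excluded from its pathways' marker sets
  p_hit <- pathway_enrichment_per_trait(prof, "g50", pw["hit"], g2m)
  expect_equal(p_hit, hypergeom_upper_p(1, 2, 1, 100))
  p_min <- pathway_enrichment_per_trait(prof, "g50", pw, g2m)
  expect_equal(p_min, min(p_hit, hypergeom_upper_p(0, 2, 1, 100)))
  expect_equal(pathway_enrichment_per_trait(prof, "g50", pw["miss"], g2m), 1)
  # gene not in any pathway -> NA (trait skipped upstream)
  expect_true(is.na(pathway_enrichment_per_trait(prof, "g99", pw, g2m)))
  # pathway whose genes all lack markers is skipped entirely
  pw0 <- structure(list(empty = c("g50", "gZZ")), class = "pathway_collection")
  expect_true(is.na(pathway_enrichment_per_trait(prof, "g50", pw0, g2m)))
})

test_that("TF-centric enrichment unions the TF pathways once", {
  mm <- marker_map(sprintf("m%03d", 1:100), "chr1", (1:100) * 1e5)
  g2m <- setNames(mm$marker_id[1:50], sprintf("g%02d", 1:50))
  prof <- score_profile("t", "EXTERNAL", c(1, rep(0, 99)), mm)
  pw <- structure(list(shared = c("tfA", "tfB", "g01", "g02")),
                  class = "pathway_collection")
  tf_map <- structure(list(g30 = c("tfA", "tfB")), class = "tf_target_map")
  p <- tf_pathway_enrichment_per_trait(prof, "g30", tf_map, pw, g2m)
  expect_equal(p, hypergeom_upper_p(1, 2, 1, 100))
  expect_true(is.na(tf_pathway_enrichment_per_trait(prof, "g01", tf_map,
                                                    pw, g2m)))
})

test_that("empirical null correction is an add-one-smoothed rank", {
  mm <- marker_map(sprintf("m%03d", 1:200), "chr1", (1:200) * 1e5)
  genes <- sprintf("g%02d", 1:60)
  g2m <- setNames(rep(mm$marker_id[1:60], 1), genes)
  pw <- structure(list(P = genes[1:20]), class = "pathway_collection")
  contexts <- rep(list(list(trait_gene = "g10")), 20)
  raw <- c(a = 1e-12, b = 1)
  out <- empirical_null_correct(raw, contexts[1:2], pw, g2m, mm,
                                n_null_per_trait = 5, seed = 9)
  M <- length(out$null_ps)
  expect_equal(out$corrected[["a"]], 1 / (1 + M))   # beats every null P
  expect_equal(out$corrected[["b"]], 1)             # all null <= 1
  expect_true(all(out$corrected > 0 & out$corrected <= 1))
})

test_that("randomized scores give no mutant enrichment, planted effects do", {
  fx <- generate_fixture(fixture_spec(n_strains = 50, n_genes = 40,
                                      fraction_cis = 0.4, seed = 65,
                                      chromosomes = rep(list(c(40, 1e8)), 3)))
  # mapped profiles: causal markers carry the top scores
  profs <- lapply(fx$expression$traits, function(tr) {
    sc <- rnorm(nrow(fx$genotypes$markers), 0, 1e-3)
    sc[match(fx$truth[[tr]], fx$genotypes$markers$marker_id)] <- 1
    score_profile(tr, "EXTERNAL", sc, fx$genotypes$markers)
  })
  planted <- mutant_enrichment(profs, fx$expression$gene_of_trait,
                               fx$mutant, fx$gene2marker, n_null = 5,
                               seed = 66)
  expect_lt(planted$ks_p, 0.01)
  # random profiles are exchangeable with their own permutation null
  set.seed(67)
  rand <- lapply(fx$expression$traits, function(tr)
    score_profile(tr, "EXTERNAL", rnorm(nrow(fx$genotypes$markers)),
                  fx$genotypes$markers))
  ks_rand <- mutant_enrichment(rand, fx$expression$gene_of_trait, fx$mutant,
                               fx$gene2marker, n_null = 5, seed = 68)
  expect_gt(ks_rand$ks_p, 0.05)
  expect_error(mutant_enrichment(profs, fx$expression$gene_of_trait,
                                 fx$mutant[0, ], fx$gene2marker),
               "empty")
})

test_that("method overlap is the mean-size-normalized intersection", {
  sets <- list(A = list(c("m1", "m2"), c("m3")),
               B = list(c("m1", "m2"), c("m3")),
               C = list(c("x", "y"), c("z")))
  ov <- method_overlap(sets)
  expect_equal(ov["A", "B"], 100)
  expect_equal(ov["A", "C"], 0)
  expect_equal(ov, t(ov))
  expect_true(all(ov >= 0 & ov <= 100))
  half <- list(A = list(sprintf("m%02d", 1:38)),
               B = list(sprintf("m%02d", 20:57)))
  expect_equal(method_overlap(half)["A", "B"], 50)
})
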