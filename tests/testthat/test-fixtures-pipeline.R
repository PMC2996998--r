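test_that("fixture bundles are internally consistent", {
  fx <- generate_fixture(fixture_spec(n_strains = 100, n_genes = 30,
                                      n_epistatic = 2, seed = 71))
  mm <- fx$genotypes$markers
  # ground truth referential integrity
  expect_true(all(unlist(fx$truth) %in% mm$marker_id))
  expect_setequal(names(fx$truth), fx$expression$traits)
  # realistic allele balance
  freq <- colMeans(fx$genotypes$values)
  expect_true(all(freq >= 0.3 & freq <= 0.7))
  # every gene within 5 Mb of a marker, regulators share pathways with targets
  expect_true(all(fx$genes$gene_id %in% names(fx$gene2marker)))
  for (target in names(fx$tf_map)) {
    for (reg in fx$tf_map[[target]]) {
      shared <- any(vapply(fx$pathways, function(g)
        all(c(reg, target) %in% g), logical(1)))
      expect_true(shared)
    }
  }
  # every gene belongs to at least one pathway
  expect_true(all(fx$genes$gene_id %in% unique(unlist(fx$pathways))))
  # planted mutant pairs carry the large effect
  planted <- mapply(function(t, regs) abs(
    fx$mutant$log2_ratio[fx$mutant$target == t &
                           fx$mutant$regulator %in% regs]),
    names(fx$tf_map), fx$tf_map)
  expect_true(all(unlist(planted) == fx$spec$mutant_log2))
})

test_that("linkage decays with physical distance in simulated panels", {
  geno <- simulate_ri_genotypes(120, list(c(60, 1e8)), 3e-8, seed = 72)
  pos <- geno$markers$position_bp
  pairs <- t(combn(seq(1, 60, by = 3), 2))
  r2 <- apply(pairs, 1, function(ij)
    abs(cor(geno$values[, ij[1]], geno$values[, ij[2]])))
  d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  expect_lt(cor(r2, d, method = "spearman"), 0)
})

test_that("fully cis fixtures place every causal marker in the cis window", {
  fx <- generate_fixture(fixture_spec(n_strains = 40, n_genes = 20,
                                      fraction_cis = 1, seed = 73,
                                      chromosomes = rep(list(c(50, 1e8)), 3)))
  mm <- fx$genotypes$markers
  for (tr in fx$expression$traits) {
    g <- fx$genes[fx$genes$gene_id == tr, ]
    m <- mm[match(fx$truth[[tr]], mm$marker_id), ]
    expect_equal(m$chromosome, g$chromosome)
    expect_lte(abs(m$position_bp - g$midpoint_bp), 5e6)
  }
})

test_that("written fixtures reload into the same matrices", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(n_strains = 30, n_genes = 12,
                                      seed = 74,
                                      chromosomes = rep(list(c(30, 1e8)), 2)))
  write_fixture(fx, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genotypes.tsv", "expression.tsv", "genes.bed", "pathways.gmt",
      "tf_map.tsv", "mutant.tsv", "truth.json")))))
  ds <- load_dataset(file.path(dir, "genotypes.tsv"),
                     file.path(dir, "expression.tsv"))
  expect_equal(unname(ds$genotypes$values), unname(fx$genotypes$values))
  expect_equal(unname(ds$expression$values), unname(fx$expression$values),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(unlist(truth) %in% fx$genotypes$markers$marker_id))
})

test_that("the pipeline runs end to end and reproduces itself", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(n_strains = 40, n_genes = 20,
                                      fraction_cis = 0.4, seed = 75,
                                      chromosomes = rep(list(c(30, 1e8)), 2)))
  write_fixture(fx, dir)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  cfg <- run_config(
    genotype_path = file.path(dir, "genotypes.tsv"),
    expression_path = file.path(dir, "expression.tsv"),
    genes_bed = file.path(dir, "genes.bed"),
    pathways_gmt = file.path(dir, "pathways.gmt"),
    tf_map_path = file.path(dir, "tf_map.tsv"),
    mutant_path = file.path(dir, "mutant.tsv"),
    methods = c("HK", "CIM"), mutant_null = 10, seed = 5, out_dir = out1)
  res1 <- run_pipeline(cfg)
  expect_true(file.exists(file.path(out1, "benchmark_summary.tsv")))
  expect_true(file.exists(file.path(out1, "benchmark_summary.json")))
  expect_true(all(c("cis_proportion", "pathway_D") %in%
                    names(res1$summary)))
  expect_equal(dim(res1$overlap), c(2, 2))
  hdr <- readLines(file.path(out1, "benchmark_summary.tsv"), n = 3)
  expect_true(any(grepl("master_seed=5", hdr)))
  expect_true(any(grepl("config_hash=", hdr)))
  expect_true(any(grepl("marker_map_hash=", hdr)))
  cfg$out_dir <- out2
  res2 <- run_pipeline(cfg)
  expect_identical(res1$summary, res2$summary)
  # EXTERNAL without score files is rejected at validation
  expect_error(run_config(
    genotype_path = file.path(dir, "genotypes.tsv"),
    expression_path = file.path(dir, "expression.tsv"),
    methods = "EXTERNAL"), "EXTERNAL")
})

test_that("the command-line front end writes a fixture bundle", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fx")
  status <- eqtlbench_main(c("fixture", "--out", out, "--seed", "3",
                             "--strains", "30", "--genes", "10"))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "genotypes.tsv")))
  expect_identical(eqtlbench_main(character(0)), 1L)
})
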