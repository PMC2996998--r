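test_that("load_dataset aligns shared strains, decodes alleles and imputes", {
  dir <- withr::local_tempdir()
  paths <- write_toy_dataset(dir,
    c("marker_id\tchromosome\tposition_bp\ts1\ts2\ts3\ts4",
      "m1\tchr1\t100\tB\tD\tB\tB",
      "m2\tchr1\t200\tB\tU\tD\tD",
      "m3\tchr1\t300\tD\tD\tH\tB"),
    c("trait_id\tgene_id\ts1\ts2\ts3",
      "t1\tg1\t1.5\t2.5\t3.5",
      "t2\t\t9\t9\t9"))
  ds <- load_dataset(paths["genotypes"], paths["expression"])
  # only s1..s3 shared; s4 dropped
  expect_identical(ds$genotypes$strains, c("s1", "s2", "s3"))
  expect_identical(ds$expression$strains, c("s1", "s2", "s3"))
  # B,D,B -> 1,0,1
  expect_equal(unname(ds$genotypes$values[, "m1"]), c(1, 0, 1))
  # m2: B,U,D -> mode of {1,0} is a tie -> imputed 1
  expect_equal(unname(ds$genotypes$values[, "m2"]), c(1, 1, 0))
  # m3: D,D,H -> mode 0
  expect_equal(unname(ds$genotypes$values[, "m3"]), c(0, 0, 0))
  expect_false(anyNA(ds$genotypes$values))
  expect_equal(ds$report$n_imputed_calls, 2L)
  expect_equal(ds$report$n_traits_dropped_no_gene, 1L)
  expect_identical(ds$expression$traits, "t1")
})

test_that("load_dataset fails on too few shared strains and unknown codes", {
  dir <- withr::local_tempdir()
  paths <- write_toy_dataset(dir,
    c("marker_id\tchromosome\tposition_bp\ts1\ts2",
      "m1\tchr1\t100\tB\tD"),
    c("trait_id\tgene_id\ts1\tsX", "t1\tg1\t1\t2"))
  expect_error(load_dataset(paths["genotypes"], paths["expression"]),
               "fewer than 2")
  paths <- write_toy_dataset(dir,
    c("marker_id\tchromosome\tposition_bp\ts1\ts2",
      "m1\tchr1\t100\tB\tD",
      "m2\tchr1\t200\tQ\tD"),
    c("trait_id\tgene_id\ts1\ts2", "t1\tg1\t1\t2"))
  expect_error(load_dataset(paths["genotypes"], paths["expression"]),
               "unknown allele code.*s1.*m2")
})

test_that("read_gmt parses sets, deduplicates and rejects malformed lines", {
  f <- withr::local_tempfile(lines = c("P1\tdesc\tg1\tg2",
                                       "P2\tdesc\tg3\tg3"))
  pw <- read_gmt(f)
  expect_equal(pw$P1, c("g1", "g2"))
  expect_equal(pw$P2, "g3")            # duplicate gene collapses to a set
  f2 <- withr::local_tempfile(lines = c("P1\tonly_two_fields"))
  expect_error(read_gmt(f2), "line 1")
  f3 <- withr::local_tempfile(lines = c("P1\td\tg1", "P1\td\tg2"))
  expect_error(read_gmt(f3), "duplicate pathway")
})

test_that("BED annotations convert to 1-based inclusive with midpoints", {
  f <- withr::local_tempfile(lines = c("chr1\t100\t200\tg1",
                                       "chr1\t0\t1\tg2"))
  ga <- read_gene_annotations(f)
  expect_equal(ga$start_bp, c(101L, 1L))
  expect_equal(ga$end_bp, c(200L, 1L))
  expect_equal(ga$midpoint_bp, c(150L, 1L))
  f2 <- withr::local_tempfile(lines = c("chr1\t5\t5\tg1"))
  expect_error(read_gene_annotations(f2), "end <= start")
  f3 <- withr::local_tempfile(lines = c("chr1\t1\t10\tg1", "chr2\t1\t10\tg1"))
  expect_error(read_gene_annotations(f3), "duplicate gene")
})

test_that("mutant table collapses repeated pairs by largest magnitude", {
  f <- withr::local_tempfile(lines = c("regulator\ttarget\tlog2_ratio",
                                       "r\tt\t1.0", "r\tt\t-2.0",
                                       "r\tu\t0"))
  mt <- read_mutant_table(f)
  expect_equal(mt$log2_ratio[mt$target == "t"], -2.0)
  expect_equal(mt$log2_ratio[mt$target == "u"], 0)
  f2 <- withr::local_tempfile(lines = c("regulator\ttarget\tlog2_ratio"))
  expect_warning(mt2 <- read_mutant_table(f2), "empty")
  expect_equal(nrow(mt2), 0L)
  f3 <- withr::local_tempfile(lines = c("regulator\ttarget\tlog2_ratio",
                                        "r\tt\tabc"))
  expect_error(read_mutant_table(f3), "non-numeric")
})

test_that("gene-to-marker mapping picks the nearest marker within 5 Mb", {
  mm <- marker_map(c("a", "b", "c"), "chr1", c(1e6, 3e6, 10e6))
  genes <- gene_annotation(c("g_exact", "g_far", "g_tie", "g_nochr"),
                           c("chr1", "chr1", "chr1", "chrX"),
                           c(3e6, 15000001 - 5e3, 2e6 - 5e3, 1),
                           c(3e6, 15000001 + 5e3, 2e6 + 5e3, 100))
  g2m <- map_genes_to_markers(genes, mm)
  expect_equal(g2m[["g_exact"]], "b")          # midpoint exactly at marker
  expect_false("g_far" %in% names(g2m))        # 5,000,001 bp away -> omitted
  expect_equal(g2m[["g_tie"]], "a")            # equidistant -> lower position
  expect_false("g_nochr" %in% names(g2m))      # no markers on its chromosome
})

test_that("gene-to-marker mapping agrees with an exhaustive scan", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(20:200, 1); ng <- sample(5:50, 1)
    chrs <- sample(1:3, p, replace = TRUE)
    pos <- unlist(lapply(split(seq_len(p), chrs), function(i)
      sort(sample.int(3e7, length(i)))))
    mm <- marker_map(sprintf("m%03d", seq_len(p)),
                     paste0("chr", sort(chrs)), pos)
    genes <- gene_annotation(sprintf("g%02d", seq_len(ng)),
                             paste0("chr", sample(1:3, ng, replace = TRUE)),
                             st <- sample.int(3e7, ng), st + 100)
    g2m <- map_genes_to_markers(genes, mm, max_dist_bp = 5e6)
    for (i in seq_len(ng)) {                   # brute-force per-gene scan
      on_chr <- which(mm$chromosome == genes$chromosome[i])
      d <- abs(mm$position_bp[on_chr] - genes$midpoint_bp[i])
      if (!length(on_chr) || min(d) > 5e6) {
        expect_false(genes$gene_id[i] %in% names(g2m))
      } else {
        best <- on_chr[d == min(d)]
        expect_equal(g2m[[genes$gene_id[i]]],
                     mm$marker_id[best[which.min(mm$position_bp[best])]])
      }
    }
  }
})

test_that("tables round-trip through their writers and readers", {
  dir <- withr::local_tempdir()
  geno <- small_panel()
  write_genotypes(geno, file.path(dir, "g.tsv"))
  ex <- expression_matrix(geno$strains, c("t1", "t2"),
                          c(t1 = "g1", t2 = "g2"),
                          matrix(rnorm(2 * length(geno$strains)),
                                 ncol = 2))
  write_expression(ex, file.path(dir, "e.tsv"))
  ds <- load_dataset(file.path(dir, "g.tsv"), file.path(dir, "e.tsv"))
  expect_equal(unname(ds$genotypes$values), unname(geno$values))
  expect_equal(ds$genotypes$markers$position_bp, geno$markers$position_bp)
  expect_equal(unname(ds$expression$values), unname(ex$values),
               tolerance = 1e-12)

  pw <- structure(list(P1 = c("g1", "g2"), P2 = c("g2", "g3", "g4")),
                  class = "pathway_collection")
  write_gmt(pw, file.path(dir, "p.gmt"))
  expect_equal(read_gmt(file.path(dir, "p.gmt"))$P2, pw$P2)

  ga <- gene_annotation(c("g1", "g2"), c("chr1", "chr2"), c(101, 5001),
                        c(200, 5100))
  write_gene_annotations(ga, file.path(dir, "a.bed"))
  ga2 <- read_gene_annotations(file.path(dir, "a.bed"))
  expect_equal(ga2$start_bp, ga$start_bp)
  expect_equal(ga2$midpoint_bp, ga$midpoint_bp)
})

test_that("score profiles round-trip with provenance metadata", {
  dir <- withr::local_tempdir()
  prof <- toy_profile(c(3, 1, 4, 1, 5), method = "RFSF", trait_id = "tr9")
  prof$meta <- list(seed = 7)
  write_score_profile(prof, file.path(dir, "p.tsv"))
  back <- read_score_profile(file.path(dir, "p.tsv"))
  expect_equal(back$scores, prof$scores)
  expect_equal(back$method, "RFSF")
  expect_equal(back$trait_id, "tr9")
  expect_equal(back$meta$seed, "7")
})
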