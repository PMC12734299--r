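test_that("ancestor generation is deterministic with the stated composition", {
  g1 <- generate_ancestor(10000, 0.5, 1, seed = 7)
  g2 <- generate_ancestor(10000, 0.5, 1, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(genome_length(g1), 10000)
  gc <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / 10000
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)

  g3 <- generate_ancestor(10000, 0.5, 2, seed = 7)
  expect_length(g3, 2)
  expect_equal(genome_length(g3), 10000)
  expect_false(identical(as.character(g1), as.character(g3)))

  expect_error(generate_ancestor(-5, 0.5, 1, seed = 1), "positive")
  expect_error(generate_ancestor(10000, 0.5, 0, seed = 1), "positive")
  expect_error(generate_ancestor(1500, 0.5, 2, seed = 1), "n_contigs")
})

test_that("simulation parameters enforce their invariants", {
  expect_error(sim_params(seed = 1, gc_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(seed = 1, background_divergence = -0.1),
               "\\[0, 1\\]")
  expect_error(sim_params(seed = 1, divergent_block_fraction = 0.3,
                          specific_fraction = 0.3), "0.5")
  expect_error(sim_params(seed = 1, divergent_block_fraction = 0.04,
                          divergent_block_divergence = 0.005,
                          background_divergence = 0.01), "exceed")
  expect_error(sim_params(length_bp = 5000, seed = 1), "10,000")
  expect_error(sim_params(1e5), "seed")
})

test_that("a zero-divergence pair reproduces the ancestor exactly", {
  anc <- generate_ancestor(20000, 0.5, 2, seed = 11)
  p <- sim_params(length_bp = 20000, background_divergence = 0,
                  n_contigs = 2, seed = 11)
  pr <- evolve_pair(anc, p)
  expect_identical(as.character(pr$genome_a), as.character(anc))
  expect_identical(as.character(pr$genome_b), as.character(anc))
  expect_equal(pr$truth$realized_background_identity, 100)
})

test_that("evolution is byte-deterministic for a fixed seed", {
  anc <- generate_ancestor(20000, 0.45, 1, seed = 3)
  p <- sim_params(length_bp = 20000, background_divergence = 0.05,
                  specific_fraction = 0.1, specific_len = 1000, seed = 3)
  pr1 <- evolve_pair(anc, p)
  pr2 <- evolve_pair(anc, p)
  expect_identical(as.character(pr1$genome_a), as.character(pr2$genome_a))
  expect_identical(as.character(pr1$genome_b), as.character(pr2$genome_b))
  expect_identical(pr1$truth$specific_intervals_A,
                   pr2$truth$specific_intervals_A)
})

test_that("realized divergence matches the double-hit-corrected expectation", {
  # direct column-count oracle on the known site-wise alignment
  anc <- generate_ancestor(2e5, 0.5, 1, seed = 17)
  p <- sim_params(length_bp = 2e5, background_divergence = 0.05, seed = 17)
  pr <- evolve_pair(anc, p)
  a <- strsplit(as.character(pr$genome_a[[1]]), "")[[1]]
  b <- strsplit(as.character(pr$genome_b[[1]]), "")[[1]]
  oracle_identity <- 100 * mean(a == b)
  expect_equal(oracle_identity, pr$truth$realized_background_identity,
               tolerance = 1e-12)
  expect_lt(abs(oracle_identity - expected_pairwise_identity(0.05)), 0.5)
})

test_that("mean realized identity tracks the analytic expectation over replicates", {
  for (d0 in c(0.01, 0.05, 0.10)) {
    realized <- vapply(1:20, function(s) {
      anc <- generate_ancestor(1e6, 0.5, 1, seed = 1000 + s)
      p <- sim_params(length_bp = 1e6, background_divergence = d0,
                      seed = 1000 + s)
      evolve_pair(anc, p)$truth$realized_background_identity
    }, numeric(1))
    expect_lt(abs(mean(realized) - expected_pairwise_identity(d0)), 0.2)
  }
})

test_that("specific segments cover the requested genome fraction", {
  anc <- generate_ancestor(5e5, 0.5, 1, seed = 23)
  p <- sim_params(length_bp = 5e5, background_divergence = 0.002,
                  specific_fraction = 0.08, seed = 23)
  pr <- evolve_pair(anc, p)
  covered <- sum(pr$truth$specific_intervals_A$end -
                   pr$truth$specific_intervals_A$start)
  expect_lt(abs(covered / 5e5 - 0.08), 0.005)
  # intervals stay inside their contig and do not overlap
  iv <- pr$truth$specific_intervals_A
  expect_true(all(iv$start >= 0 & iv$end <= 5e5))
  iv <- iv[order(iv$start), ]
  if (nrow(iv) > 1) {
    expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
})

test_that("indels conserve length bookkeeping", {
  anc <- generate_ancestor(50000, 0.5, 1, seed = 31)
  p <- sim_params(length_bp = 50000, background_divergence = 0.01,
                  indel_rate = 2e-4, mean_indel_len = 4, seed = 31)
  pr <- evolve_pair(anc, p)
  t <- pr$truth
  expect_equal(genome_length(pr$genome_a),
               50000 + t$inserted_bp[["A"]] - t$deleted_bp[["A"]])
  expect_equal(genome_length(pr$genome_b),
               50000 + t$inserted_bp[["B"]] - t$deleted_bp[["B"]])
  expect_gt(t$inserted_bp[["A"]] + t$deleted_bp[["A"]], 0)
})

test_that("spectrum planting realizes the requested identity mixture", {
  anc <- generate_ancestor(1e5, 0.5, 1, seed = 41)
  sp <- data.frame(fraction = c(0.9, 0.05), identity = c(99.5, 86))
  pr <- evolve_spectrum_pair(anc, sp, specific_fraction = 0.02, seed = 41)
  # planted mismatch counts are exact: 90 tiles x 5 + 5 tiles x 140
  n_high <- nrow(pr$truth$spectrum_intervals[[1]])
  n_band <- nrow(pr$truth$spectrum_intervals[[2]])
  expect_equal(n_high, 90)
  expect_equal(n_band, 5)
  a <- strsplit(as.character(pr$genome_a[[1]]), "")[[1]]
  b <- strsplit(as.character(pr$genome_b[[1]]), "")[[1]]
  spec_iv <- pr$truth$specific_intervals_A
  spec_mask <- logical(1e5)
  for (k in seq_len(nrow(spec_iv))) {
    spec_mask[(spec_iv$start[k] + 1):spec_iv$end[k]] <- TRUE
  }
  mm <- sum(a != b & !spec_mask)
  expect_equal(mm, 90 * 5 + 5 * 140)
})

test_that("cassette insertion conserves length and handles both strands", {
  anc <- generate_ancestor(10000, 0.5, 1, seed = 51)
  cas <- as.character(generate_ancestor(1200, 0.5, 1, seed = 52)[[1]])
  ins <- insert_rdna_cassette(anc, cas, "contig_1", 5000, "+")
  expect_equal(genome_length(ins$genome), 11200)
  expect_equal(substr(as.character(ins$genome[[1]]), 5001, 6200), cas)
  expect_equal(ins$interval$start, 5000)
  expect_equal(ins$interval$end, 6200)

  pre <- insert_rdna_cassette(anc, cas, "contig_1", 0, "+")
  expect_equal(substr(as.character(pre$genome[[1]]), 1, 1200), cas)

  minus <- insert_rdna_cassette(anc, cas, "contig_1", 5000, "-")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cas)))
  expect_equal(substr(as.character(minus$genome[[1]]), 5001, 6200), rc)

  expect_error(insert_rdna_cassette(anc, cas, "contig_1", 20000), "position")
  expect_error(insert_rdna_cassette(anc, substr(cas, 1, 400), "contig_1", 0),
               "500")
  expect_error(insert_rdna_cassette(anc, cas, "nope", 0), "contig")
})

test_that("coverage simulation matches the karyotype expectations", {
  p <- coverage_sim_params(mean_depth = 200, nuclear_ratio = 0.5, seed = 1)
  hom <- simulate_gene_coverage(p, "homokaryon")
  expect_setequal(hom$gene, mat_gene_vocabulary())
  # all six genes share the same expectation; with depth 200 every gene
  # should sit within ~5 sd of it
  expect_true(all(abs(hom$reads_per_kbp - 200) < 5 * sqrt(200 / 0.55)))

  # averaged over replicates the heterokaryon expectations separate
  reps <- lapply(1:100, function(s) {
    simulate_gene_coverage(
      coverage_sim_params(200, 0.5, seed = s), "heterokaryon")
  })
  mat_mean <- mean(vapply(reps, function(r) {
    mean(r$reads_per_kbp[grepl("^mat", r$gene)])
  }, numeric(1)))
  flank_mean <- mean(vapply(reps, function(r) {
    mean(r$reads_per_kbp[r$gene %in% c("APN2", "SLA2")])
  }, numeric(1)))
  expect_lt(abs(mat_mean - 100), 5)
  expect_lt(abs(flank_mean - 200), 5)

  # a strongly biased nuclear ratio starves the minority idiomorph
  biased <- simulate_gene_coverage(
    coverage_sim_params(200, 0.95, seed = 2), "heterokaryon")
  expect_lt(biased$reads_per_kbp[biased$gene == "mat1-2-1"], 50)

  expect_error(coverage_sim_params(0, 0.5, seed = 1), "positive")
  expect_error(coverage_sim_params(100, 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("mat fixtures realize the requested architectures", {
  fx <- build_mat_fixture("fused", seed = 61)
  genes <- fx$annotations$gene
  expect_setequal(genes, mat_gene_vocabulary())
  apn2 <- fx$annotations[fx$annotations$gene == "APN2", ]
  sla2 <- fx$annotations[fx$annotations$gene == "SLA2", ]
  mats <- fx$annotations[grepl("^mat", fx$annotations$gene), ]
  expect_true(all(mats$start >= min(apn2$start, sla2$start) &
                    mats$end <= max(apn2$end, sla2$end)))

  fx12 <- build_mat_fixture("single_mat1-2", seed = 62)
  expect_true("mat1-2-1" %in% fx12$annotations$gene)
  expect_false(any(grepl("^mat1-1", fx12$annotations$gene)))

  fxsu <- build_mat_fixture("split_unlinked", seed = 63)
  expect_length(fxsu$genome, 2)

  fxp <- build_mat_fixture("fused", pseudogenize_mat113 = TRUE, seed = 64)
  expect_true(fxp$annotations$pseudogene[fxp$annotations$gene == "mat1-1-3"])

  expect_error(build_mat_fixture("nonsense", seed = 1), "unknown architecture")
})

test_that("annotation and coverage tables round-trip through files", {
  fx <- build_mat_fixture("fused", pseudogenize_mat113 = TRUE, seed = 71)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations_tsv(fx$annotations, tsv)
  write_annotations_gff3(fx$annotations, gff)
  back_tsv <- read_annotations(tsv)
  back_gff <- read_annotations(gff)
  for (back in list(back_tsv, back_gff)) {
    expect_equal(back$gene, fx$annotations$gene)
    expect_equal(back$start, fx$annotations$start)
    expect_equal(back$end, fx$annotations$end)
    expect_equal(back$strand, fx$annotations$strand)
  }
  # pseudogene flag survives GFF3 (not part of the 5-column TSV)
  expect_equal(back_gff$pseudogene, fx$annotations$pseudogene)

  cov <- simulate_gene_coverage(coverage_sim_params(150, seed = 72),
                                "homokaryon")
  cov_path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(cov, cov_path)
  back <- read_coverage_tsv(cov_path)
  expect_equal(back$gene, cov$gene)
  expect_equal(back$reads_per_kbp, cov$reads_per_kbp, tolerance = 1e-9)
})
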