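test_that("the decision rules fire in the documented order", {
  t <- delimit_thresholds()
  # high ANI: conspecific
  expect_equal(classify_pair(make_rani(99.74), t)$verdict, "same_species")
  expect_equal(classify_pair(make_rani(100), t)$verdict, "same_species")
  # low ANI with a divergent-block spectrum: conspecific via the exception
  ex <- classify_pair(make_rani(98.69, high = 0.90, band = 0.04,
                                specific = 0.01), t)
  expect_equal(ex$verdict, "same_species_divergent_blocks")
  expect_match(paste(ex$evidence, collapse = " "), "rule 2")
  # low ANI without the signature: distinct species
  expect_equal(classify_pair(make_rani(93.01, high = 0.05, band = 0.005,
                                       specific = 0.085), t)$verdict,
               "different_species")
  # each exception condition is individually necessary
  expect_equal(classify_pair(make_rani(98.69, high = 0.5, band = 0.04,
                                       specific = 0.01), t)$verdict,
               "different_species")
  expect_equal(classify_pair(make_rani(98.69, high = 0.9, band = 0.005,
                                       specific = 0.01), t)$verdict,
               "different_species")
  expect_equal(classify_pair(make_rani(98.69, high = 0.9, band = 0.04,
                                       specific = 0.08), t)$verdict,
               "different_species")
  # the undecided zone
  expect_equal(classify_pair(make_rani(99.2), t)$verdict, "ambiguous")
  expect_equal(classify_pair(make_rani(99.0), t)$verdict, "ambiguous")
})

test_that("classification is pure and monotone in ANI for a fixed spectrum", {
  t <- delimit_thresholds()
  r <- make_rani(99.2)
  expect_identical(classify_pair(r, t)$verdict, classify_pair(r, t)$verdict)
  rank <- c(different_species = 1, same_species_divergent_blocks = 1,
            ambiguous = 2, same_species = 3)
  grid <- seq(97, 100, by = 0.05)
  verdicts <- vapply(grid, function(a) {
    classify_pair(make_rani(a, high = 0.99, band = 0, specific = 0),
                  t)$verdict
  }, character(1))
  expect_true(all(diff(rank[verdicts]) >= 0))
  # the transition into same_species happens exactly at t_same
  expect_equal(unname(verdicts[grid == 99.5]), "same_species")
  expect_equal(unname(verdicts[grid == 99.45]), "ambiguous")
})

test_that("threshold construction validates its arguments", {
  expect_error(delimit_thresholds(t_same = 99, t_diff = 99.5), "below")
  expect_error(delimit_thresholds(high_id_min_fraction = 1.2), "\\[0, 1\\]")
  expect_error(classify_pair(list(ani_mean = 99)), "reciprocal_ani")
})

test_that("all pairs of a small panel are computed and classified", {
  anc <- generate_ancestor(40000, 0.5, 1, seed = 101)
  close1 <- evolve_pair(anc, sim_params(
    length_bp = 40000, background_divergence = divergence_for_identity(99.8),
    seed = 102))
  far <- evolve_pair(anc, sim_params(
    length_bp = 40000, background_divergence = divergence_for_identity(95),
    seed = 103))
  genomes <- list(a1 = close1$genome_a, a2 = close1$genome_b,
                  b1 = far$genome_b)
  res <- run_all_pairs(genomes)
  expect_equal(nrow(res$calls), 3)  # n(n-1)/2
  expect_equal(sum(res$calls$verdict == "same_species"), 1)
  expect_equal(res$calls$verdict[res$calls$id_a == "a1" &
                                   res$calls$id_b == "a2"], "same_species")
  expect_equal(res$ani_matrix, t(res$ani_matrix))
  expect_true(all(diag(res$ani_matrix) == 100))

  expect_error(run_all_pairs(genomes[1]), "at least two")
  expect_error(run_all_pairs(setNames(genomes, c("x", "x", "y"))),
               "duplicate")
})

test_that("reports round-trip through the files they write", {
  anc <- generate_ancestor(20000, 0.5, 1, seed = 111)
  pr <- evolve_pair(anc, sim_params(
    length_bp = 20000, background_divergence = divergence_for_identity(99.8),
    seed = 112))
  res <- run_all_pairs(list(g1 = pr$genome_a, g2 = pr$genome_b))
  dir <- withr::local_tempdir()
  write_report(res, dir)
  expect_true(file.exists(file.path(dir, "ani_matrix.tsv")))
  expect_true(file.exists(file.path(dir, "calls.tsv")))
  back <- read_ani_matrix(file.path(dir, "ani_matrix.tsv"))
  expect_equal(back, res$ani_matrix)
  js_files <- list.files(file.path(dir, "pairs"), full.names = TRUE)
  expect_length(js_files, 1)
  js <- jsonlite::read_json(js_files[1])
  # thresholds and config are echoed verbatim
  expect_equal(js$thresholds$t_same, res$thresholds$t_same)
  expect_equal(js$config$window_bp, res$config$window_bp)
  # verdict in the JSON matches a re-classification of the same pair
  recl <- classify_pair(res$pairs[[1]], res$thresholds)
  expect_equal(js$verdict, recl$verdict)
  expect_equal(js$ani_mean, res$pairs[[1]]$ani_mean)
  # histogram totals are conserved in the serialized report
  fwd <- js$forward
  expect_equal(sum(unlist(fwd$histogram$counts)) + fwd$histogram$zero_hits,
               fwd$n_fragments)
})
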