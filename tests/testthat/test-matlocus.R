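test_that("each fixture architecture is classified as itself", {
  for (arch in mat_fixture_architectures()) {
    for (seed in 1:5) {
      fx <- build_mat_fixture(arch, seed = seed)
      cl <- classify_architecture(fx$annotations, contig_lens(fx$genome))
      expect_equal(architecture_fixture_label(cl), arch,
                   info = sprintf("%s seed %d", arch, seed))
      expect_equal(cl$edge_reassembled,
                   arch == "split_edge_reassemblable",
                   info = sprintf("%s seed %d", arch, seed))
    }
  }
})

test_that("edge reassembly respects the distance bound", {
  fx <- build_mat_fixture("split_edge_reassemblable", seed = 7)
  lens <- contig_lens(fx$genome)
  join <- attempt_edge_reassembly(fx$annotations, lens)
  expect_true(join$success)
  # a zero bound can never bridge the gap the fixture leaves
  cl0 <- classify_architecture(fx$annotations, lens, edge_distance = 0)
  expect_false(cl0$edge_reassembled)
  expect_equal(cl0$class, "incomplete")
  # disabling reassembly leaves the split classification
  cl_off <- classify_architecture(fx$annotations, lens,
                                  attempt_reassembly = FALSE)
  expect_false(cl_off$edge_reassembled)

  # unlinked fixture: the orphan idiomorph sits mid-contig and the flanks
  # share a contig, so reassembly cannot fire
  fxu <- build_mat_fixture("split_unlinked", seed = 8)
  ju <- attempt_edge_reassembly(fxu$annotations, contig_lens(fxu$genome))
  expect_false(ju$success)
  clu <- classify_architecture(fxu$annotations, contig_lens(fxu$genome))
  expect_equal(clu$class, "split_unlinked")
})

test_that("degenerate annotations are reported, not misclassified", {
  fx <- build_mat_fixture("fused", seed = 9)
  lens <- contig_lens(fx$genome)
  dup <- rbind(fx$annotations,
               transform(fx$annotations[fx$annotations$gene == "mat1-2-1", ],
                         contig = "contig_other"))
  expect_warning(
    cl <- classify_architecture(dup, c(lens, contig_other = 10000L)),
    "duplicated")
  expect_equal(cl$class, "incomplete")

  no_flanks <- fx$annotations[grepl("^mat", fx$annotations$gene), ]
  cl2 <- classify_architecture(no_flanks, lens)
  expect_equal(cl2$class, "incomplete")

  expect_error(classify_architecture(fx$annotations, lens["bogus"]),
               "length")
  expect_error(classify_architecture(fx$annotations[0, ], lens),
               "non-empty")
})

test_that("published per-gene coverage values give an equal-coverage verdict", {
  printed <- list(
    PSN1167 = list(flanks = c(184, 195), mats = c(196, 208, 224, 206)),
    PSN850 = list(flanks = c(202, 226), mats = c(246, 242, 217, 238)),
    CBS365.69 = list(flanks = c(1241, 1090), mats = c(1289, 1289, 1216, 1019)))
  for (nm in names(printed)) {
    ct <- coverage_ratio_test(make_coverage(printed[[nm]]$flanks,
                                            printed[[nm]]$mats))
    expect_equal(ct$verdict, "equal_coverage", info = nm)
    expect_lt(ct$flank_mat_ratio, 1)
  }
})

test_that("a balanced heterokaryon shows the elevated-flank signature", {
  cov <- simulate_gene_coverage(
    coverage_sim_params(200, 0.5, seed = 17), "heterokaryon")
  ct <- coverage_ratio_test(cov)
  expect_equal(ct$verdict, "elevated_flank")
  expect_gt(ct$flank_mat_ratio, 1.5)
  expect_lt(ct$p_value, 0.05)
})

test_that("zero mat coverage is undetermined, not a verdict", {
  cov <- make_coverage(c(200, 210), c(0, 0, 0, 0))
  ct <- coverage_ratio_test(cov)
  expect_equal(ct$verdict, "undetermined")
  expect_error(coverage_ratio_test(make_coverage(c(1, 2), c(1, 1, 1, 1))[1:2, ]),
               "flanking")
})

test_that("pseudogenes can be excluded from the coverage comparison", {
  cov <- make_coverage(c(200, 200), c(100, 100, 500, 100))
  with_psi <- coverage_ratio_test(cov, exclude = "mat1-1-3")
  without <- coverage_ratio_test(cov)
  expect_gt(with_psi$flank_mat_ratio, without$flank_mat_ratio)
})

test_that("the breeding-system truth table is total and follows the rules", {
  archs <- list(
    fused = structure(list(class = "fused",
                           idiomorph_present = c("mat1-1", "mat1-2"),
                           edge_reassembled = FALSE, evidence = character(0)),
                      class = "mat_architecture"),
    split = structure(list(class = "split_unlinked",
                           idiomorph_present = c("mat1-1", "mat1-2"),
                           edge_reassembled = FALSE, evidence = character(0)),
                      class = "mat_architecture"),
    single = structure(list(class = "single_idiomorph",
                            idiomorph_present = "mat1-2",
                            edge_reassembled = FALSE, evidence = character(0)),
                       class = "mat_architecture"),
    incomplete = structure(list(class = "incomplete",
                                idiomorph_present = character(0),
                                edge_reassembled = FALSE,
                                evidence = character(0)),
                           class = "mat_architecture"))
  verdicts <- list("equal_coverage", "elevated_flank", "undetermined", NULL)
  fertility <- list(TRUE, FALSE, NA)
  allowed <- c("homothallic", "heterothallic_likely",
               "single_mating_type_unresolved", "undetermined")
  for (a in archs) for (v in verdicts) for (f in fertility) {
    call <- infer_breeding_system(a, v, f)
    expect_true(call$call %in% allowed)
  }
  # the specific published-case mappings
  expect_equal(infer_breeding_system(archs$fused, NULL, TRUE)$call,
               "homothallic")
  expect_equal(infer_breeding_system(archs$split, "equal_coverage")$call,
               "homothallic")
  expect_equal(infer_breeding_system(archs$split, "elevated_flank")$call,
               "heterothallic_likely")
  expect_equal(infer_breeding_system(archs$split, NULL)$call,
               "undetermined")
  expect_equal(infer_breeding_system(archs$single, NULL, FALSE)$call,
               "heterothallic_likely")
  expect_equal(infer_breeding_system(archs$single, NULL, TRUE)$call,
               "single_mating_type_unresolved")
  expect_equal(infer_breeding_system(archs$incomplete)$call, "undetermined")
})

test_that("the strain-level report chains files into a breeding call", {
  fx <- build_mat_fixture("split_unlinked", seed = 23)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations_gff3(fx$annotations, gff)
  cov <- simulate_gene_coverage(coverage_sim_params(200, seed = 23),
                                "homokaryon")
  cov_path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(cov, cov_path)
  rep <- mat_locus_report(gff, contig_lens(fx$genome), cov_path,
                          fertility_observed = TRUE, strain = "demo")
  expect_equal(rep$architecture$class, "split_unlinked")
  expect_equal(rep$coverage_test$verdict, "equal_coverage")
  expect_equal(rep$breeding_call$call, "homothallic")

  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mat_report(rep, js, tsv)
  back <- jsonlite::read_json(js)
  expect_equal(back$architecture$class, "split_unlinked")
  expect_equal(back$breeding_call$call, "homothallic")
  line <- read.delim(tsv)
  expect_equal(line$breeding_call, "homothallic")
})
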