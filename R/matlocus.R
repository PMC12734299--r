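# Mating-type locus architecture and breeding-system inference. The
# classifier works from gene annotations alone (no homology search): it
# asks whether the mat genes sit between the APN2/SLA2 anchors on one
# contig (fused locus, the arrangement of homothallic Sordariales),
# whether a split locus can be rejoined because the mat genes lie at
# contig edges, or whether the idiomorphs are unlinked or one is missing.
# The coverage-ratio test then separates a homothallic strain (all six
# genes single-copy) from a mat1-1/mat1-2 heterokaryon, in which each
# idiomorph is carried by only part of the nuclei and the flanking genes
# accumulate the summed coverage of both idiomorph classes.

.norm_genes <- function(genes) {
  vocab <- mat_gene_vocabulary()
  m <- match(tolower(genes), tolower(vocab))
  out <- vocab[m]
  out[is.na(m)] <- NA_character_
  out
}

.check_annotations <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "contig", "start", "end", "strand") %in%
                  names(annotations)))
  if (nrow(annotations) == 0) stop("annotations must be non-empty")
  if (any(annotations$start >= annotations$end)) {
    stop("annotation intervals must satisfy start < end")
  }
  ann <- annotations
  norm <- .norm_genes(ann$gene)
  if (anyNA(norm)) {
    warning("dropping annotations outside the MAT-region vocabulary: ",
            paste(unique(ann$gene[is.na(norm)]), collapse = ", "))
  }
  ann$gene <- norm
  ann <- ann[!is.na(ann$gene), , drop = FALSE]
  if (!"pseudogene" %in% names(ann)) ann$pseudogene <- FALSE
  ann
}

#' Attempt contig-edge reassembly of a split MAT locus
#'
#' A locus split over two contigs can still represent the fused
#' arrangement when the assembly merely broke inside the locus. The join
#' is accepted when (i) APN2 lies on one contig without SLA2 and SLA2 on
#' another without APN2, (ii) every mat gene lies on one of those two
#' contigs, (iii) on each contig the mat genes sit between the anchor gene
#' and a contig end, and (iv) the gap between the gene cluster and that
#' contig end is at most `edge_distance`.
#'
#' @param annotations annotation data.frame (gene, contig, start, end,
#'   strand).
#' @param contig_lengths named vector of contig lengths (bp).
#' @param edge_distance maximum cluster-to-edge gap, bp.
#' @return list with `success` (logical) and `evidence` (character).
#' @export
attempt_edge_reassembly <- function(annotations, contig_lengths,
                                    edge_distance = 2000) {
  ann <- .check_annotations(annotations)
  mat_genes <- c(.MAT1_GENES, .MAT2_GENES)
  apn2 <- ann[ann$gene == "APN2", , drop = FALSE]
  sla2 <- ann[ann$gene == "SLA2", , drop = FALSE]
  fail <- function(msg) list(success = FALSE, evidence = msg)
  if (nrow(apn2) != 1 || nrow(sla2) != 1) {
    return(fail("edge reassembly needs exactly one APN2 and one SLA2"))
  }
  c1 <- apn2$contig; c2 <- sla2$contig
  if (c1 == c2) {
    return(fail("APN2 and SLA2 on the same contig; nothing to rejoin"))
  }
  mats <- ann[ann$gene %in% mat_genes, , drop = FALSE]
  if (!all(mats$contig %in% c(c1, c2))) {
    return(fail("mat genes on contigs other than the APN2/SLA2 contigs"))
  }
  side_ok <- function(ct, anchor) {
    if (!ct %in% names(contig_lengths)) {
      stop("no length provided for contig '", ct, "'")
    }
    clen <- contig_lengths[[ct]]
    rows <- rbind(anchor, mats[mats$contig == ct, , drop = FALSE])
    lo <- min(rows$start); hi <- max(rows$end)
    mids <- (rows$start + rows$end) / 2
    anchor_mid <- (anchor$start + anchor$end) / 2
    # towards the right end: anchor innermost, cluster within edge_distance
    right_ok <- (clen - hi) <= edge_distance && all(mids >= anchor_mid)
    left_ok <- lo <= edge_distance && all(mids <= anchor_mid)
    right_ok || left_ok
  }
  if (side_ok(c1, apn2) && side_ok(c2, sla2)) {
    list(success = TRUE,
         evidence = sprintf(
           "locus rejoined across contig edges: %s (APN2 side) + %s (SLA2 side), edge_distance %d bp",
           c1, c2, as.integer(edge_distance)))
  } else {
    fail("mat genes not within edge_distance of the relevant contig ends")
  }
}

#' Classify the mating-type locus architecture
#'
#' Classes: `fused` (both idiomorphs present, all mat genes between APN2
#' and SLA2 on one contig, possibly after contig-edge reassembly),
#' `split_unlinked` (both idiomorphs present, exactly one flanked by
#' APN2/SLA2, the other on a contig carrying neither flank),
#' `single_idiomorph` (only one idiomorph's genes present), `incomplete`
#' (flanks or mat genes missing, or contradictory placements). A gene
#' annotated twice on different contigs triggers a duplicated-gene warning
#' and the `incomplete` class.
#'
#' @param annotations annotation data.frame (gene, contig, start, end,
#'   strand, optional pseudogene).
#' @param contig_lengths named vector of contig lengths for every
#'   referenced contig.
#' @param edge_distance passed to [attempt_edge_reassembly()].
#' @param attempt_reassembly try contig-edge reassembly before settling on
#'   a split class.
#' @return a `mat_architecture` object: `class`, `idiomorph_present`,
#'   `edge_reassembled`, `evidence`.
#' @export
classify_architecture <- function(annotations, contig_lengths,
                                  edge_distance = 2000,
                                  attempt_reassembly = TRUE) {
  ann <- .check_annotations(annotations)
  missing_ct <- setdiff(ann$contig, names(contig_lengths))
  if (length(missing_ct) > 0) {
    stop("no length provided for contig(s): ",
         paste(missing_ct, collapse = ", "))
  }
  out <- function(class, idio, edge = FALSE, evidence = character(0)) {
    structure(list(class = class, idiomorph_present = idio,
                   edge_reassembled = edge, evidence = evidence,
                   annotations = ann),
              class = "mat_architecture")
  }
  dup <- tapply(ann$contig, ann$gene, function(x) length(unique(x)))
  if (any(dup > 1)) {
    warning("duplicated gene(s) on different contigs: ",
            paste(names(dup)[dup > 1], collapse = ", "))
    return(out("incomplete", character(0),
               evidence = "duplicated gene placements"))
  }
  have <- unique(ann$gene)
  idio <- c(if (any(have %in% .MAT1_GENES)) "mat1-1",
            if (any(have %in% .MAT2_GENES)) "mat1-2")
  flanks <- intersect(have, .FLANK_GENES)
  if (length(idio) == 0) {
    return(out("incomplete", idio, evidence = "no mat genes annotated"))
  }
  if (length(flanks) == 0) {
    return(out("incomplete", idio,
               evidence = "APN2 and SLA2 both missing"))
  }
  if (length(idio) == 1) {
    return(out("single_idiomorph", idio,
               evidence = sprintf("only the %s idiomorph is present",
                                  idio)))
  }
  mats <- ann[ann$gene %in% c(.MAT1_GENES, .MAT2_GENES), , drop = FALSE]
  apn2 <- ann[ann$gene == "APN2", , drop = FALSE]
  sla2 <- ann[ann$gene == "SLA2", , drop = FALSE]
  if (nrow(apn2) == 1 && nrow(sla2) == 1 &&
      apn2$contig == sla2$contig) {
    ct <- apn2$contig
    lo <- min(apn2$start, sla2$start)
    hi <- max(apn2$end, sla2$end)
    inside <- mats$contig == ct & mats$start >= lo & mats$end <= hi
    if (all(inside)) {
      return(out("fused", idio,
                 evidence = sprintf(
                   "all mat genes between APN2 and SLA2 on %s", ct)))
    }
    # one idiomorph flanked, the other elsewhere without flanks?
    flanked_mat1 <- all(inside[mats$gene %in% .MAT1_GENES])
    flanked_mat2 <- all(inside[mats$gene %in% .MAT2_GENES])
    orphan <- mats[!inside, , drop = FALSE]
    orphan_clean <- !any(orphan$contig %in% c(apn2$contig, sla2$contig))
    if (xor(flanked_mat1, flanked_mat2) && orphan_clean) {
      return(out("split_unlinked", idio,
                 evidence = sprintf(
                   "%s idiomorph flanked by APN2/SLA2 on %s; %s on %s without flanks",
                   if (flanked_mat1) "mat1-1" else "mat1-2", ct,
                   paste(unique(orphan$gene), collapse = ","),
                   paste(unique(orphan$contig), collapse = ","))))
    }
    return(out("incomplete", idio,
               evidence = "mat genes outside the APN2/SLA2 span"))
  }
  if (attempt_reassembly) {
    join <- attempt_edge_reassembly(ann, contig_lengths, edge_distance)
    if (join$success) {
      return(out("fused", idio, edge = TRUE, evidence = join$evidence))
    }
  }
  out("incomplete", idio,
      evidence = "flanks on different contigs and no edge reassembly")
}

#' @export
print.mat_architecture <- function(x, ...) {
  cat(sprintf("MAT locus architecture: %s%s\n", x$class,
              if (x$edge_reassembled) " (edge-reassembled)" else ""))
  cat("  idiomorphs present:",
      if (length(x$idiomorph_present)) {
        paste(x$idiomorph_present, collapse = ", ")
      } else "none", "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Map a classification back to the fixture architecture label
#'
#' Inverse of [build_mat_fixture()] for recovery testing: a fused class
#' reached through edge reassembly maps to `split_edge_reassemblable`, a
#' single idiomorph to `single_mat1-1`/`single_mat1-2`.
#'
#' @param architecture a `mat_architecture`.
#' @return one of [mat_fixture_architectures()], or `NA` for classes with
#'   no fixture counterpart.
#' @export
architecture_fixture_label <- function(architecture) {
  stopifnot(inherits(architecture, "mat_architecture"))
  switch(architecture$class,
         fused = if (architecture$edge_reassembled) {
           "split_edge_reassemblable"
         } else "fused",
         split_unlinked = "split_unlinked",
         single_idiomorph = paste0("single_",
                                   architecture$idiomorph_present[1]),
         NA_character_)
}

#' Coverage-ratio test for heterokaryosis at the MAT locus
#'
#' Compares read coverage (reads/kbp) of the flanking single-copy genes
#' (APN2, SLA2) with the mat genes. In a homokaryon all six genes are
#' single-copy and the ratio is near 1; in a mat1-1/mat1-2 heterokaryon
#' the flanks carry the summed coverage of both nuclear classes and the
#' ratio approaches 2. The verdict is `elevated_flank` only when the
#' elevation is both practically large (ratio at least `fold_threshold`)
#' and statistically supported (one-sided two-sample Poisson rate test,
#' flank rate greater than mat rate, significant at `alpha`);
#' `equal_coverage` when neither criterion fires; `undetermined` when the
#' two disagree. Pseudogenes can be excluded from the mat mean via
#' `exclude` since they may diverge in mappability.
#'
#' @param coverage data.frame with columns `gene` and `reads_per_kbp`
#'   (optionally `length_bp`, used as Poisson exposure; 1 kbp assumed
#'   otherwise).
#' @param fold_threshold practical-equivalence fold cut, default 1.5.
#' @param alpha significance level of the rate test.
#' @param exclude genes excluded from the mat-gene mean (e.g. pseudogenic
#'   mat1-1-3).
#' @return a `coverage_test` object: `flank_mat_ratio`, `p_value`,
#'   `verdict` (`equal_coverage`, `elevated_flank` or `undetermined`).
#' @export
coverage_ratio_test <- function(coverage, fold_threshold = 1.5,
                                alpha = 0.05, exclude = character(0)) {
  stopifnot(is.data.frame(coverage),
            all(c("gene", "reads_per_kbp") %in% names(coverage)))
  cov <- coverage
  cov$gene <- .norm_genes(cov$gene)
  cov <- cov[!is.na(cov$gene), , drop = FALSE]
  flank <- cov[cov$gene %in% .FLANK_GENES, , drop = FALSE]
  mats <- cov[cov$gene %in% c(.MAT1_GENES, .MAT2_GENES) &
                !cov$gene %in% .norm_genes(exclude), , drop = FALSE]
  if (nrow(flank) == 0 || nrow(mats) == 0) {
    stop("need coverage for at least one flanking and one mat gene")
  }
  if (all(mats$reads_per_kbp == 0)) {
    return(structure(list(
      flank_mat_ratio = NA_real_, p_value = NA_real_,
      verdict = "undetermined",
      evidence = "mat genes have zero coverage; ratio undefined"),
      class = "coverage_test"))
  }
  kbp <- function(d) {
    if ("length_bp" %in% names(d)) d$length_bp / 1000 else rep(1, nrow(d))
  }
  fk <- kbp(flank); mk <- kbp(mats)
  ratio <- mean(flank$reads_per_kbp) / mean(mats$reads_per_kbp)
  pt <- stats::poisson.test(
    c(round(sum(flank$reads_per_kbp * fk)),
      round(sum(mats$reads_per_kbp * mk))),
    T = c(sum(fk), sum(mk)), alternative = "greater")
  verdict <- if (ratio >= fold_threshold && pt$p.value < alpha) {
    "elevated_flank"
  } else if (ratio < fold_threshold && pt$p.value >= alpha) {
    "equal_coverage"
  } else {
    "undetermined"  # fold and test disagree; no confident call
  }
  structure(list(
    flank_mat_ratio = ratio, p_value = pt$p.value, verdict = verdict,
    evidence = sprintf(
      "mean flank %.1f vs mean mat %.1f reads/kbp (ratio %.2f, one-sided Poisson p = %.3g)",
      mean(flank$reads_per_kbp), mean(mats$reads_per_kbp), ratio,
      pt$p.value)), class = "coverage_test")
}

#' @export
print.coverage_test <- function(x, ...) {
  cat("Coverage-ratio test:", x$verdict, "\n")
  cat(" ", x$evidence, "\n")
  invisible(x)
}

#' Infer the breeding system from locus architecture and coverage
#'
#' Decision rules: a fused locus implies homothallism. An unlinked split
#' locus is homothallic when flank and mat coverage are equal (all genes
#' single-copy) and likely heterothallic when the flanks show elevated
#' coverage (heterokaryon signature); without a usable coverage verdict it
#' stays undetermined. A single idiomorph suggests heterothallism with
#' loss of one mating type, but observed (even partial) fertility of
#' single-spore isolates leaves single-mating-type reproduction open and
#' downgrades the call to `single_mating_type_unresolved`. Incomplete
#' architectures are undetermined.
#'
#' @param architecture a `mat_architecture`.
#' @param coverage_verdict a `coverage_test`, one of its verdict strings,
#'   or `NULL` when no coverage is available.
#' @param fertility_observed optional flag: did single-spore isolates show
#'   (possibly partial) sexual development?
#' @return a `breeding_call` object: `call`, `flank_mat_ratio`,
#'   `test_pvalue`, `evidence`.
#' @export
infer_breeding_system <- function(architecture, coverage_verdict = NULL,
                                  fertility_observed = NA) {
  stopifnot(inherits(architecture, "mat_architecture"))
  ratio <- NA_real_; pval <- NA_real_
  if (inherits(coverage_verdict, "coverage_test")) {
    ratio <- coverage_verdict$flank_mat_ratio
    pval <- coverage_verdict$p_value
    coverage_verdict <- coverage_verdict$verdict
  }
  if (!is.null(coverage_verdict)) {
    coverage_verdict <- match.arg(coverage_verdict,
                                  c("equal_coverage", "elevated_flank",
                                    "undetermined"))
  }
  ev <- character(0)
  call <- switch(
    architecture$class,
    fused = {
      ev <- c(ev, "fused APN2--mat--SLA2 locus carries both idiomorphs")
      "homothallic"
    },
    split_unlinked = {
      if (identical(coverage_verdict, "equal_coverage")) {
        ev <- c(ev, "unlinked idiomorphs with equal flank/mat coverage: all six genes single-copy")
        "homothallic"
      } else if (identical(coverage_verdict, "elevated_flank")) {
        ev <- c(ev, "flank coverage exceeds mat coverage: heterokaryon signature")
        "heterothallic_likely"
      } else {
        ev <- c(ev, "unlinked idiomorphs but no usable coverage evidence")
        "undetermined"
      }
    },
    single_idiomorph = {
      if (isTRUE(fertility_observed)) {
        ev <- c(ev, "single idiomorph yet sexual development observed; single-mating-type reproduction cannot be excluded")
        "single_mating_type_unresolved"
      } else {
        ev <- c(ev, "single idiomorph present: heterothallism with loss of one mating type is the best explanation")
        "heterothallic_likely"
      }
    },
    {
      ev <- c(ev, "architecture incomplete; no call possible")
      "undetermined"
    })
  structure(list(call = call, flank_mat_ratio = ratio,
                 test_pvalue = pval,
                 evidence = c(ev, architecture$evidence)),
            class = "breeding_call")
}

#' @export
print.breeding_call <- function(x, ...) {
  cat("Breeding-system call:", x$call, "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Full MAT-locus report for one strain
#'
#' Chains architecture classification, the coverage-ratio test (when a
#' coverage table is supplied) and the breeding-system inference.
#'
#' @param annotations annotation data.frame or path readable by
#'   [read_annotations()].
#' @param contig_lengths named vector of contig lengths.
#' @param coverage optional coverage data.frame or TSV path.
#' @param fertility_observed optional fertility flag.
#' @param strain strain label for the report.
#' @param edge_distance passed to [classify_architecture()].
#' @param exclude_pseudogenes exclude annotated pseudogenes from the
#'   coverage mat-gene mean.
#' @return a `mat_locus_report` object.
#' @export
mat_locus_report <- function(annotations, contig_lengths, coverage = NULL,
                             fertility_observed = NA, strain = "strain",
                             edge_distance = 2000,
                             exclude_pseudogenes = TRUE) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(coverage)) coverage <- read_coverage_tsv(coverage)
  arch <- classify_architecture(annotations, contig_lengths, edge_distance)
  covtest <- NULL
  if (!is.null(coverage)) {
    excl <- if (exclude_pseudogenes && "pseudogene" %in% names(annotations)) {
      annotations$gene[annotations$pseudogene %in% TRUE]
    } else character(0)
    covtest <- coverage_ratio_test(coverage, exclude = excl)
  }
  call <- infer_breeding_system(arch, covtest, fertility_observed)
  structure(list(strain = strain, architecture = arch,
                 coverage_test = covtest, breeding_call = call,
                 fertility_observed = fertility_observed,
                 edge_distance = edge_distance),
            class = "mat_locus_report")
}

#' @export
print.mat_locus_report <- function(x, ...) {
  cat("== MAT locus report:", x$strain, "==\n")
  print(x$architecture)
  if (!is.null(x$coverage_test)) print(x$coverage_test)
  print(x$breeding_call)
  invisible(x)
}

#' Write a MAT-locus report as JSON plus a one-line TSV summary
#' @param report a `mat_locus_report`.
#' @param json_path JSON output file.
#' @param tsv_path optional TSV output file.
#' @export
write_mat_report <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "mat_locus_report"))
  x <- list(
    strain = report$strain,
    architecture = list(
      class = report$architecture$class,
      idiomorph_present = report$architecture$idiomorph_present,
      edge_reassembled = report$architecture$edge_reassembled,
      evidence = report$architecture$evidence),
    coverage_test = if (!is.null(report$coverage_test)) {
      list(flank_mat_ratio = report$coverage_test$flank_mat_ratio,
           p_value = report$coverage_test$p_value,
           verdict = report$coverage_test$verdict)
    },
    breeding_call = list(call = report$breeding_call$call,
                         evidence = report$breeding_call$evidence),
    fertility_observed = report$fertility_observed,
    edge_distance = report$edge_distance)
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  if (!is.null(tsv_path)) {
    row <- data.frame(
      strain = report$strain,
      architecture = report$architecture$class,
      idiomorphs = paste(report$architecture$idiomorph_present,
                         collapse = "+"),
      edge_reassembled = report$architecture$edge_reassembled,
      coverage_verdict = if (is.null(report$coverage_test)) "NA" else
        report$coverage_test$verdict,
      breeding_call = report$breeding_call$call,
      stringsAsFactors = FALSE)
    utils::write.table(row, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
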