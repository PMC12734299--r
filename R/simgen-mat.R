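# Mating-type locus fixtures. In Sordariales the MAT locus sits between
# the conserved single-copy genes APN2 and SLA2; homothallic strains carry
# the mat1-1 idiomorph genes (mat1-1-1, mat1-1-2, mat1-1-3) and the mat1-2
# idiomorph gene (mat1-2-1) together in that span. The fixture generator
# lays out the five locus architectures that assemblies of such strains
# can show, with randomized spacers, strands and gene order, so the
# classifier can be validated against known truth.

#' The fixed MAT-region gene vocabulary
#' @return character vector of the six gene symbols.
#' @export
mat_gene_vocabulary <- function() {
  c("APN2", "SLA2", "mat1-1-1", "mat1-1-2", "mat1-1-3", "mat1-2-1")
}

.MAT1_GENES <- c("mat1-1-1", "mat1-1-2", "mat1-1-3")
.MAT2_GENES <- "mat1-2-1"
.FLANK_GENES <- c("APN2", "SLA2")

# typical gene lengths (bp) used by the fixture and coverage simulators
.mat_gene_lengths <- function() {
  c("APN2" = 1500L, "SLA2" = 3000L, "mat1-1-1" = 1100L,
    "mat1-1-2" = 1200L, "mat1-1-3" = 550L, "mat1-2-1" = 800L)
}

#' The five MAT-locus fixture architectures
#' @return character vector of architecture labels accepted by
#'   [build_mat_fixture()].
#' @export
mat_fixture_architectures <- function() {
  c("fused", "split_unlinked", "split_edge_reassemblable",
    "single_mat1-1", "single_mat1-2")
}

# lay genes on one contig in the given order with random spacers;
# left_pad/right_pad are exact pad lengths before/after the cluster
.layout_contig <- function(contig, genes, left_pad, right_pad,
                           spacer_range = c(200L, 1500L)) {
  lens <- .mat_gene_lengths()[genes]
  n <- length(genes)
  spacers <- if (n > 1) {
    sample(spacer_range[1]:spacer_range[2], n - 1, replace = TRUE)
  } else integer(0)
  starts <- integer(n)
  pos <- left_pad
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    starts[k] <- pos
    rows[[k]] <- data.frame(
      gene = genes[k], contig = contig,
      start = pos, end = pos + lens[[k]],
      strand = sample(c("+", "-"), 1), pseudogene = FALSE,
      stringsAsFactors = FALSE)
    pos <- pos + lens[[k]] + if (k < n) spacers[k] else 0L
  }
  list(annotations = do.call(rbind, rows),
       length = pos + right_pad)
}

#' Build a MAT-locus fixture genome
#'
#' Generates a small random genome plus gene annotations realizing one of
#' five locus architectures: `fused` (both idiomorphs between APN2 and
#' SLA2 on one contig), `split_unlinked` (both idiomorphs present, one
#' flanked, the other on its own contig without flanks),
#' `split_edge_reassemblable` (the locus split over two contigs with the
#' mat genes at contig edges, so the fused structure can be recovered),
#' `single_mat1-1` and `single_mat1-2` (a single idiomorph between the
#' flanks). Gene order within the cluster and strands are randomized.
#'
#' @param architecture one of [mat_fixture_architectures()].
#' @param edge_distance for the edge-reassemblable architecture, maximum
#'   distance (bp) between the split cluster and the contig end; the
#'   fixture places the gap in `[10, 0.8 * edge_distance]`.
#' @param pseudogenize_mat113 mark mat1-1-3 as a pseudogene (observed in
#'   several Sordariales assemblies).
#' @param seed integer seed.
#' @return list with elements `genome`, `annotations` (data.frame: gene,
#'   contig, start, end, strand, pseudogene; 0-based half-open),
#'   `architecture`.
#' @export
build_mat_fixture <- function(architecture, edge_distance = 2000,
                              pseudogenize_mat113 = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (!architecture %in% mat_fixture_architectures()) {
    stop("unknown architecture '", architecture, "'; must be one of: ",
         paste(mat_fixture_architectures(), collapse = ", "))
  }
  set.seed(as.integer(seed))
  pad <- function() sample(2000:5000, 1)
  layouts <- list()
  if (architecture == "fused") {
    genes <- c("APN2", sample(c(.MAT1_GENES, .MAT2_GENES)), "SLA2")
    layouts$contig_mat <- .layout_contig("contig_mat", genes, pad(), pad())
  } else if (architecture %in% c("single_mat1-1", "single_mat1-2")) {
    idio <- if (architecture == "single_mat1-1") sample(.MAT1_GENES)
            else .MAT2_GENES
    layouts$contig_mat <- .layout_contig("contig_mat",
                                         c("APN2", idio, "SLA2"),
                                         pad(), pad())
  } else if (architecture == "split_unlinked") {
    flanked <- sample(c("mat1-1", "mat1-2"), 1)
    if (flanked == "mat1-1") {
      inner <- sample(.MAT1_GENES); orphan <- .MAT2_GENES
    } else {
      inner <- .MAT2_GENES; orphan <- sample(.MAT1_GENES)
    }
    layouts$contig_mat <- .layout_contig("contig_mat",
                                         c("APN2", inner, "SLA2"),
                                         pad(), pad())
    # orphan idiomorph mid-contig, well away from both ends
    far <- edge_distance + sample(3000:6000, 1)
    layouts$contig_orphan <- .layout_contig("contig_orphan", orphan,
                                            far, edge_distance +
                                              sample(3000:6000, 1))
  } else { # split_edge_reassemblable
    cluster <- sample(c(.MAT1_GENES, .MAT2_GENES))
    k <- sample(1:3, 1)
    gap <- function() sample(10:max(10L, floor(0.8 * edge_distance)), 1)
    # contig 1: pad APN2 [cluster 1..k] <gap> | end
    layouts$contig_apn2 <- .layout_contig(
      "contig_apn2", c("APN2", cluster[seq_len(k)]), pad(), gap())
    # contig 2: | <gap> [cluster k+1..4] SLA2 pad
    layouts$contig_sla2 <- .layout_contig(
      "contig_sla2", c(cluster[(k + 1):4], "SLA2"), gap(), pad())
  }
  ann <- do.call(rbind, lapply(layouts, `[[`, "annotations"))
  rownames(ann) <- NULL
  if (pseudogenize_mat113 && "mat1-1-3" %in% ann$gene) {
    ann$pseudogene[ann$gene == "mat1-1-3"] <- TRUE
  }
  contigs <- vapply(layouts, function(l) {
    .int_to_seq(sample.int(4L, l$length, replace = TRUE))
  }, character(1))
  names(contigs) <- vapply(layouts, function(l) l$annotations$contig[1],
                           character(1))
  list(genome = genome(contigs, id = paste0("matfix_", architecture)),
       annotations = ann, architecture = architecture)
}

#' Coverage-simulation parameters
#'
#' @param mean_depth expected coverage (reads/kbp) of single-copy genes.
#' @param nuclear_ratio proportion of mat1-1 nuclei in a heterokaryotic
#'   mycelium, in `[0, 1]`.
#' @param gene_lengths named vector of gene lengths in bp; defaults to the
#'   package's typical MAT-region gene lengths.
#' @param seed integer seed.
#' @export
coverage_sim_params <- function(mean_depth, nuclear_ratio = 0.5,
                                gene_lengths = .mat_gene_lengths(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (nuclear_ratio < 0 || nuclear_ratio > 1) {
    stop("nuclear_ratio must be in [0, 1]")
  }
  if (any(gene_lengths <= 0)) stop("all gene lengths must be positive")
  structure(list(mean_depth = mean_depth, nuclear_ratio = nuclear_ratio,
                 gene_lengths = gene_lengths, seed = as.integer(seed)),
            class = "coverage_sim_params")
}

#' Simulate per-gene read coverage
#'
#' Homokaryotic mycelia carry one nuclear genotype: every gene has
#' expectation `mean_depth` reads/kbp. In a mat1-1/mat1-2 heterokaryon the
#' idiomorphs are carried by different nuclei: flanking single-copy genes
#' keep expectation `mean_depth`, mat1-1 genes get `nuclear_ratio *
#' mean_depth` and mat1-2 genes `(1 - nuclear_ratio) * mean_depth`. Read
#' counts per gene are Poisson with mean `expectation * length_kbp`,
#' rescaled to reads/kbp.
#'
#' @param params a [coverage_sim_params()] object.
#' @param karyotype `"homokaryon"` or `"heterokaryon"`.
#' @return data.frame with columns `gene`, `length_bp`, `reads_per_kbp`.
#' @export
simulate_gene_coverage <- function(params,
                                   karyotype = c("homokaryon",
                                                 "heterokaryon")) {
  stopifnot(inherits(params, "coverage_sim_params"))
  karyotype <- match.arg(karyotype)
  set.seed(params$seed)
  genes <- names(params$gene_lengths)
  expect <- rep(params$mean_depth, length(genes))
  if (karyotype == "heterokaryon") {
    expect[genes %in% .MAT1_GENES] <- params$nuclear_ratio * params$mean_depth
    expect[genes %in% .MAT2_GENES] <- (1 - params$nuclear_ratio) *
      params$mean_depth
  }
  kbp <- params$gene_lengths / 1000
  counts <- rpois(length(genes), lambda = expect * kbp)
  data.frame(gene = genes, length_bp = as.integer(params$gene_lengths),
             reads_per_kbp = counts / kbp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write gene annotations as a 5-column TSV
#'
#' Columns: gene, contig, start, end, strand (0-based, half-open).
#' @param annotations annotation data.frame.
#' @param path output file.
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "contig", "start", "end",
                                     "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene annotations as GFF3
#'
#' Pseudogene status is recorded in the `pseudo` attribute.
#' @inheritParams write_annotations_tsv
#' @export
write_annotations_gff3 <- function(annotations, path) {
  pseudo <- if ("pseudogene" %in% names(annotations)) {
    annotations$pseudogene %in% TRUE
  } else rep(FALSE, nrow(annotations))
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "anidelim"
  S4Vectors::mcols(gr)$ID <- gsub("[^A-Za-z0-9._-]", "_", annotations$gene)
  S4Vectors::mcols(gr)$Name <- annotations$gene
  S4Vectors::mcols(gr)$pseudo <- ifelse(pseudo, "true", NA_character_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3 or 5-column TSV
#'
#' The format is detected from the `##gff-version` header line. TSV input
#' must carry the header `gene contig start end strand` with 0-based
#' half-open coordinates; GFF3 coordinates are converted from 1-based
#' closed to 0-based half-open.
#'
#' @param path annotation file.
#' @return annotation data.frame (gene, contig, start, end, strand,
#'   pseudogene).
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##gff-version")) {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    gene <- if ("Name" %in% names(mc)) as.character(mc$Name) else
      as.character(mc$ID)
    pseudo <- if ("pseudo" %in% names(mc)) {
      !is.na(mc$pseudo) & mc$pseudo == "true"
    } else rep(FALSE, length(gr))
    data.frame(
      gene = gene,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      pseudogene = pseudo,
      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "contig", "start", "end", "strand") %in%
                    names(ann)))
    ann$pseudogene <- if ("pseudogene" %in% names(ann)) {
      as.logical(ann$pseudogene)
    } else FALSE
    ann[, c("gene", "contig", "start", "end", "strand", "pseudogene")]
  }
}

#' Write a per-gene coverage table (2-column TSV)
#' @param coverage data.frame with columns `gene` and `reads_per_kbp`.
#' @param path output file.
#' @export
write_coverage_tsv <- function(coverage, path) {
  utils::write.table(coverage[, c("gene", "reads_per_kbp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene coverage table
#' @param path TSV with columns `gene` and `reads_per_kbp`.
#' @export
read_coverage_tsv <- function(path) {
  cov <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "reads_per_kbp") %in% names(cov)))
  cov
}
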