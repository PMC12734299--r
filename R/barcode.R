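# ITS/LSU barcode extraction and difference counting. Barcodes are located
# in an assembly by local alignment of a reference barcode against all
# contigs (both strands); pairwise differences are counted from a global
# alignment in the "N differences out of M aligned nucleotides" idiom:
# aligned nucleotides are columns where both sequences carry a base,
# substitutions are the mismatching ones, and indel columns are reported
# separately. IUPAC-compatible pairs (e.g. A vs R) count as identity, as
# Sanger-derived reference barcodes routinely contain ambiguity codes.

# substitution matrix over the IUPAC alphabet: match when the base sets
# intersect, mismatch otherwise
.iupac_submat <- function(match = 1, mismatch = -2) {
  codes <- Biostrings::IUPAC_CODE_MAP
  letters <- names(codes)
  sets <- strsplit(codes, "")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (i in seq_along(letters)) {
    for (j in seq_along(letters)) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0) m[i, j] <- match
    }
  }
  m
}

.iupac_compatible <- function(a, b) {
  codes <- Biostrings::IUPAC_CODE_MAP
  sa <- strsplit(codes[a], "")
  sb <- strsplit(codes[b], "")
  mapply(function(x, y) length(intersect(x, y)) > 0, sa, sb,
         USE.NAMES = FALSE)
}

# column scan shared by align_and_count(); aligned strings must be equal
# length and gapped with "-"
.count_alignment_columns <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  gap_a <- a == "-"
  gap_b <- b == "-"
  both <- !gap_a & !gap_b
  compat <- logical(sum(both))
  if (any(both)) compat <- .iupac_compatible(a[both], b[both])
  n_aligned <- sum(both)
  n_sub <- sum(!compat)
  n_indel <- sum(xor(gap_a, gap_b))
  list(n_aligned = n_aligned, n_substitutions = n_sub,
       n_indel_columns = n_indel)
}

#' Count pairwise differences between two barcode sequences
#'
#' Globally aligns the two sequences with affine gap penalties and counts:
#' `n_aligned`, the columns where both sequences carry a base;
#' `n_substitutions`, the mismatching such columns (IUPAC-compatible pairs
#' are not differences); `n_indel_columns`, columns with a gap in exactly
#' one sequence. The summary string follows the "N differences out of M
#' aligned nucleotides" idiom.
#'
#' @param seq_a,seq_b nucleotide sequences (character or `DNAString`),
#'   length >= 50.
#' @param match,mismatch,gap_open,gap_ext alignment scoring; counts near
#'   alignment ties can shift by one under different scoring, so the
#'   parameters are explicit.
#' @return a `pairwise_diff` object.
#' @export
align_and_count <- function(seq_a, seq_b, match = 1, mismatch = -2,
                            gap_open = 5, gap_ext = 1) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) < 50 || nchar(b) < 50) {
    stop("both sequences must be at least 50 bp")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .iupac_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  counts <- .count_alignment_columns(al_a, al_b)
  structure(c(counts, list(
    summary_text = sprintf("%d differences out of %d aligned nucleotides",
                           counts$n_substitutions, counts$n_aligned),
    aligned_a = al_a, aligned_b = al_b, score = Biostrings::score(pa)
  )), class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat(x$summary_text, "\n")
  cat(sprintf("  (plus %d indel columns)\n", x$n_indel_columns))
  invisible(x)
}

#' Extract a barcode region from an assembly
#'
#' Locates the best local alignment of a reference barcode (ITS, LSU or
#' combined ITS+LSU) against all contigs of the genome, both strands, and
#' extracts the aligned subject interval. The returned sequence is
#' reported in the reference orientation (reverse-complemented for
#' minus-strand hits).
#'
#' @param x a genome.
#' @param reference reference barcode (character or `DNAString`), length
#'   >= 100.
#' @param min_identity minimum percent identity of the best alignment;
#'   below it the barcode is treated as absent and an error is raised.
#' @param config an [ani_config()] supplying alignment scoring.
#' @return an `extracted_barcode` object with fields `source_id`,
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `sequence`,
#'   `identity_to_reference`.
#' @export
extract_barcode <- function(x, reference, min_identity = 75,
                            config = ani_config()) {
  ref <- toupper(as.character(reference))
  if (nchar(ref) < 100) stop("reference barcode must be at least 100 bp")
  q <- Biostrings::DNAStringSet(ref)
  names(q) <- "reference"
  hits <- .blast_best_hits(q, x, reward = config$reward,
                           penalty = config$penalty,
                           gap_open = config$gap_open,
                           gap_ext = config$gap_ext,
                           task = config$task, evalue = config$evalue)
  qlen <- nchar(ref)
  if (nrow(hits) > 0) {
    af <- (abs(hits$qend[1] - hits$qstart[1]) + 1) / qlen
  }
  if (nrow(hits) == 0 || hits$pident[1] < min_identity || af < 0.5) {
    stop("barcode not found in ", genome_id(x),
         ": no region with identity >= ", min_identity,
         "% covering at least half the reference ",
         "(the assembly may lack the rDNA cassette)")
  }
  h <- hits[1, ]
  lo <- min(h$sstart, h$send) - 1L  # 0-based half-open
  hi <- max(h$sstart, h$send)
  span <- Biostrings::subseq(x[[h$sseqid]], lo + 1L, hi)
  if (h$strand == "-") span <- Biostrings::reverseComplement(span)
  structure(list(
    source_id = genome_id(x), contig = h$sseqid,
    start = lo, end = hi, strand = h$strand,
    sequence = as.character(span),
    identity_to_reference = h$pident
  ), class = "extracted_barcode")
}

#' @export
print.extracted_barcode <- function(x, ...) {
  cat(sprintf("Barcode from %s: %s:%d-%d (%s), %.2f%% identity to reference\n",
              x$source_id, x$contig, x$start, x$end, x$strand,
              x$identity_to_reference))
  invisible(x)
}

#' Pairwise difference counts for a set of barcodes
#'
#' Computes [align_and_count()] for every unordered pair; the result is
#' symmetric with an all-zero diagonal.
#'
#' @param barcodes named character vector, named `DNAStringSet`, or list
#'   of `extracted_barcode` objects; at least two, with unique ids.
#' @param ... passed to [align_and_count()].
#' @return a `barcode_diff_matrix` object: `pairs` (long-format
#'   data.frame) plus symmetric matrices `substitutions`, `aligned`,
#'   `indel_columns`.
#' @export
batch_diff <- function(barcodes, ...) {
  if (is.list(barcodes) && all(vapply(barcodes, inherits, logical(1),
                                      "extracted_barcode"))) {
    ids <- vapply(barcodes, `[[`, character(1), "source_id")
    seqs <- vapply(barcodes, `[[`, character(1), "sequence")
    names(seqs) <- ids
    barcodes <- seqs
  }
  seqs <- stats::setNames(as.character(barcodes), names(barcodes))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("barcodes must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate barcode ids")
  n <- length(seqs)
  if (n < 2) stop("need at least two barcodes")
  ids <- names(seqs)
  subs <- matrix(0L, n, n, dimnames = list(ids, ids))
  alig <- matrix(0L, n, n, dimnames = list(ids, ids))
  indl <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(alig) <- nchar(seqs)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- align_and_count(seqs[i], seqs[j], ...)
      subs[i, j] <- subs[j, i] <- d$n_substitutions
      alig[i, j] <- alig[j, i] <- d$n_aligned
      indl[i, j] <- indl[j, i] <- d$n_indel_columns
      pairs[[length(pairs) + 1]] <- data.frame(
        id_a = ids[i], id_b = ids[j],
        n_substitutions = d$n_substitutions, n_aligned = d$n_aligned,
        n_indel_columns = d$n_indel_columns,
        summary_text = d$summary_text, stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, pairs), substitutions = subs,
                 aligned = alig, indel_columns = indl),
            class = "barcode_diff_matrix")
}

#' @export
print.barcode_diff_matrix <- function(x, ...) {
  cat("Pairwise barcode differences (substitutions):\n")
  print(x$substitutions)
  invisible(x)
}

#' Write pairwise barcode differences as TSV
#' @param x a `barcode_diff_matrix`.
#' @param path output file.
#' @export
write_diff_tsv <- function(x, path) {
  stopifnot(inherits(x, "barcode_diff_matrix"))
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write extracted barcodes as FASTA
#' @param barcodes list of `extracted_barcode` objects.
#' @param path output file.
#' @export
write_barcodes_fasta <- function(barcodes, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(barcodes, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(barcodes, function(b) {
    sprintf("%s %s:%d-%d(%s)", b$source_id, b$contig, b$start, b$end,
            b$strand)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Exact global alignment (dynamic programming)
#'
#' Needleman--Wunsch with affine gaps and IUPAC-aware matching (two
#' letters match when their base sets intersect). Terminal gaps are
#' penalized. Exposed for validation of alignment-derived counts.
#'
#' @param seq_a,seq_b sequences.
#' @param match,mismatch,gap_open,gap_ext scoring (defaults as in
#'   [align_and_count()]).
#' @return list with `score`, `aligned_a`, `aligned_b`.
#' @export
align_global_exact <- function(seq_a, seq_b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 1) {
  .nw_align_cpp(toupper(as.character(seq_a)), toupper(as.character(seq_b)),
                match, mismatch, gap_open, gap_ext, TRUE)
}
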