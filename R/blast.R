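# Thin wrapper around the NCBI BLAST+ command-line tools, which carry out
# the per-fragment local alignment step of the ANI engine and the barcode
# localization step. Scoring parameters are always passed explicitly so
# that results are reproducible and can be checked against the package's
# exact dynamic-programming aligner.

.require_blast <- function() {
  for (tool in c("blastn", "makeblastdb")) {
    if (Sys.which(tool) == "") {
      stop("NCBI BLAST+ tool '", tool, "' not found on the PATH; ",
           "it is required for alignment-based operations", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Best local alignment of each query sequence against all subject contigs,
# both strands. Returns one row per query that produced at least one HSP:
# qseqid, pident, length (alignment columns), nident, qstart, qend, sstart,
# send (1-based, sstart > send on the minus strand), bitscore, strand.
.blast_best_hits <- function(queries, subject, reward = 2, penalty = -3,
                             gap_open = 5, gap_ext = 2, task = "blastn",
                             evalue = 1e-4) {
  .require_blast()
  stopifnot(methods::is(queries, "DNAStringSet"), length(queries) > 0)
  wd <- tempfile("blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  qfa <- file.path(wd, "query.fa")
  sfa <- file.path(wd, "subject.fa")
  db <- file.path(wd, "subjectdb")
  out <- file.path(wd, "hits.tsv")
  Biostrings::writeXStringSet(queries, qfa)
  Biostrings::writeXStringSet(subject, sfa)
  status <- system2("makeblastdb",
                    c("-in", shQuote(sfa), "-dbtype", "nucl",
                      "-out", shQuote(db)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("makeblastdb failed")
  args <- c("-query", shQuote(qfa), "-db", shQuote(db),
            "-task", task,
            "-reward", reward, "-penalty", penalty,
            "-gapopen", gap_open, "-gapextend", gap_ext,
            "-evalue", format(evalue, scientific = TRUE),
            "-dust", "no", "-soft_masking", "false",
            "-num_threads", "1",
            "-outfmt", shQuote(paste("6 qseqid sseqid pident length nident",
                                     "qstart qend sstart send bitscore")),
            "-out", shQuote(out))
  status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn failed (exit status ", status, ")")
  cols <- c("qseqid", "sseqid", "pident", "length", "nident",
            "qstart", "qend", "sstart", "send", "bitscore")
  if (file.size(out) == 0) {
    hits <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    hits$qseqid <- character(0); hits$sseqid <- character(0)
    return(hits)
  }
  hits <- utils::read.delim(out, header = FALSE, col.names = cols,
                            colClasses = c("character", "character",
                                           rep("numeric", 8)))
  # best HSP per query: highest bitscore, ties broken by identity then
  # by input order (BLAST emits its own best-first ordering)
  o <- order(hits$qseqid, -hits$bitscore, -hits$pident)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  hits$strand <- ifelse(hits$sstart <= hits$send, "+", "-")
  rownames(hits) <- NULL
  hits
}
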