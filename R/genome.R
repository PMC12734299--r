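#' Construct a genome assembly object
#'
#' A genome is a named [Biostrings::DNAStringSet] of contigs with a strain
#' identifier attached. Sequences are uppercased on ingest; contig names
#' must be unique.
#'
#' @param contigs named character vector or `DNAStringSet` of contig
#'   sequences (alphabet A/C/G/T/N plus IUPAC ambiguity codes).
#' @param id strain label.
#' @return a `DNAStringSet` with metadata element `id`.
#' @export
genome <- function(contigs, id = "genome") {
  if (is.character(contigs)) {
    if (is.null(names(contigs))) {
      names(contigs) <- paste0("contig_", seq_along(contigs))
    }
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  if (!methods::is(contigs, "DNAStringSet")) {
    stop("`contigs` must be a character vector or a DNAStringSet")
  }
  if (length(contigs) < 1L) stop("a genome needs at least one contig")
  if (anyDuplicated(names(contigs))) stop("contig names must be unique")
  S4Vectors::metadata(contigs)$id <- id
  contigs
}

#' Strain identifier of a genome
#' @param x a genome (`DNAStringSet`).
#' @return the strain label, or `"genome"` when none was set.
#' @export
genome_id <- function(x) {
  id <- S4Vectors::metadata(x)$id
  if (is.null(id)) "genome" else id
}

#' Total genome length in bp
#' @param x a genome.
#' @export
genome_length <- function(x) sum(Biostrings::width(x))

#' Read a genome assembly from FASTA
#' @param path FASTA file.
#' @param id strain label; defaults to the file name without extension.
#' @export
read_genome <- function(path, id = sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                       basename(path))) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  genome(x, id = id)
}

#' Write a genome assembly to FASTA
#' @param x a genome.
#' @param path output file.
#' @export
write_genome <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# integer codes 1..4 = A,C,G,T used by the simulator
.BASES <- c("A", "C", "G", "T")

.seq_to_int <- function(s) {
  codes <- utf8ToInt(s)
  map <- integer(128)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("a")] <- 1L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("g")] <- 3L; map[utf8ToInt("t")] <- 4L
  out <- map[codes]
  if (any(out == 0L)) stop("sequence contains letters outside A/C/G/T")
  out
}

.int_to_seq <- function(v) {
  intToUtf8(utf8ToInt("ACGT") [v])
}
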