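# Fragment-based average nucleotide identity. The query genome is tiled
# into fixed-length fragments; each fragment is aligned locally against
# the whole subject assembly (both strands) and the best alignment's
# identity (matches / alignment columns, gap columns counting as
# mismatches) is recorded. ANI is the unweighted mean identity over hit
# fragments; fragments with no acceptable alignment ("zero hits") measure
# the specific-sequence fraction; the per-fragment identity histogram is
# the diagnostic spectrum on which the species-delimitation exception rule
# operates.

#' Configuration for the ANI engine
#'
#' Defaults follow the common fragment-ANI convention: non-overlapping
#' 1 kb fragments, a hit requiring at least half the fragment aligned at
#' >= 70% identity. Alignment scoring (reward 2, penalty -3, gap open 5,
#' gap extend 2) is passed explicitly to the aligner so runs are exactly
#' reproducible.
#'
#' @param window_bp fragment window, bp.
#' @param step_bp tiling step, bp; equal to `window_bp` gives
#'   non-overlapping fragments.
#' @param min_fragment_length trailing fragments shorter than this are
#'   discarded.
#' @param max_n_fraction fragments with more than this fraction of N are
#'   masked and excluded from the fragment count (reported separately).
#' @param min_identity minimum percent identity for a hit.
#' @param min_aligned_fraction minimum fraction of the fragment covered by
#'   the alignment for a hit.
#' @param reward,penalty,gap_open,gap_ext nucleotide alignment scoring.
#' @param task blastn task (`"blastn"` is sensitive down to the 70%
#'   identity hit floor; `"megablast"` is faster for close genomes).
#' @param evalue E-value cutoff passed to the aligner.
#' @param bin_edges identity histogram bin edges (percent), strictly
#'   increasing, last edge 100; bins are half-open `[lo, hi)` with the top
#'   bin closed.
#' @param high_id_cut identity cut (percent) defining the high-identity
#'   fraction of the spectrum.
#' @param divergent_band percent interval `[lo, hi)` defining the
#'   divergent band of the spectrum.
#' @return an `ani_config` list.
#' @export
ani_config <- function(window_bp = 1000, step_bp = 1000,
                       min_fragment_length = 500, max_n_fraction = 0.5,
                       min_identity = 70, min_aligned_fraction = 0.5,
                       reward = 2, penalty = -3, gap_open = 5, gap_ext = 2,
                       task = c("blastn", "megablast"), evalue = 1e-4,
                       bin_edges = c(70, 75, 80, 85, 90, 95, 97, 99,
                                     99.5, 100),
                       high_id_cut = 99.5, divergent_band = c(85, 90)) {
  task <- match.arg(task)
  if (min_fragment_length < 100) stop("min_fragment_length must be >= 100")
  if (window_bp < min_fragment_length) {
    stop("window_bp must be >= min_fragment_length")
  }
  if (step_bp < 1) stop("step_bp must be >= 1")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (bin_edges[length(bin_edges)] != 100) stop("last bin edge must be 100")
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 min_fragment_length = as.integer(min_fragment_length),
                 max_n_fraction = max_n_fraction,
                 min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 reward = reward, penalty = penalty,
                 gap_open = gap_open, gap_ext = gap_ext,
                 task = task, evalue = evalue,
                 bin_edges = bin_edges, high_id_cut = high_id_cut,
                 divergent_band = divergent_band),
            class = "ani_config")
}

#' Tile a genome into fragments
#'
#' Fragments are laid per contig from position 0 with the given step;
#' trailing fragments shorter than `min_fragment_length` are discarded.
#' Fragments whose N fraction exceeds `max_n_fraction` are flagged as
#' masked: they are excluded from the fragment count used by ANI and the
#' specific-sequence fraction and reported separately.
#'
#' @param x a genome.
#' @param window_bp,step_bp,min_fragment_length,max_n_fraction see
#'   [ani_config()].
#' @return data.frame with columns `contig`, `start` (0-based), `length`,
#'   `masked`.
#' @export
fragment_genome <- function(x, window_bp = 1000, step_bp = 1000,
                            min_fragment_length = 500,
                            max_n_fraction = 0.5) {
  if (genome_length(x) == 0) stop("empty genome")
  out <- lapply(names(x), function(ct) {
    clen <- Biostrings::width(x)[match(ct, names(x))]
    starts <- seq.int(1L, clen, by = step_bp)
    lens <- pmin(window_bp, clen - starts + 1L)
    keep <- lens >= min_fragment_length
    starts <- starts[keep]; lens <- lens[keep]
    if (length(starts) == 0) return(NULL)
    v <- Biostrings::Views(x[[ct]], start = starts, width = lens)
    n_count <- Biostrings::letterFrequency(v, "N")[, 1]
    data.frame(contig = ct, start = starts - 1L, length = lens,
               masked = n_count / lens > max_n_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      length = integer(0), masked = logical(0))
  }
  rownames(out) <- NULL
  out
}

# extract fragment sequences as a DNAStringSet named frag_<i>
.fragment_seqs <- function(x, fragments) {
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(fragments)),
    function(i) {
      Biostrings::subseq(x[[fragments$contig[i]]],
                         fragments$start[i] + 1L,
                         fragments$start[i] + fragments$length[i])
    }))
  names(seqs) <- sprintf("frag_%d", seq_len(nrow(fragments)))
  seqs
}

#' Identity histogram of fragment hits
#'
#' Each identity is assigned to exactly one half-open bin `[lo, hi)`; the
#' top bin is closed at 100. Zero-hit fragments are carried alongside so
#' that `sum(counts) + zero_hits` equals the number of (unmasked)
#' fragments.
#'
#' @param identities numeric vector of hit identities (percent).
#' @param bin_edges strictly increasing edges, last edge 100.
#' @param zero_hits number of zero-hit fragments.
#' @return an `identity_histogram` object.
#' @export
identity_histogram <- function(identities,
                               bin_edges = c(70, 75, 80, 85, 90, 95, 97,
                                             99, 99.5, 100),
                               zero_hits = 0) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (bin_edges[length(bin_edges)] != 100) stop("last bin edge must be 100")
  identities <- identities[!is.na(identities)]
  if (any(identities < 0 | identities > 100)) {
    stop("identities must lie in [0, 100]")
  }
  if (any(identities < bin_edges[1])) {
    stop("identity below the first bin edge (", bin_edges[1], ")")
  }
  k <- length(bin_edges) - 1L
  idx <- pmin(findInterval(identities, bin_edges), k)
  counts <- tabulate(idx, nbins = k)
  structure(list(bin_edges = bin_edges, counts = counts,
                 zero_hits = as.integer(zero_hits)),
            class = "identity_histogram")
}

#' @export
print.identity_histogram <- function(x, ...) {
  k <- length(x$bin_edges) - 1L
  lab <- sprintf("[%g, %g%s", x$bin_edges[-length(x$bin_edges)],
                 x$bin_edges[-1], c(rep(")", k - 1L), "]"))
  cat("Identity histogram\n")
  for (i in seq_len(k)) cat(sprintf("  %-12s %d\n", lab[i], x$counts[i]))
  cat(sprintf("  zero hits    %d\n", x$zero_hits))
  invisible(x)
}

#' Best local-alignment identity of a single fragment
#'
#' Aligns one fragment against all subject contigs, both strands, and
#' applies the hit criteria. A zero-hit outcome is valid and returned with
#' `hit = FALSE`.
#'
#' @param fragment_seq fragment sequence (character or `DNAString`).
#' @param subject subject genome.
#' @param config an [ani_config()].
#' @return list with elements `hit`, `identity_percent` (NA on zero-hit),
#'   `aligned_fraction`.
#' @export
best_fragment_identity <- function(fragment_seq, subject,
                                   config = ani_config()) {
  q <- Biostrings::DNAStringSet(as.character(fragment_seq))
  names(q) <- "frag_1"
  hits <- .blast_best_hits(q, subject, reward = config$reward,
                           penalty = config$penalty,
                           gap_open = config$gap_open,
                           gap_ext = config$gap_ext,
                           task = config$task, evalue = config$evalue)
  qlen <- Biostrings::width(q)[1]
  if (nrow(hits) == 0) {
    return(list(hit = FALSE, identity_percent = NA_real_,
                aligned_fraction = 0))
  }
  af <- (abs(hits$qend[1] - hits$qstart[1]) + 1) / qlen
  ok <- af >= config$min_aligned_fraction &&
    hits$pident[1] >= config$min_identity
  list(hit = ok,
       identity_percent = if (ok) hits$pident[1] else NA_real_,
       aligned_fraction = af)
}

#' Directional fragment-ANI of a query genome against a subject
#'
#' Tiles the query, aligns every unmasked fragment against the subject and
#' summarizes: `ani_percent` is the unweighted mean identity over hit
#' fragments, `specific_fraction` the zero-hit share of unmasked
#' fragments, and `histogram` the identity spectrum. If no fragment hits,
#' `ani_percent` is `NA` with a warning (undefined, not zero).
#'
#' @param query,subject genomes.
#' @param config an [ani_config()].
#' @return a `directional_ani` object.
#' @export
directional_ani <- function(query, subject, config = ani_config()) {
  if (genome_length(query) == 0 || genome_length(subject) == 0) {
    stop("both genomes must be non-empty")
  }
  fragments <- fragment_genome(query, config$window_bp, config$step_bp,
                               config$min_fragment_length,
                               config$max_n_fraction)
  n_masked <- sum(fragments$masked)
  frag <- fragments[!fragments$masked, , drop = FALSE]
  n_frag <- nrow(frag)
  if (n_frag == 0) stop("no usable fragments in the query genome")
  seqs <- .fragment_seqs(query, frag)
  hits <- .blast_best_hits(seqs, subject, reward = config$reward,
                           penalty = config$penalty,
                           gap_open = config$gap_open,
                           gap_ext = config$gap_ext,
                           task = config$task, evalue = config$evalue)
  frag$identity <- NA_real_
  frag$aligned_fraction <- 0
  if (nrow(hits) > 0) {
    idx <- match(hits$qseqid, names(seqs))
    af <- (abs(hits$qend - hits$qstart) + 1) / frag$length[idx]
    ok <- af >= config$min_aligned_fraction &
      hits$pident >= config$min_identity
    frag$aligned_fraction[idx] <- af
    frag$identity[idx[ok]] <- hits$pident[ok]
  }
  n_hits <- sum(!is.na(frag$identity))
  zero_hits <- n_frag - n_hits
  ani <- if (n_hits > 0) mean(frag$identity, na.rm = TRUE) else NA_real_
  if (n_hits == 0) {
    warning("no fragment hits: ANI is undefined for ",
            genome_id(query), " vs ", genome_id(subject))
  }
  structure(list(
    query_id = genome_id(query), subject_id = genome_id(subject),
    ani_percent = ani, n_fragments = n_frag, n_hits = n_hits,
    n_masked = n_masked, specific_fraction = zero_hits / n_frag,
    histogram = identity_histogram(frag$identity, config$bin_edges,
                                   zero_hits),
    fragments = frag, config = config
  ), class = "directional_ani")
}

#' @export
print.directional_ani <- function(x, ...) {
  cat(sprintf("Directional ANI: %s (query) vs %s (subject)\n",
              x$query_id, x$subject_id))
  cat(sprintf("  ANI %.3f%% over %d/%d hit fragments; specific %.2f%%; masked %d\n",
              x$ani_percent, x$n_hits, x$n_fragments,
              100 * x$specific_fraction, x$n_masked))
  invisible(x)
}

#' Reciprocal fragment-ANI between two assemblies
#'
#' Runs the directional analysis in both directions with identical
#' parameters and averages the two ANI values. The pooled hit fragments of
#' both directions give `high_identity_fraction` (share of hit fragments
#' at or above `high_id_cut`); `divergent_band_fraction` is the share of
#' all unmasked fragments whose identity falls in `divergent_band`.
#'
#' @param genome_a,genome_b genomes.
#' @param config an [ani_config()].
#' @return a `reciprocal_ani` object with elements `forward`, `reverse`,
#'   `ani_mean`, `high_identity_fraction`, `divergent_band_fraction`.
#' @export
reciprocal_ani <- function(genome_a, genome_b, config = ani_config()) {
  fwd <- directional_ani(genome_a, genome_b, config)
  rev <- directional_ani(genome_b, genome_a, config)
  if (is.na(fwd$ani_percent)) {
    stop("forward direction (", fwd$query_id, " vs ", fwd$subject_id,
         ") has no hits: ANI undefined")
  }
  if (is.na(rev$ani_percent)) {
    stop("reverse direction (", rev$query_id, " vs ", rev$subject_id,
         ") has no hits: ANI undefined")
  }
  pooled <- c(fwd$fragments$identity, rev$fragments$identity)
  hit_ids <- pooled[!is.na(pooled)]
  n_all <- fwd$n_fragments + rev$n_fragments
  band <- config$divergent_band
  structure(list(
    forward = fwd, reverse = rev,
    ani_mean = (fwd$ani_percent + rev$ani_percent) / 2,
    high_identity_fraction = if (length(hit_ids)) {
      mean(hit_ids >= config$high_id_cut)
    } else 0,
    divergent_band_fraction = sum(hit_ids >= band[1] & hit_ids < band[2]) /
      n_all,
    specific_fraction_mean = (fwd$specific_fraction +
                                rev$specific_fraction) / 2,
    config = config
  ), class = "reciprocal_ani")
}

#' @export
print.reciprocal_ani <- function(x, ...) {
  cat(sprintf("Reciprocal ANI: %s vs %s\n",
              x$forward$query_id, x$reverse$query_id))
  cat(sprintf("  mean ANI %.3f%% (forward %.3f, reverse %.3f)\n",
              x$ani_mean, x$forward$ani_percent, x$reverse$ani_percent))
  cat(sprintf("  high-identity fraction %.3f; divergent band [%g,%g) %.3f\n",
              x$high_identity_fraction, x$config$divergent_band[1],
              x$config$divergent_band[2], x$divergent_band_fraction))
  cat(sprintf("  specific fraction: %.2f%% / %.2f%% (per direction)\n",
              100 * x$forward$specific_fraction,
              100 * x$reverse$specific_fraction))
  invisible(x)
}

#' Exact local alignment (dynamic programming)
#'
#' Exhaustive Smith--Waterman with affine gaps (a gap of length `k` costs
#' `gap_open + k * gap_ext`). Intended for validation and short sequences;
#' complexity is O(query x subject).
#'
#' @param query,subject sequences (character or `DNAString`).
#' @param reward,penalty,gap_open,gap_ext scoring; defaults match
#'   [ani_config()].
#' @param both_strands also align against the reverse complement of the
#'   subject and keep the better score.
#' @return list with `score`, `nident`, `ncols`, `identity_percent`,
#'   coordinates (1-based) and `strand`.
#' @export
align_local_exact <- function(query, subject, reward = 2, penalty = -3,
                              gap_open = 5, gap_ext = 2,
                              both_strands = TRUE) {
  q <- as.character(query)
  s <- as.character(subject)
  res <- .sw_align_cpp(q, s, reward, penalty, gap_open, gap_ext)
  res$strand <- "+"
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    alt <- .sw_align_cpp(q, rc, reward, penalty, gap_open, gap_ext)
    if (alt$score > res$score) {
      alt$strand <- "-"
      res <- alt
    }
  }
  res$identity_percent <- if (res$ncols > 0) {
    100 * res$nident / res$ncols
  } else NA_real_
  res
}
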