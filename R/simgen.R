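# Synthetic genome-pair generator. Two genomes are derived independently
# from a common random ancestor under a Jukes-Cantor-like substitution
# process, with optional high-divergence blocks, lineage-specific segments
# (zero-hit regions), indels, and a planted rDNA cassette. Every stochastic
# choice is seeded and the realized structure is returned as a truth record
# so downstream ANI and barcode results can be checked against ground truth.

#' Simulation parameters for a synthetic genome pair
#'
#' Divergence parameters are pairwise: substitutions are applied to each
#' lineage at half the stated rate, so that the expected pairwise
#' divergence matches the parameter up to double-hit effects (which the
#' analytic expectation in the truth record corrects for).
#'
#' @param length_bp total genome length in bp (>= 10,000).
#' @param gc_fraction expected GC content in `[0, 1]`.
#' @param background_divergence expected pairwise per-site substitution
#'   probability `d0` outside divergent blocks.
#' @param divergent_block_fraction proportion of the genome placed in
#'   high-divergence blocks.
#' @param divergent_block_divergence pairwise per-site substitution
#'   probability inside blocks; must exceed `background_divergence` when
#'   blocks are requested.
#' @param specific_fraction proportion of each genome replaced by
#'   lineage-unique random segments with no counterpart in the partner.
#' @param indel_rate per-site indel initiation probability (per lineage).
#' @param mean_indel_len mean indel length (geometric).
#' @param n_contigs number of contigs the genome is split into.
#' @param block_len length of each divergent block, bp.
#' @param specific_len length of each lineage-specific segment, bp.
#' @param seed integer seed; mandatory.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(length_bp = 1e6, gc_fraction = 0.5,
                       background_divergence = 0.01,
                       divergent_block_fraction = 0,
                       divergent_block_divergence = 0,
                       specific_fraction = 0,
                       indel_rate = 0, mean_indel_len = 3,
                       n_contigs = 1, block_len = 5000, specific_len = 5000,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  p <- list(length_bp = as.integer(length_bp), gc_fraction = gc_fraction,
            background_divergence = background_divergence,
            divergent_block_fraction = divergent_block_fraction,
            divergent_block_divergence = divergent_block_divergence,
            specific_fraction = specific_fraction,
            indel_rate = indel_rate, mean_indel_len = mean_indel_len,
            n_contigs = as.integer(n_contigs),
            block_len = as.integer(block_len),
            specific_len = as.integer(specific_len),
            seed = as.integer(seed))
  props <- c("gc_fraction", "background_divergence",
             "divergent_block_fraction", "divergent_block_divergence",
             "specific_fraction", "indel_rate")
  for (nm in props) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("`", nm, "` must be in [0, 1]")
  }
  if (p$divergent_block_fraction + p$specific_fraction > 0.5) {
    stop("divergent_block_fraction + specific_fraction must be <= 0.5")
  }
  if (p$divergent_block_fraction > 0 &&
      p$divergent_block_divergence <= p$background_divergence) {
    stop("divergent_block_divergence must exceed background_divergence")
  }
  if (p$length_bp < 10000L) stop("length_bp must be at least 10,000")
  if (p$n_contigs < 1L) stop("n_contigs must be >= 1")
  if (p$mean_indel_len <= 0) stop("mean_indel_len must be positive")
  structure(p, class = "sim_params")
}

#' Expected pairwise identity under the simulator's substitution model
#'
#' Each lineage substitutes a site with probability `d/2`, replacements
#' uniform over the three alternative bases. Two lineages then agree at a
#' site with probability `(1 - d/2)^2 + (d/2)^2 / 3`.
#'
#' @param d pairwise divergence parameter in `[0, 1]`.
#' @return expected pairwise identity in percent.
#' @export
expected_pairwise_identity <- function(d) {
  s <- d / 2
  100 * ((1 - s)^2 + s^2 / 3)
}

#' Divergence parameter giving a target expected pairwise identity
#'
#' Inverts [expected_pairwise_identity()] in closed form.
#'
#' @param identity_percent target expected pairwise identity in percent.
#' @return the pairwise divergence parameter `d`.
#' @export
divergence_for_identity <- function(identity_percent) {
  p <- identity_percent / 100
  stopifnot(p > 0, p <= 1)
  # (4/3) s^2 - 2 s + (1 - p) = 0, smaller root
  s <- (3 / 4) * (1 - sqrt(1 - (4 / 3) * (1 - p)))
  2 * s
}

#' Generate a random ancestor genome
#'
#' Bases are i.i.d. with the stated GC expectation; the total length is
#' split as evenly as possible over `n_contigs` contigs. Deterministic for
#' a fixed seed.
#'
#' @inheritParams sim_params
#' @return a genome (`DNAStringSet`).
#' @export
generate_ancestor <- function(length_bp, gc_fraction = 0.5, n_contigs = 1,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  length_bp <- as.integer(length_bp)
  n_contigs <- as.integer(n_contigs)
  if (length_bp <= 0 || n_contigs <= 0) {
    stop("length_bp and n_contigs must be positive")
  }
  if (length_bp < n_contigs * 1000L) {
    stop("length_bp must be at least n_contigs * 1000")
  }
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  lens <- rep(length_bp %/% n_contigs, n_contigs)
  extra <- length_bp %% n_contigs
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  contigs <- vapply(lens, function(L) {
    .int_to_seq(sample.int(4L, L, replace = TRUE, prob = prob))
  }, character(1))
  names(contigs) <- sprintf("contig_%d", seq_len(n_contigs))
  genome(contigs, id = sprintf("ancestor_seed%d", as.integer(seed)))
}

# place `n` non-overlapping intervals of length `len` uniformly across
# contigs, avoiding `avoid` (data.frame contig/start/end, 0-based
# half-open). Bounded rejection sampling; errors after `retries` misses.
.place_intervals <- function(contig_lens, n, len, avoid = NULL,
                             retries = 1000L) {
  placed <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  taken <- if (is.null(avoid)) placed else avoid
  ok_lens <- contig_lens[contig_lens >= len]
  if (n > 0 && length(ok_lens) == 0) {
    stop("simulation error: no contig can hold an interval of ", len, " bp")
  }
  misses <- 0L
  while (nrow(placed) < n) {
    ct <- sample(names(ok_lens), 1L, prob = as.numeric(ok_lens))
    start <- sample.int(ok_lens[[ct]] - len + 1L, 1L) - 1L
    end <- start + len
    clash <- taken$contig == ct & taken$start < end & taken$end > start
    if (any(clash)) {
      misses <- misses + 1L
      if (misses > retries) {
        stop("simulation error: could not place ", n,
             " non-overlapping intervals after ", retries, " retries")
      }
      next
    }
    row <- data.frame(contig = ct, start = start, end = end,
                      stringsAsFactors = FALSE)
    placed <- rbind(placed, row)
    taken <- rbind(taken, row)
  }
  placed[order(placed$contig, placed$start), , drop = FALSE]
}

# logical mask of positions covered by intervals, per contig
.interval_mask <- function(contig_lens, intervals) {
  masks <- lapply(contig_lens, function(L) logical(L))
  if (!is.null(intervals) && nrow(intervals) > 0) {
    for (k in seq_len(nrow(intervals))) {
      ct <- intervals$contig[k]
      masks[[ct]][(intervals$start[k] + 1L):intervals$end[k]] <- TRUE
    }
  }
  masks
}

# Jukes-Cantor-like substitution: each selected site is replaced by one of
# the three alternative bases with equal probability.
.substitute <- function(v, idx) {
  if (length(idx) == 0) return(v)
  v[idx] <- ((v[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  v
}

#' Evolve a genome pair from a common ancestor
#'
#' Both genomes are derived independently from the ancestor. Substitutions
#' are applied per lineage at half the pairwise rate (`d0/2` outside
#' divergent blocks, `d_div/2` inside). A `specific_fraction` of the genome
#' is replaced, at the same coordinates in both genomes, by independent
#' random segments, so each genome carries that fraction of sequence with
#' no counterpart in the partner. Optional indels (geometric length) are
#' applied outside all annotated intervals. The returned truth record
#' carries the analytic identity expectation, the realized identities
#' measured by direct column comparison, and all planted intervals
#' (0-based, half-open).
#'
#' @param ancestor a genome from [generate_ancestor()].
#' @param params a [sim_params()] object.
#' @return list with elements `genome_a`, `genome_b`, `truth`.
#' @export
evolve_pair <- function(ancestor, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  contig_lens <- setNames(Biostrings::width(ancestor), names(ancestor))
  L <- sum(contig_lens)
  anc <- lapply(setNames(names(ancestor), names(ancestor)),
                function(ct) .seq_to_int(as.character(ancestor[[ct]])))

  n_blocks <- round(params$divergent_block_fraction * L / params$block_len)
  blocks <- .place_intervals(contig_lens, n_blocks, params$block_len)
  n_spec <- round(params$specific_fraction * L / params$specific_len)
  specific <- .place_intervals(contig_lens, n_spec, params$specific_len,
                               avoid = blocks)

  block_mask <- .interval_mask(contig_lens, blocks)
  spec_mask <- .interval_mask(contig_lens, specific)

  s_bg <- params$background_divergence / 2
  s_blk <- params$divergent_block_divergence / 2
  prob <- c((1 - params$gc_fraction) / 2, params$gc_fraction / 2,
            params$gc_fraction / 2, (1 - params$gc_fraction) / 2)

  evolve_one <- function() {
    lapply(setNames(names(anc), names(anc)), function(ct) {
      v <- anc[[ct]]
      n <- length(v)
      rate <- rep(s_bg, n)
      rate[block_mask[[ct]]] <- s_blk
      rate[spec_mask[[ct]]] <- 0
      idx <- which(runif(n) < rate)
      v <- .substitute(v, idx)
      if (any(spec_mask[[ct]])) {
        v[spec_mask[[ct]]] <- sample.int(4L, sum(spec_mask[[ct]]),
                                         replace = TRUE, prob = prob)
      }
      v
    })
  }
  a <- evolve_one()
  b <- evolve_one()

  # realized identities by direct column comparison (pre-indel coordinates)
  same <- mapply(function(x, y) x == y, a, b, SIMPLIFY = FALSE)
  bg_same <- unlist(mapply(function(s, bm, sm) s[!bm & !sm],
                           same, block_mask, spec_mask, SIMPLIFY = FALSE))
  blk_same <- unlist(mapply(function(s, bm) s[bm],
                            same, block_mask, SIMPLIFY = FALSE))
  realized_bg <- if (length(bg_same)) 100 * mean(bg_same) else NA_real_
  realized_blk <- if (length(blk_same)) 100 * mean(blk_same) else NA_real_

  protected <- rbind(blocks, specific)
  indels_a <- list(ins = 0L, del = 0L)
  indels_b <- list(ins = 0L, del = 0L)
  shift_a <- blocks; shift_sa <- specific
  shift_b <- blocks; shift_sb <- specific
  if (params$indel_rate > 0) {
    res_a <- .apply_indels(a, params, protected, prob)
    a <- res_a$seqs; indels_a <- res_a$totals
    shift_a <- .shift_intervals(blocks, res_a$events)
    shift_sa <- .shift_intervals(specific, res_a$events)
    res_b <- .apply_indels(b, params, protected, prob)
    b <- res_b$seqs; indels_b <- res_b$totals
    shift_b <- .shift_intervals(blocks, res_b$events)
    shift_sb <- .shift_intervals(specific, res_b$events)
  }

  truth <- structure(list(
    expected_background_identity =
      expected_pairwise_identity(params$background_divergence),
    expected_block_identity = if (n_blocks > 0)
      expected_pairwise_identity(params$divergent_block_divergence)
    else NA_real_,
    realized_background_identity = realized_bg,
    realized_block_identity = realized_blk,
    block_intervals = shift_a,
    specific_intervals_A = shift_sa,
    specific_intervals_B = shift_sb,
    cassette_interval = NULL,
    inserted_bp = c(A = indels_a$ins, B = indels_b$ins),
    deleted_bp = c(A = indels_a$del, B = indels_b$del),
    seed_used = params$seed,
    params = unclass(params)
  ), class = "truth_record")

  mk <- function(seqs, tag) {
    genome(vapply(seqs, .int_to_seq, character(1)),
           id = paste0("sim", params$seed, "_", tag))
  }
  list(genome_a = mk(a, "A"), genome_b = mk(b, "B"), truth = truth)
}

# apply seeded indels to one lineage, skipping protected intervals;
# returns modified sequences, net totals and the event list used to shift
# recorded interval coordinates.
.apply_indels <- function(seqs, params, protected, prob) {
  totals <- list(ins = 0L, del = 0L)
  events <- data.frame(contig = character(0), pos = integer(0),
                       delta = integer(0), stringsAsFactors = FALSE)
  out <- seqs
  for (ct in names(seqs)) {
    v <- out[[ct]]
    n <- length(v)
    pos <- which(runif(n) < params$indel_rate)
    if (length(pos) == 0) next
    lens <- rgeom(length(pos), 1 / params$mean_indel_len) + 1L
    is_ins <- runif(length(pos)) < 0.5
    prot <- protected[protected$contig == ct, , drop = FALSE]
    keep <- rep(TRUE, length(pos))
    for (k in seq_along(pos)) {
      lo <- pos[k] - 1L
      hi <- if (is_ins[k]) lo else lo + lens[k]
      if (nrow(prot) > 0 &&
          any(prot$start < hi + 1L & prot$end > lo)) keep[k] <- FALSE
      if (!is_ins[k] && pos[k] + lens[k] - 1L > n) keep[k] <- FALSE
    }
    pos <- pos[keep]; lens <- lens[keep]; is_ins <- is_ins[keep]
    if (length(pos) == 0) next
    # apply right-to-left so earlier coordinates stay valid
    o <- order(pos, decreasing = TRUE)
    for (k in o) {
      if (is_ins[k]) {
        ins <- sample.int(4L, lens[k], replace = TRUE, prob = prob)
        v <- append(v, ins, after = pos[k])
        totals$ins <- totals$ins + lens[k]
      } else {
        v <- v[-(pos[k]:(pos[k] + lens[k] - 1L))]
        totals$del <- totals$del + lens[k]
      }
    }
    out[[ct]] <- v
    events <- rbind(events, data.frame(
      contig = ct, pos = pos,
      delta = ifelse(is_ins, lens, -lens), stringsAsFactors = FALSE))
  }
  list(seqs = out, totals = totals, events = events)
}

# shift interval coordinates by the cumulative indel delta upstream of each
# interval (indels never fall inside recorded intervals)
.shift_intervals <- function(intervals, events) {
  if (nrow(intervals) == 0 || nrow(events) == 0) return(intervals)
  for (k in seq_len(nrow(intervals))) {
    e <- events[events$contig == intervals$contig[k] &
                  events$pos <= intervals$start[k], , drop = FALSE]
    d <- sum(e$delta)
    intervals$start[k] <- intervals$start[k] + d
    intervals$end[k] <- intervals$end[k] + d
  }
  intervals
}

#' Evolve a genome pair with a planted per-tile identity spectrum
#'
#' Divides the ancestor into fixed tiles and plants an exact number of
#' substitutions in each tile so that the pairwise identity spectrum of the
#' pair is controlled tile by tile -- the structure in which fragment-based
#' ANI results are reported (counts of fragments per identity band). Each
#' tile assigned to a spectrum class with identity `I` receives
#' `round(tile_bp * (1 - I/100))` substitutions at distinct sites, split
#' between the two lineages so no site is hit twice. Tiles assigned to the
#' specific class are replaced in both genomes by independent random
#' sequence. Tiles are aligned to the start of each contig, matching the
#' default non-overlapping fragment tiling of the ANI engine.
#'
#' @param ancestor a genome from [generate_ancestor()].
#' @param spectrum data.frame with columns `fraction` and `identity`
#'   (percent); fractions (plus `specific_fraction`) must sum to at most 1.
#'   Leftover tiles stay identical (100% identity).
#' @param specific_fraction fraction of tiles made lineage-specific.
#' @param tile_bp tile length, default 1000 (the ANI engine's default
#'   fragment window).
#' @param seed integer seed.
#' @return list with elements `genome_a`, `genome_b`, `truth`; the truth
#'   record's `spectrum_intervals` lists the tiles of each class.
#' @export
evolve_spectrum_pair <- function(ancestor, spectrum, specific_fraction = 0,
                                 tile_bp = 1000, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(is.data.frame(spectrum),
            all(c("fraction", "identity") %in% names(spectrum)),
            all(spectrum$fraction >= 0),
            all(spectrum$identity >= 0 & spectrum$identity <= 100))
  if (sum(spectrum$fraction) + specific_fraction > 1 + 1e-9) {
    stop("spectrum fractions plus specific_fraction exceed 1")
  }
  set.seed(as.integer(seed))
  contig_lens <- setNames(Biostrings::width(ancestor), names(ancestor))
  anc <- lapply(setNames(names(ancestor), names(ancestor)),
                function(ct) .seq_to_int(as.character(ancestor[[ct]])))
  tiles <- do.call(rbind, lapply(names(contig_lens), function(ct) {
    n <- contig_lens[[ct]] %/% tile_bp
    if (n == 0) return(NULL)
    data.frame(contig = ct, start = (seq_len(n) - 1L) * tile_bp,
               end = seq_len(n) * tile_bp, stringsAsFactors = FALSE)
  }))
  nt <- nrow(tiles)
  n_per_class <- round(spectrum$fraction * nt)
  n_spec <- round(specific_fraction * nt)
  if (sum(n_per_class) + n_spec > nt) stop("too few tiles for the spectrum")
  perm <- sample.int(nt)
  cls <- rep(0L, nt) # 0 = untouched
  off <- 0L
  for (k in seq_len(nrow(spectrum))) {
    if (n_per_class[k] > 0) {
      cls[perm[(off + 1L):(off + n_per_class[k])]] <- k
      off <- off + n_per_class[k]
    }
  }
  if (n_spec > 0) {
    cls[perm[(off + 1L):(off + n_spec)]] <- -1L
  }
  base_freq <- table(factor(unlist(anc), levels = 1:4))
  prob <- as.numeric(base_freq) / sum(base_freq)

  a <- anc; b <- anc
  for (t in seq_len(nt)) {
    if (cls[t] == 0L) next
    ct <- tiles$contig[t]
    pos <- (tiles$start[t] + 1L):tiles$end[t]
    if (cls[t] == -1L) {
      a[[ct]][pos] <- sample.int(4L, tile_bp, replace = TRUE, prob = prob)
      b[[ct]][pos] <- sample.int(4L, tile_bp, replace = TRUE, prob = prob)
      next
    }
    id <- spectrum$identity[cls[t]]
    n_mm <- round(tile_bp * (1 - id / 100))
    if (n_mm == 0) next
    sites <- sample(pos, n_mm)
    half <- n_mm %/% 2L
    a[[ct]] <- .substitute(a[[ct]], sites[seq_len(half)])
    if (n_mm > half) {
      b[[ct]] <- .substitute(b[[ct]], sites[(half + 1L):n_mm])
    }
  }

  class_intervals <- lapply(seq_len(nrow(spectrum)), function(k) {
    tiles[cls == k, , drop = FALSE]
  })
  names(class_intervals) <- sprintf("identity_%s", spectrum$identity)
  spec_int <- tiles[cls == -1L, , drop = FALSE]

  same <- unlist(mapply(function(x, y) x == y, a, b, SIMPLIFY = FALSE))
  truth <- structure(list(
    expected_background_identity = NA_real_,
    expected_block_identity = NA_real_,
    realized_background_identity = 100 * mean(same),
    realized_block_identity = NA_real_,
    block_intervals = if (nrow(spectrum)) class_intervals[[
      which.min(spectrum$identity)]] else tiles[0, ],
    spectrum_intervals = class_intervals,
    specific_intervals_A = spec_int,
    specific_intervals_B = spec_int,
    cassette_interval = NULL,
    inserted_bp = c(A = 0L, B = 0L),
    deleted_bp = c(A = 0L, B = 0L),
    seed_used = as.integer(seed),
    params = list(spectrum = spectrum, specific_fraction = specific_fraction,
                  tile_bp = tile_bp)
  ), class = "truth_record")

  mk <- function(seqs, tag) {
    genome(vapply(seqs, .int_to_seq, character(1)),
           id = paste0("simspec", seed, "_", tag))
  }
  list(genome_a = mk(a, "A"), genome_b = mk(b, "B"), truth = truth)
}

#' Insert an rDNA cassette into a genome
#'
#' Inserts a cassette (for instance an ITS+LSU barcode region) verbatim at
#' the stated position; on the minus strand the reverse complement is
#' inserted. The returned interval records the span the cassette occupies
#' in the new genome (0-based, half-open).
#'
#' @param x a genome.
#' @param cassette cassette sequence (character or `DNAString`), length >=
#'   500.
#' @param contig contig name.
#' @param position 0-based insertion offset within the contig.
#' @param strand `"+"` or `"-"`.
#' @return list with elements `genome` and `interval`.
#' @export
insert_rdna_cassette <- function(x, cassette, contig, position,
                                 strand = c("+", "-")) {
  strand <- match.arg(strand)
  cas <- Biostrings::DNAString(toupper(as.character(cassette)))
  if (length(cas) < 500) stop("cassette must be at least 500 bp")
  if (!contig %in% names(x)) stop("no contig named '", contig, "'")
  clen <- Biostrings::width(x)[match(contig, names(x))]
  position <- as.integer(position)
  if (position < 0 || position > clen) {
    stop("position must be in [0, ", clen, "]")
  }
  ins <- if (strand == "-") Biostrings::reverseComplement(cas) else cas
  old <- x[[contig]]
  new_contig <- Biostrings::xscat(
    Biostrings::subseq(old, 1, position),
    ins,
    Biostrings::subseq(old, position + 1, clen))
  contigs <- as.character(x)
  contigs[[contig]] <- as.character(new_contig)
  list(
    genome = genome(contigs, id = genome_id(x)),
    interval = list(contig = contig, start = position,
                    end = position + length(cas), strand = strand)
  )
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Truth record (seed", x$seed_used, ")\n")
  cat(sprintf("  expected background identity: %s\n",
              format(x$expected_background_identity)))
  cat(sprintf("  realized background identity: %s\n",
              format(x$realized_background_identity)))
  if (!is.na(x$realized_block_identity)) {
    cat(sprintf("  realized block identity: %.3f\n",
                x$realized_block_identity))
  }
  cat(sprintf("  divergent blocks: %d, specific segments: %d\n",
              nrow(x$block_intervals), nrow(x$specific_intervals_A)))
  invisible(x)
}

#' Simulate a conspecific pair carrying a minority of divergent blocks
#'
#' Preset around [evolve_spectrum_pair()] reproducing the identity-spectrum
#' signature of a conspecific pair whose mean ANI is dragged below the
#' species threshold by a minority of highly divergent regions: most
#' fragments at or above 99.5% identity, a few percent of fragments in the
#' 85-90% band, and around 1% lineage-specific sequence per genome.
#'
#' @param length_bp genome length (one contig).
#' @param high_identity,high_fraction identity (percent) and genome
#'   fraction of the dominant high-similarity class.
#' @param band_identity,band_fraction identity and fraction of the
#'   divergent-block class.
#' @param specific_fraction lineage-specific fraction per genome.
#' @param gc_fraction ancestor GC content.
#' @param seed integer seed.
#' @return as [evolve_spectrum_pair()].
#' @export
simulate_divergent_block_pair <- function(length_bp = 5e5,
                                          high_identity = 99.5,
                                          high_fraction = 0.95,
                                          band_identity = 85.2,
                                          band_fraction = 0.04,
                                          specific_fraction = 0.01,
                                          gc_fraction = 0.5, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  anc <- generate_ancestor(length_bp, gc_fraction, 1, seed = seed)
  evolve_spectrum_pair(
    anc,
    spectrum = data.frame(fraction = c(high_fraction, band_fraction),
                          identity = c(high_identity, band_identity)),
    specific_fraction = specific_fraction, seed = seed + 1L)
}
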