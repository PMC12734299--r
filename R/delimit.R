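# Species-delimitation decision rules. The primary thresholds: pairs with
# mean reciprocal ANI at or above 99.5% are conspecific; pairs below 99%
# are distinct species -- unless the identity spectrum shows the signature
# of a conspecific pair whose ANI is dragged down by a minority of highly
# divergent blocks (most hit fragments >= 99.5% identity, a material
# fraction in the 85-90% band, few specific sequences). The 99-99.5% zone
# is reported as ambiguous: above 99.5 conspecificity is consistent,
# below 99 distinctness is usual, and the interval in between is not
# adjudicated by ANI alone.

#' Thresholds for species delimitation
#'
#' @param t_same ANI (percent) at or above which a pair is called the same
#'   species.
#' @param t_diff ANI below which a pair is called different species
#'   (unless the divergent-block exception fires).
#' @param high_id_cut identity cut defining "highly similar" fragments.
#' @param high_id_min_fraction minimum fraction of hit fragments at or
#'   above `high_id_cut` for the exception.
#' @param divergent_band identity interval `[lo, hi)` of the divergent
#'   block signature.
#' @param divergent_band_min_fraction minimum fraction of all fragments in
#'   the band for the exception.
#' @param max_specific_for_conspecific maximum mean specific-sequence
#'   fraction for the exception.
#' @return a `delimit_thresholds` object.
#' @export
delimit_thresholds <- function(t_same = 99.5, t_diff = 99.0,
                               high_id_cut = 99.5,
                               high_id_min_fraction = 0.80,
                               divergent_band = c(85, 90),
                               divergent_band_min_fraction = 0.02,
                               max_specific_for_conspecific = 0.03) {
  if (t_diff >= t_same) stop("t_diff must be below t_same")
  for (p in c(high_id_min_fraction, divergent_band_min_fraction,
              max_specific_for_conspecific)) {
    if (p < 0 || p > 1) stop("fractions must be in [0, 1]")
  }
  structure(list(t_same = t_same, t_diff = t_diff,
                 high_id_cut = high_id_cut,
                 high_id_min_fraction = high_id_min_fraction,
                 divergent_band = divergent_band,
                 divergent_band_min_fraction = divergent_band_min_fraction,
                 max_specific_for_conspecific =
                   max_specific_for_conspecific),
            class = "delimit_thresholds")
}

#' Classify a genome pair from its reciprocal ANI
#'
#' Pure decision function over a [reciprocal_ani()] result. Rule order:
#' (1) `ani_mean >= t_same` gives `same_species`; (2) `ani_mean < t_diff`
#' with a high-identity-dominated spectrum, a populated divergent band and
#' few specific sequences gives `same_species_divergent_blocks`;
#' (3) `ani_mean < t_diff` otherwise gives `different_species`;
#' (4) the remaining `[t_diff, t_same)` zone is `ambiguous`.
#'
#' @param r a `reciprocal_ani` object.
#' @param thresholds a [delimit_thresholds()] object.
#' @return a `species_call` object with `verdict`, `ani_mean` and an
#'   `evidence` list naming the rule that fired.
#' @export
classify_pair <- function(r, thresholds = delimit_thresholds()) {
  if (!inherits(r, "reciprocal_ani")) {
    stop("`r` must be a reciprocal_ani object")
  }
  if (is.na(r$ani_mean)) stop("reciprocal ANI is incomplete (NA ani_mean)")
  t <- thresholds
  ani <- r$ani_mean
  spec_mean <- r$specific_fraction_mean
  ev <- sprintf(
    "ani_mean %.3f; high-identity fraction %.3f; band [%g,%g) fraction %.4f; mean specific fraction %.4f",
    ani, r$high_identity_fraction, t$divergent_band[1],
    t$divergent_band[2], r$divergent_band_fraction, spec_mean)
  if (ani >= t$t_same) {
    verdict <- "same_species"
    ev <- c(ev, sprintf("rule 1: ani_mean >= %.2f", t$t_same))
  } else if (ani < t$t_diff &&
             r$high_identity_fraction >= t$high_id_min_fraction &&
             r$divergent_band_fraction >= t$divergent_band_min_fraction &&
             spec_mean <= t$max_specific_for_conspecific) {
    verdict <- "same_species_divergent_blocks"
    ev <- c(ev, sprintf(
      "rule 2: ani_mean < %.2f but spectrum dominated by >= %.1f%% fragments with a divergent band: conspecific pair with divergent blocks",
      t$t_diff, t$high_id_cut))
  } else if (ani < t$t_diff) {
    verdict <- "different_species"
    ev <- c(ev, sprintf("rule 3: ani_mean < %.2f", t$t_diff))
  } else {
    verdict <- "ambiguous"
    ev <- c(ev, sprintf("rule 4: ani_mean in [%.2f, %.2f)",
                        t$t_diff, t$t_same))
  }
  structure(list(id_a = r$forward$query_id, id_b = r$reverse$query_id,
                 verdict = verdict, ani_mean = ani,
                 high_identity_fraction = r$high_identity_fraction,
                 divergent_band_fraction = r$divergent_band_fraction,
                 specific_fraction_mean = spec_mean,
                 evidence = ev, thresholds = t),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("%s vs %s: %s (ANI %.3f%%)\n", x$id_a, x$id_b, x$verdict,
              x$ani_mean))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' All-pairs reciprocal ANI and species calls
#'
#' Computes the upper triangle of pairwise reciprocal ANIs and classifies
#' every pair; the reported matrices are symmetric.
#'
#' @param genomes named list of genomes (unique ids, at least two).
#' @param config an [ani_config()].
#' @param thresholds a [delimit_thresholds()].
#' @return a `delimit_result`: `calls` data.frame, symmetric `ani_matrix`
#'   and `verdict_matrix`, and the per-pair `reciprocal_ani` objects.
#' @export
run_all_pairs <- function(genomes, config = ani_config(),
                          thresholds = delimit_thresholds()) {
  if (length(genomes) < 2) stop("need at least two genomes")
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(genomes, genome_id, character(1))
  }
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  n <- length(genomes)
  ani_m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ver_m <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  diag(ani_m) <- 100
  diag(ver_m) <- "same_species"
  pairs <- list(); calls <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- reciprocal_ani(genomes[[i]], genomes[[j]], config)
      cl <- classify_pair(r, thresholds)
      ani_m[i, j] <- ani_m[j, i] <- r$ani_mean
      ver_m[i, j] <- ver_m[j, i] <- cl$verdict
      key <- paste(ids[i], ids[j], sep = "__")
      pairs[[key]] <- r
      calls[[key]] <- data.frame(
        id_a = ids[i], id_b = ids[j], ani_mean = r$ani_mean,
        verdict = cl$verdict,
        high_identity_fraction = r$high_identity_fraction,
        divergent_band_fraction = r$divergent_band_fraction,
        specific_fraction_a = r$forward$specific_fraction,
        specific_fraction_b = r$reverse$specific_fraction,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(calls = do.call(rbind, c(calls, make.row.names = FALSE)),
                 ani_matrix = ani_m, verdict_matrix = ver_m,
                 pairs = pairs, config = config, thresholds = thresholds),
            class = "delimit_result")
}

#' @export
print.delimit_result <- function(x, ...) {
  cat("Species delimitation over", nrow(x$ani_matrix), "genomes\n")
  print(round(x$ani_matrix, 2))
  cat("\nVerdicts:\n")
  print(x$calls[, c("id_a", "id_b", "ani_mean", "verdict")])
  invisible(x)
}

# serialize a directional ANI for the JSON report
.dir_ani_list <- function(d) {
  list(query_id = d$query_id, subject_id = d$subject_id,
       ani_percent = d$ani_percent, n_fragments = d$n_fragments,
       n_hits = d$n_hits, n_masked = d$n_masked,
       specific_fraction = d$specific_fraction,
       histogram = list(bin_edges = d$histogram$bin_edges,
                        counts = d$histogram$counts,
                        zero_hits = d$histogram$zero_hits))
}

#' Write delimitation reports
#'
#' Writes the symmetric ANI matrix and verdict matrix as TSV, a per-pair
#' calls table, one JSON file per pair carrying both directional
#' histograms plus the configuration echo, and a log of rule firings.
#'
#' @param result a `delimit_result` from [run_all_pairs()].
#' @param dir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "delimit_result"))
  if (is.null(result$calls) || nrow(result$calls) == 0) {
    stop("no calls to report")
  }
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create report directory: ", dir)
  write_matrix <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_matrix(result$ani_matrix, file.path(dir, "ani_matrix.tsv"))
  write_matrix(result$verdict_matrix, file.path(dir, "verdict_matrix.tsv"))
  utils::write.table(result$calls, file.path(dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pair_dir <- file.path(dir, "pairs")
  dir.create(pair_dir, showWarnings = FALSE)
  log_lines <- character(0)
  for (key in names(result$pairs)) {
    r <- result$pairs[[key]]
    cl <- classify_pair(r, result$thresholds)
    jsonlite::write_json(list(
      pair = key,
      ani_mean = r$ani_mean,
      verdict = cl$verdict,
      high_identity_fraction = r$high_identity_fraction,
      divergent_band_fraction = r$divergent_band_fraction,
      forward = .dir_ani_list(r$forward),
      reverse = .dir_ani_list(r$reverse),
      evidence = cl$evidence,
      config = unclass(result$config),
      thresholds = unclass(result$thresholds)
    ), file.path(pair_dir, paste0(key, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("%s\t%s\t%s", key, cl$verdict,
                           utils::tail(cl$evidence, 1)))
  }
  writeLines(log_lines, file.path(dir, "rule_log.tsv"))
  invisible(dir)
}

#' Read a matrix written by [write_report()]
#' @param path TSV with an `id` column and one column per genome.
#' @return matrix with dimnames.
#' @export
read_ani_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
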