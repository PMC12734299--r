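# shared fixture builders; everything is generated in code under fixed
# seeds, no stored data

contig_lens <- function(g) {
  stats::setNames(Biostrings::width(g), names(g))
}

# coverage table from flank / mat reads-per-kbp vectors, in the vocabulary
# order APN2, SLA2, mat1-1-1, mat1-1-2, mat1-1-3, mat1-2-1
make_coverage <- function(flanks, mats) {
  data.frame(
    gene = c("APN2", "SLA2", "mat1-1-1", "mat1-1-2", "mat1-1-3",
             "mat1-2-1"),
    reads_per_kbp = c(flanks, mats), stringsAsFactors = FALSE)
}

# minimal reciprocal_ani stand-in for exercising the pure decision rules
make_rani <- function(ani, high = 0.99, band = 0, specific = 0,
                      id_a = "A", id_b = "B") {
  structure(list(
    forward = list(query_id = id_a, subject_id = id_b,
                   specific_fraction = specific),
    reverse = list(query_id = id_b, subject_id = id_a,
                   specific_fraction = specific),
    ani_mean = ani, high_identity_fraction = high,
    divergent_band_fraction = band, specific_fraction_mean = specific,
    config = ani_config()), class = "reciprocal_ani")
}

# plant k substitutions at interior positions of a sequence (deterministic
# given the RNG state); returns the mutated string
plant_substitutions <- function(s, positions) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) {
    substr(s, p, p) <- swap[[substr(s, p, p)]]
  }
  s
}
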