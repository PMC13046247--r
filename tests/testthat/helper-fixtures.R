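# Shared fixtures and independent oracles, built in code.

tiny_layout <- function(lengths = c(1e5, 5e4), ...) {
  make_genome_layout(lengths, ...)
}

# BinnedTrack from a plain list of vectors (chromosome lengths inferred).
track_from <- function(values, bin_size = 10, lengths = NULL,
                       state = "raw_counts") {
  if (is.null(names(values)))
    names(values) <- paste0("chr", seq_along(values))
  if (is.null(lengths)) lengths <- lengths(values) * bin_size
  layout <- make_genome_layout(lengths, names(values))
  binned_track(values, layout, bin_size, state = state)
}

two_sample_sheet <- function() {
  data.frame(sample_id = c("chip", "unt"), role = c("chip", "untagged"),
             stringsAsFactors = FALSE)
}

# Brute-force all-pairs overlap oracle (>= 1 bp, 0-based half-open).
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Brute-force Venn labelling oracle mirroring the figure-legend rule.
brute_venn_labels <- function(peaks, features) {
  lab_of <- c(hotspot = "Spo11", axis = "Red1", centromere = "Centromere")
  vapply(seq_len(nrow(peaks)), function(i) {
    hit <- character(0)
    for (cl in names(lab_of)) {
      f <- features[features$class == cl, , drop = FALSE]
      if (nrow(f) && any(f$chrom == peaks$chrom[i] &
                         f$start < peaks$end[i] & f$end > peaks$start[i]))
        hit <- c(hit, lab_of[[cl]])
    }
    if (length(hit)) paste(hit, collapse = "+") else "Nil"
  }, character(1))
}

# Direct-summation Nadaraya-Watson oracle with the full Gaussian kernel.
nw_oracle <- function(v, centers, bandwidth) {
  sd <- 0.25 * bandwidth / qnorm(0.75)
  vapply(seq_along(v), function(i) {
    w <- dnorm(centers - centers[i], 0, sd)
    sum(w * v) / sum(w)
  }, 0)
}

random_intervals <- function(n, chroms, max_pos = 1e5, max_width = 2000) {
  start <- floor(runif(n, 0, max_pos - max_width))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + ceiling(runif(n, 1, max_width)),
             stringsAsFactors = FALSE)
}

# One-sample ChIP + untagged simulation binned and peak-called.
sim_and_call <- function(layout, features, model, n_reads, seed,
                         params = peak_params()) {
  rd <- simulate_experiment(layout, features, model, n_reads,
                            samples = two_sample_sheet(), seed = seed)
  chip <- bin_reads(rd$chip, layout)
  unt <- bin_reads(rd$unt, layout)
  list(reads = rd, chip = chip, unt = unt,
       peaks = call_peaks(chip, unt, params))
}
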