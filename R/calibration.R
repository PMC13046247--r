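#' Binned coverage track
#'
#' A `BinnedTrack` holds one value per fixed-width bin per chromosome
#' (the genome is partitioned into `bin_size`-bp bins, default 10 bp; the
#' last bin of each chromosome may be short). `state` tracks the
#' processing stage: `raw_counts`, `normalized`, `calibrated` or
#' `smoothed`. Calibrated values may be negative (untagged subtraction is
#' not clamped).
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param layout a [make_genome_layout()] object.
#' @param bin_size bin width in bp.
#' @param state processing state flag.
#' @param provenance free-form list recording inputs/parameters.
#' @return an object of class `BinnedTrack`.
#' @export
binned_track <- function(values, layout, bin_size = 10,
                         state = "raw_counts", provenance = list()) {
  stopifnot(inherits(layout, "GenomeLayout"))
  nb <- ceiling(layout$chrom_lengths / bin_size)
  if (!identical(sort(names(values)), sort(layout$chrom_names)))
    stop("track chromosomes must match the layout")
  values <- values[layout$chrom_names]
  for (ch in layout$chrom_names)
    if (length(values[[ch]]) != nb[[ch]])
      stop("bin vector length mismatch on ", ch)
  structure(list(values = values, layout = layout,
                 bin_size = as.integer(bin_size), state = state,
                 provenance = provenance),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat("BinnedTrack [", x$state, "]: ", length(x$values),
      " chromosomes, bin ", x$bin_size, " bp, total ",
      format(sum(unlist(lapply(x$values, sum))), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Genome-wide total of a track
#' @param track a [binned_track()].
#' @return sum over all bins of all chromosomes.
#' @export
track_total <- function(track) sum(vapply(track$values, sum, 0))

#' Genome-wide mean per-bin coverage of a track
#'
#' Used as the "untagged sample coverage" in SF2: the untagged sample's
#' mean raw reads per bin over all bins of all chromosomes.
#'
#' @param track a [binned_track()].
#' @return mean value per bin.
#' @export
track_mean_coverage <- function(track) {
  track_total(track) / sum(lengths(track$values))
}

same_grid <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$values), names(b$values)) &&
    identical(lengths(a$values), lengths(b$values))
}

#' Count uniquely mapped target and spike-in reads
#'
#' @param reads a `MappedReadSet` (see [simulate_experiment()],
#'   [read_reads_tsv()]).
#' @return named numeric vector `c(n_target_unique, n_spike_unique)`;
#'   ambiguous and unmapped reads are excluded from both.
#' @examples
#' count_unique_reads(data.frame(status = c("target_unique",
#'   "target_unique", "spike_unique", "ambiguous")))
#' @export
count_unique_reads <- function(reads) {
  st <- reads$status
  if (length(st) && !all(st %in% READ_STATUSES))
    stop("unknown read status: ",
         paste(unique(setdiff(st, READ_STATUSES)), collapse = ", "))
  c(n_target_unique = sum(st == "target_unique"),
    n_spike_unique = sum(st == "spike_unique"))
}

#' Spike-in scaling factors
#'
#' SF1 is the ratio of uniquely mapped target-genome reads to uniquely
#' mapped spike-in reads; SF2 is SF1 divided by the untagged sample's
#' coverage (its genome-wide mean reads per bin, see
#' [track_mean_coverage()]).
#'
#' @param n_target_unique,n_spike_unique unique read counts.
#' @param untagged_coverage untagged mean reads per bin.
#' @param sample_id optional label.
#' @return a list of class `ScalingFactors` with elements `sf1`, `sf2`,
#'   `sample_id`.
#' @examples
#' compute_scaling(2000, 200, 2.5) # sf1 = 10, sf2 = 4
#' @export
compute_scaling <- function(n_target_unique, n_spike_unique,
                            untagged_coverage, sample_id = NA_character_) {
  if (is.na(n_spike_unique) || n_spike_unique <= 0)
    stop("no spike-in signal: zero uniquely mapped spike reads")
  if (is.na(untagged_coverage) || untagged_coverage <= 0)
    stop("untagged coverage must be positive")
  if (n_target_unique < 0) stop("negative read count")
  sf1 <- n_target_unique / n_spike_unique
  structure(list(sf1 = sf1, sf2 = sf1 / untagged_coverage,
                 sample_id = sample_id),
            class = "ScalingFactors")
}

#' @export
print.ScalingFactors <- function(x, ...) {
  cat("ScalingFactors", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"),
      ": SF1 =", format(x$sf1, digits = 6),
      ", SF2 =", format(x$sf2, digits = 6), "\n")
  invisible(x)
}

#' Bin uniquely mapped target reads
#'
#' Partitions the genome into `bin_size`-bp bins and counts uniquely
#' mapped target reads by 5' position (`bin = floor(pos / bin_size)`,
#' half-open bins). Only `target_unique` records contribute; the bin total
#' equals the unique target read count.
#'
#' @param reads a `MappedReadSet`.
#' @param layout a [make_genome_layout()] object.
#' @param bin_size bin width in bp (default 10).
#' @return a `raw_counts` [binned_track()].
#' @export
bin_reads <- function(reads, layout, bin_size = 10) {
  stopifnot(inherits(layout, "GenomeLayout"))
  keep <- which(reads$status == "target_unique")
  chrom <- reads$chrom[keep]
  pos <- reads$pos[keep]
  if (length(keep)) {
    if (!all(chrom %in% layout$chrom_names)) {
      bad <- keep[which(!(chrom %in% layout$chrom_names))[1L]]
      stop("read ", bad, " on unknown chromosome ", reads$chrom[bad])
    }
    oob <- pos < 0 | pos >= layout$chrom_lengths[chrom]
    if (any(oob))
      stop("read ", keep[which(oob)[1L]],
           " position outside chromosome bounds")
  }
  nb <- ceiling(layout$chrom_lengths / bin_size)
  values <- lapply(layout$chrom_names, function(ch) {
    p <- pos[chrom == ch]
    tabulate(floor(p / bin_size) + 1L, nbins = nb[[ch]])
  })
  names(values) <- layout$chrom_names
  binned_track(values, layout, bin_size, state = "raw_counts",
               provenance = list(sample_id = attr(reads, "sample_id"),
                                 n_target_unique = length(keep)))
}

#' Calibrate a ChIP track against the untagged control
#'
#' Produces the calibrated read depth: each track is placed on a
#' depth-independent scale (reads per million target-unique reads, the
#' `normalized` state) and multiplied by its sample's SF2; the normalized
#' untagged signal is then subtracted bin by bin. Because SF1 is itself
#' the target/spike read ratio, the result is proportional to
#' `counts / spike_reads` — the spike-calibrated occupancy — up to the
#' shared untagged-coverage constant, and is invariant to sequencing
#' depth. Negative values are retained.
#'
#' `scale = "none"` skips the per-million normalization and applies SF2 to
#' the raw bin values directly (the literal printed arithmetic; only
#' appropriate when libraries are depth-matched).
#'
#' @param chip,untagged `raw_counts` [binned_track()]s on the same grid.
#' @param sf_chip,sf_untagged [compute_scaling()] factors for the two
#'   samples.
#' @param scale `"rpm"` (default) or `"none"`.
#' @return a `calibrated` [binned_track()].
#' @export
calibrate <- function(chip, untagged, sf_chip, sf_untagged,
                      scale = c("rpm", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(chip, "BinnedTrack"), inherits(untagged, "BinnedTrack"),
            inherits(sf_chip, "ScalingFactors"),
            inherits(sf_untagged, "ScalingFactors"))
  if (!same_grid(chip, untagged))
    stop("chip and untagged tracks are on different layouts or bin sizes")
  norm <- function(track) {
    if (scale == "none") return(track$values)
    tot <- track_total(track)
    if (tot <= 0) stop("cannot normalize an empty track")
    lapply(track$values, function(v) v / tot * 1e6)
  }
  cv <- norm(chip)
  uv <- norm(untagged)
  values <- mapply(function(a, b) a * sf_chip$sf2 - b * sf_untagged$sf2,
                   cv, uv, SIMPLIFY = FALSE)
  binned_track(values, chip$layout, chip$bin_size, state = "calibrated",
               provenance = list(chip = chip$provenance$sample_id,
                                 untagged = untagged$provenance$sample_id,
                                 sf2_chip = sf_chip$sf2,
                                 sf2_untagged = sf_untagged$sf2,
                                 scale = scale))
}

#' Average replicate tracks
#'
#' Per-bin arithmetic mean of tracks with identical layout, bin size and
#' state (the calibrated depths of two biological replicates, typically).
#'
#' @param tracks list of [binned_track()]s.
#' @return a [binned_track()] of the same state.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks to average")
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!same_grid(ref, t)) stop("tracks are on different grids")
    if (!identical(ref$state, t$state))
      stop("tracks are in different states")
  }
  values <- lapply(names(ref$values), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)
  })
  names(values) <- names(ref$values)
  binned_track(values, ref$layout, ref$bin_size, state = ref$state,
               provenance = list(
                 averaged = lapply(tracks,
                                   function(t) t$provenance$sample_id %||%
                                     t$provenance)))
}

# Bin centers in bp; the final (possibly short) bin uses its true center.
bin_centers <- function(n, bin_size, chrom_len) {
  ctr <- (seq_len(n) - 0.5) * bin_size
  ctr[n] <- ((n - 1) * bin_size + chrom_len) / 2
  ctr
}

#' Smooth a track with a Gaussian kernel
#'
#' Genome-wide Nadaraya-Watson smoothing at each bin center with a
#' Gaussian kernel whose quartiles sit at +/- 0.25 * bandwidth
#' (`sd = 0.25 * bandwidth / qnorm(0.75)`, the convention of the classic
#' kernel-smoother interface), with weights renormalized over the
#' available bins at chromosome edges. Computed by FFT convolution with
#' the kernel truncated at 8 standard deviations (relative truncation
#' error < 1e-13); bins within kernel range of a short final bin are
#' recomputed by direct summation at the true bin centers.
#'
#' @param track a [binned_track()].
#' @param bandwidth kernel bandwidth in bp (default 1000).
#' @return a `smoothed` [binned_track()].
#' @export
smooth_track <- function(track, bandwidth = 1000) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive")
  bs <- track$bin_size
  sd <- 0.25 * bandwidth / qnorm(0.75)
  half <- max(1L, as.integer(ceiling(8 * sd / bs)))
  kern <- dnorm(seq(-half, half) * bs, 0, sd)
  values <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- length(v)
    L <- track$layout$chrom_lengths[[ch]]
    if (n == 1L) return(v)
    num <- conv_center(v, kern)
    den <- conv_center(rep(1, n), kern)
    out <- num / den
    # exact handling of a short final bin: its center shifts, affecting
    # every bin within kernel range; recompute those directly
    if (L %% bs != 0) {
      ctr <- bin_centers(n, bs, L)
      idx <- seq.int(max(1L, n - half), n)
      for (i in idx) {
        j <- seq.int(max(1L, i - half), min(n, i + half))
        w <- dnorm(ctr[j] - ctr[i], 0, sd)
        out[i] <- sum(w * v[j]) / sum(w)
      }
    }
    out
  })
  names(values) <- names(track$values)
  binned_track(values, track$layout, bs, state = "smoothed",
               provenance = c(track$provenance, list(bandwidth = bandwidth)))
}

# Central slice of the linear convolution of x with symmetric kernel k
# (length 2*half+1): result[i] = sum_j x[j] * k[i - j + half + 1].
conv_center <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  full <- convolve(x, rev(k), type = "open")
  full[(half + 1L):(half + length(x))]
}
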