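#' Peak-calling parameters
#'
#' @param p_max Poisson p-value retention threshold; peaks with
#'   `p > p_max` are filtered out (default `1e-5`).
#' @param merge_gap maximum bp between significant bins merged into one
#'   peak (default 100).
#' @param min_width minimum peak width in bp (default 50).
#' @param local_lambda_windows window sizes in bp over which the local
#'   control background is estimated (default 1, 5 and 10 kb).
#' @return a list of class `PeakCallingParams`.
#' @export
peak_params <- function(p_max = 1e-5, merge_gap = 100, min_width = 50,
                        local_lambda_windows = c(1000, 5000, 10000)) {
  if (!is.finite(p_max) || p_max <= 0 || p_max >= 1)
    stop("p_max must be in (0, 1)")
  if (merge_gap < 0 || min_width < 0)
    stop("merge_gap and min_width must be nonnegative")
  if (any(local_lambda_windows <= 0))
    stop("local lambda windows must be positive")
  structure(list(p_max = p_max, merge_gap = merge_gap,
                 min_width = min_width,
                 local_lambda_windows = local_lambda_windows),
            class = "PeakCallingParams")
}

new_peak_set <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"))
}

#' Call peaks with a local-Poisson model
#'
#' A self-contained implementation of the algorithmic core of
#' model-based ChIP-seq peak callers: for each bin, a local background
#' rate `lambda` is the depth-scaled maximum of the control's mean
#' coverage over several window sizes and its genome-wide mean; the bin
#' p-value is the Poisson upper tail `P(X >= obs | lambda)`. Significant
#' bins (`p <= p_max`) within `merge_gap` bp are merged into peaks; the
#' peak p-value is the minimum bin p-value, the summit the highest-count
#' bin, and q-values come from Benjamini-Hochberg correction over all
#' bins. Calling operates on raw pooled counts with the untagged sample
#' as control; without a control a uniform background (the ChIP track's
#' genome-wide mean) is used.
#'
#' @param chip_counts raw-count [binned_track()] (replicate-pooled ChIP).
#' @param control_counts optional raw-count [binned_track()] (untagged).
#' @param params a [peak_params()] list.
#' @return a `PeakSet` data.frame with columns
#'   `chrom, start, end, summit, p_value, q_value, label`.
#' @export
call_peaks <- function(chip_counts, control_counts = NULL,
                       params = peak_params()) {
  stopifnot(inherits(chip_counts, "BinnedTrack"),
            inherits(params, "PeakCallingParams"))
  bs <- chip_counts$bin_size
  total_chip <- track_total(chip_counts)
  if (total_chip <= 0) stop("empty ChIP track")
  if (!is.null(control_counts)) {
    stopifnot(inherits(control_counts, "BinnedTrack"))
    if (!same_grid(chip_counts, control_counts))
      stop("chip and control tracks are on different grids")
    total_ctrl <- track_total(control_counts)
    if (total_ctrl <= 0) control_counts <- NULL
  }
  chip_mean <- total_chip / sum(lengths(chip_counts$values))
  ratio <- if (is.null(control_counts)) 1 else total_chip / total_ctrl
  ctrl_mean <- if (is.null(control_counts)) chip_mean else
    total_ctrl / sum(lengths(control_counts$values))

  chroms <- sort(names(chip_counts$values))
  all_p <- list()
  for (ch in chroms) {
    v <- chip_counts$values[[ch]]
    if (is.null(control_counts)) {
      lam <- rep(chip_mean, length(v))
    } else {
      cv <- control_counts$values[[ch]]
      lam <- rep(ctrl_mean, length(v))
      for (w in params$local_lambda_windows)
        lam <- pmax(lam, running_mean(cv, max(1L, round(w / bs))))
      lam <- lam * ratio
    }
    all_p[[ch]] <- list(p = ppois(v - 1, lam, lower.tail = FALSE), v = v)
  }
  q_all <- p.adjust(unlist(lapply(all_p, `[[`, "p"), use.names = FALSE),
                    method = "BH")
  offs <- cumsum(c(0, vapply(all_p, function(x) length(x$p), 0)))
  names(offs) <- c(chroms, "end")

  peaks <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    p <- all_p[[ch]]$p
    v <- all_p[[ch]]$v
    q <- q_all[(offs[ci] + 1):(offs[ci] + length(p))]
    sig <- which(p <= params$p_max & v > 0)
    if (!length(sig)) next
    gap_bins <- floor(params$merge_gap / bs)
    grp <- cumsum(c(1L, diff(sig) > gap_bins + 1L))
    L <- chip_counts$layout$chrom_lengths[[ch]]
    for (g in unique(grp)) {
      idx <- sig[grp == g]
      start <- (idx[1L] - 1L) * bs
      end <- min(idx[length(idx)] * bs, L)
      if (end - start < params$min_width) next
      span <- idx[1L]:idx[length(idx)]
      smt_bin <- span[which.max(v[span])]
      best <- idx[which.min(p[idx])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end,
        summit = min((smt_bin - 1L) * bs + bs %/% 2L, L - 1L),
        p_value = p[best], q_value = q[best],
        label = NA_character_, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               summit = numeric(0), p_value = numeric(0),
               q_value = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
  new_peak_set(df)
}

#' Peak width summary
#'
#' @param peaks a `PeakSet`.
#' @return list with `median`, `mean` and the vector of `widths` (bp).
#' @export
peak_width_stats <- function(peaks) {
  if (nrow(peaks) == 0L) stop("empty peak set")
  w <- peaks$end - peaks$start
  list(median = median(w), mean = mean(w), widths = w)
}

PEAK_LABELS <- c("Spo11", "Red1", "Centromere")
CLASS_TO_LABEL <- c(hotspot = "Spo11", axis = "Red1",
                    centromere = "Centromere")

all_venn_labels <- function() {
  combos <- unlist(lapply(1:3, function(k)
    apply(utils::combn(PEAK_LABELS, k), 2, paste, collapse = "+")))
  c(combos, "Nil")
}

#' Classify peaks against feature maps
#'
#' Venn-style annotation: a peak receives every feature class it overlaps
#' by at least 1 bp (hotspot -> `Spo11`, axis -> `Red1`, centromere ->
#' `Centromere`); a peak overlapping no feature is `Nil`. Each peak is
#' counted once under its exact label combination, so the category counts
#' partition the peak set.
#'
#' @param peaks a `PeakSet`.
#' @param features a [feature_set()].
#' @return list with `peaks` (labelled `PeakSet`) and `category_counts`
#'   (named integer vector over all 8 Venn categories).
#' @export
annotate_peaks <- function(peaks, features) {
  hit <- sapply(names(CLASS_TO_LABEL), function(cl)
    overlaps_any(peaks, features[features$class == cl, , drop = FALSE]))
  if (nrow(peaks) == 1L) hit <- matrix(hit, nrow = 1L,
                                       dimnames = list(NULL,
                                                       names(CLASS_TO_LABEL)))
  labels <- if (nrow(peaks) == 0L) character(0) else
    apply(hit, 1L, function(h) {
      lab <- CLASS_TO_LABEL[names(h)[h]]
      if (length(lab)) paste(lab[order(match(lab, PEAK_LABELS))],
                             collapse = "+") else "Nil"
    })
  peaks$label <- labels
  counts <- table(factor(labels, levels = all_venn_labels()))
  list(peaks = new_peak_set(peaks),
       category_counts = setNames(as.integer(counts), names(counts)))
}

#' Fraction of peaks overlapping another peak set
#'
#' Asymmetric: the fraction of `a`-peaks overlapping at least one `b`-peak
#' by at least 1 bp.
#'
#' @param a,b `PeakSet`s.
#' @return value in `[0, 1]`.
#' @export
peakset_overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L) stop("empty reference peak set")
  mean(overlaps_any(a, b))
}

#' Fold enrichment over the untagged control in windows
#'
#' Per window, the ratio of library-size-normalized (reads-per-million)
#' ChIP signal to untagged signal, each stabilized with a pseudocount.
#' A window's signal is the sum of all bins its span touches.
#'
#' @param chip_counts,untagged_counts raw-count [binned_track()]s.
#' @param windows data.frame with columns `chrom, start, end`.
#' @param pseudocount added to both RPM values (default 0.5).
#' @return numeric vector of per-window fold enrichment.
#' @export
fold_enrichment <- function(chip_counts, untagged_counts, windows,
                            pseudocount = 0.5) {
  stopifnot(inherits(chip_counts, "BinnedTrack"),
            inherits(untagged_counts, "BinnedTrack"))
  if (!same_grid(chip_counts, untagged_counts))
    stop("tracks are on different grids")
  bs <- chip_counts$bin_size
  lens <- chip_counts$layout$chrom_lengths
  if (!all(windows$chrom %in% names(lens)) ||
      any(windows$start < 0) || any(windows$end > lens[windows$chrom]))
    stop("window out of genome bounds")
  win_sum <- function(track) {
    vapply(seq_len(nrow(windows)), function(i) {
      v <- track$values[[windows$chrom[i]]]
      b0 <- floor(windows$start[i] / bs) + 1L
      b1 <- floor((windows$end[i] - 1) / bs) + 1L
      sum(v[b0:b1])
    }, 0)
  }
  rpm_c <- win_sum(chip_counts) / track_total(chip_counts) * 1e6
  rpm_u <- win_sum(untagged_counts) / track_total(untagged_counts) * 1e6
  (rpm_c + pseudocount) / (rpm_u + pseudocount)
}

#' Average signal profile around aligned centers
#'
#' Aligns fixed-width windows (`+/- flank` bp) on the given centers and
#' averages the track bin values across them (e.g. a metaprofile over the
#' top DSB hotspots). Windows extending past a chromosome end are
#' dropped.
#'
#' @param track a [binned_track()].
#' @param centers data.frame with columns `chrom, pos` (bp).
#' @param flank half-window in bp (default 500).
#' @return numeric vector of length `2 * flank / bin_size`: the mean
#'   signal per bin offset.
#' @export
metaprofile <- function(track, centers, flank = 500) {
  stopifnot(inherits(track, "BinnedTrack"))
  bs <- track$bin_size
  nf <- as.integer(flank %/% bs)
  if (nf < 1L) stop("flank smaller than one bin")
  rows <- list()
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    cb <- floor(centers$pos[i] / bs) + 1L
    lo <- cb - nf
    hi <- cb + nf - 1L
    if (lo < 1L || hi > length(v)) next
    rows[[length(rows) + 1L]] <- v[lo:hi]
  }
  if (!length(rows)) stop("no usable centers (all windows clipped)")
  colMeans(do.call(rbind, rows))
}
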