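#' Occupancy model for the read simulator
#'
#' Parameterizes the generative model behind [simulate_experiment()]:
#' a uniform nonspecific background plus feature-centered enrichment, a
#' fixed-ratio spike-in genome, a truncated-normal fragment-length model
#' and a mapping-ambiguity rate.
#'
#' The per-hotspot rate multiplier is
#' `enrichment["hotspot"] * (strength/s0)^strength_coupling *
#' (snp/d0)^snp_coupling`, where `s0` is the geometric-mean hotspot
#' strength and `d0` the genome-mean SNP density, so couplings of either
#' sign redistribute signal across hotspots without changing the overall
#' enrichment scale. Axis/centromere/coldspot sites use their class
#' multiplier directly. Multipliers below 1 are treated as 1 (depletion
#' below background is not modelled).
#'
#' `spike_fraction` is the expected spike-in read share of an
#' enrichment-free (untagged) sample: spike chromatin is pulled down
#' nonspecifically at a fixed per-cell ratio, so tagged samples — whose
#' specific enrichment adds target material — realize a lower spike share.
#' This is what makes the spike-in ratio report IP efficiency and
#' occupancy rather than sequencing depth.
#'
#' @param background_rate nonspecific rate in reads per bp (relative
#'   units; only ratios matter).
#' @param enrichment named multipliers per feature class.
#' @param strength_coupling exponent linking hotspot enrichment to
#'   strength (positive prefers strong hotspots, negative weak ones).
#' @param snp_coupling exponent linking hotspot enrichment to local SNP
#'   density.
#' @param fragment_mean,fragment_sd fragment-length model in bp; lengths
#'   are normal truncated to `[100, 1000]` bp (sonication to ~300-400 bp).
#' @param spike_fraction expected spike read fraction of an untagged
#'   sample, in `[0, 1)`; default 1/11 emulates a 1:10 spike:target cell
#'   mixture with equal nonspecific recovery.
#' @param ambiguous_rate fraction of target reads flagged as ambiguously
#'   mapped, in `[0, 1)`.
#' @return a list of class `OccupancyModel`.
#' @export
occupancy_model <- function(background_rate = 0.01,
                            enrichment = c(hotspot = 20, axis = 10,
                                           centromere = 10, coldspot = 1),
                            strength_coupling = 0,
                            snp_coupling = 0,
                            fragment_mean = 350, fragment_sd = 25,
                            spike_fraction = 1 / 11,
                            ambiguous_rate = 0.05) {
  if (!is.finite(background_rate) || background_rate <= 0)
    stop("background_rate must be positive")
  enr <- c(hotspot = 1, axis = 1, centromere = 1, coldspot = 1)
  enr[names(enrichment)] <- enrichment
  if (any(!is.finite(enr)) || any(enr < 0))
    stop("enrichment multipliers must be nonnegative")
  if (spike_fraction < 0 || spike_fraction >= 1)
    stop("spike_fraction must be in [0, 1)")
  if (ambiguous_rate < 0 || ambiguous_rate >= 1)
    stop("ambiguous_rate must be in [0, 1)")
  if (fragment_mean <= 0 || fragment_sd <= 0)
    stop("fragment model parameters must be positive")
  structure(list(background_rate = background_rate, enrichment = enr,
                 strength_coupling = strength_coupling,
                 snp_coupling = snp_coupling,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 spike_fraction = spike_fraction,
                 ambiguous_rate = ambiguous_rate),
            class = "OccupancyModel")
}

READ_STATUSES <- c("target_unique", "spike_unique", "ambiguous", "unmapped")

new_mapped_read_set <- function(df, sample_id, role = NA_character_,
                                truth = NULL) {
  structure(df, sample_id = sample_id, role = role, ground_truth = truth,
            class = c("MappedReadSet", "data.frame"))
}

# Truncated-normal sampling by inverse CDF (exact, vectorized).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Local SNP density (per kb) around feature midpoints, floored to avoid a
# zero base for negative couplings.
local_snp_density <- function(features, snps, flank = 500, floor_per_kb = 0.1) {
  mid <- floor((features$start + features$end) / 2)
  dens <- numeric(nrow(features))
  for (ch in unique(features$chrom)) {
    i <- features$chrom == ch
    pos <- snps[[ch]] %||% integer(0)
    cnt <- count_in_intervals(pos, mid[i] - flank, mid[i] + flank)
    dens[i] <- cnt / (2 * flank / 1000)
  }
  pmax(dens, floor_per_kb)
}

# Per-feature rate multipliers under a model (>= 1 after clamping).
feature_multipliers <- function(features, model, snps = NULL) {
  m <- rep(1, nrow(features))
  for (cl in FEATURE_CLASSES) {
    i <- features$class == cl
    if (!any(i)) next
    m[i] <- model$enrichment[[cl]]
  }
  hot <- features$class == "hotspot"
  if (any(hot)) {
    if (model$strength_coupling != 0) {
      s <- features$strength[hot]
      s0 <- exp(mean(log(pmax(s, .Machine$double.eps))))
      m[hot] <- m[hot] * (s / s0)^model$strength_coupling
    }
    if (model$snp_coupling != 0) {
      if (is.null(snps))
        stop("snp_coupling != 0 requires a SNP map")
      d <- local_snp_density(features, snps)
      d0 <- exp(mean(log(d)))
      m[hot] <- m[hot] * (d / d0)^model$snp_coupling
    }
  }
  pmax(m, 1)
}

#' Simulate a calibrated ChIP-seq experiment
#'
#' Generates mapped-read records (no sequences; mapping status is a label)
#' for a set of samples under an [occupancy_model()]. Tagged ChIP samples
#' draw fragment midpoints from a mixture of uniform background and
#' feature-centered enrichment; untagged controls use background only.
#' Read 5' positions are derived from the fragment-length model (5' end of
#' the fragment on a Bernoulli(0.5) strand). Spike-in reads carry no
#' target position; `ambiguous_rate` of target reads are flagged
#' ambiguous (they retain a position but are excluded from unique-read
#' counting).
#'
#' A ground-truth sidecar (attribute `ground_truth` on each sample) records
#' per-feature expected and observed fragment-midpoint counts plus the
#' expected spike share, for parameter-recovery tests.
#'
#' @param layout a [make_genome_layout()] object.
#' @param features a [feature_set()] (may be empty for pure background).
#' @param model an [occupancy_model()].
#' @param n_reads total reads per sample; scalar or per-sample vector.
#' @param samples data.frame with columns `sample_id` and `role`
#'   (`"chip"` or `"untagged"`); default two ChIP replicates plus one
#'   untagged control.
#' @param snps optional [plant_snps()] map (needed when
#'   `snp_coupling != 0`).
#' @param occupancy_scale multiplier on specific occupancy (the
#'   enrichment-above-background mass); scalar or per-sample. Emulates
#'   genuine occupancy differences between samples, which the spike-in
#'   calibration is designed to recover.
#' @param seed integer seed.
#' @return named list of `MappedReadSet` data.frames (columns
#'   `chrom, pos, strand, status`), one per sample.
#' @examples
#' layout <- make_genome_layout(5e5)
#' fs <- plant_features(layout, n_hotspots = 10, seed = 1)
#' reads <- simulate_experiment(layout, fs, occupancy_model(),
#'                              n_reads = 2e4, seed = 1)
#' sapply(reads, nrow)
#' @export
simulate_experiment <- function(layout, features, model, n_reads,
                                samples = NULL, snps = NULL,
                                occupancy_scale = 1, seed = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"),
            inherits(model, "OccupancyModel"))
  if (is.null(samples))
    samples <- data.frame(
      sample_id = c("chip_rep1", "chip_rep2", "untagged"),
      role = c("chip", "chip", "untagged"), stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(samples)) ||
      !all(samples$role %in% c("chip", "untagged")) ||
      anyDuplicated(samples$sample_id))
    stop("invalid sample specification")
  ns <- nrow(samples)
  n_reads <- rep_len(as.numeric(n_reads), ns)
  if (any(n_reads <= 0)) stop("n_reads must be positive")
  occupancy_scale <- rep_len(as.numeric(occupancy_scale), ns)
  if (any(occupancy_scale < 0)) stop("occupancy_scale must be nonnegative")
  has_enr <- any(model$enrichment != 1) || model$strength_coupling != 0 ||
    model$snp_coupling != 0
  if (nrow(features) == 0L && has_enr && any(samples$role == "chip"))
    stop("empty feature set with nonzero class enrichment")

  G <- genome_size(layout)
  B <- model$background_rate
  mult <- if (nrow(features)) feature_multipliers(features, model, snps)
          else numeric(0)
  widths <- features$end - features$start
  # nonspecific spike mass relative to target background mass
  spike_mass <- model$spike_fraction / (1 - model$spike_fraction) * G * B

  with_seed(seed, {
    out <- vector("list", ns)
    names(out) <- samples$sample_id
    for (si in seq_len(ns)) {
      role <- samples$role[si]
      n <- n_reads[si]
      extra <- if (role == "chip" && nrow(features))
        occupancy_scale[si] * (mult - 1) * widths * B
      else rep(0, nrow(features))
      target_mass <- G * B + sum(extra)
      p_spike <- spike_mass / (spike_mass + target_mass)
      n_spike <- rbinom(1L, n, p_spike)
      n_target <- n - n_spike

      # component draw: background + one extra component per feature
      comp_w <- c(G * B, extra)
      counts <- as.vector(rmultinom(1L, n_target, comp_w))
      n_bg <- counts[1L]
      mid_chrom <- character(0)
      mid_pos <- numeric(0)
      if (n_bg > 0L) {
        ci <- sample.int(length(layout$chrom_names), n_bg, replace = TRUE,
                         prob = layout$chrom_lengths)
        mid_chrom <- layout$chrom_names[ci]
        mid_pos <- floor(runif(n_bg, 0, layout$chrom_lengths[ci]))
      }
      if (length(extra)) {
        fi <- rep.int(seq_along(extra), counts[-1L])
        if (length(fi)) {
          mid_chrom <- c(mid_chrom, features$chrom[fi])
          mid_pos <- c(mid_pos,
                       floor(runif(length(fi), features$start[fi],
                                   features$end[fi])))
        }
      }
      # fragment model: 5' position is the fragment end picked by strand
      fl <- rnorm_trunc(n_target, model$fragment_mean, model$fragment_sd,
                        100, 1000)
      strand <- ifelse(runif(n_target) < 0.5, "+", "-")
      pos5 <- ifelse(strand == "+", round(mid_pos - fl / 2),
                     round(mid_pos + fl / 2))
      pos5 <- pmin(pmax(pos5, 0), layout$chrom_lengths[mid_chrom] - 1)
      status <- ifelse(runif(n_target) < model$ambiguous_rate,
                       "ambiguous", "target_unique")
      df <- data.frame(
        chrom = c(mid_chrom, rep(NA_character_, n_spike)),
        pos = c(pos5, rep(NA_real_, n_spike)),
        strand = c(strand, rep(NA_character_, n_spike)),
        status = c(status, rep("spike_unique", n_spike)),
        stringsAsFactors = FALSE)

      truth <- NULL
      if (nrow(features)) {
        # expected midpoints per feature window: uniform background plus
        # every enrichment component overlapping the window (features of
        # different classes may overlap; their extra mass is shared
        # proportionally to the overlap width)
        rate <- B * widths
        if (any(extra > 0)) {
          gr <- granges_pair(features, features)
          ov <- GenomicRanges::findOverlaps(gr$a, gr$b, minoverlap = 1L)
          qh <- S4Vectors::queryHits(ov)
          sh <- S4Vectors::subjectHits(ov)
          ow <- IRanges::width(IRanges::pintersect(
            IRanges::ranges(gr$a)[qh], IRanges::ranges(gr$b)[sh]))
          for (k in seq_along(qh))
            rate[qh[k]] <- rate[qh[k]] + extra[sh[k]] * ow[k] / widths[sh[k]]
        }
        exp_mid <- n_target * rate / target_mass
        obs_mid <- integer(nrow(features))
        for (ch in unique(features$chrom)) {
          i <- features$chrom == ch
          pos <- sort(mid_pos[mid_chrom == ch])
          obs_mid[i] <- count_in_intervals(pos, features$start[i],
                                           features$end[i])
        }
        truth <- data.frame(name = features$name, class = features$class,
                            expected_midpoints = exp_mid,
                            observed_midpoints = obs_mid,
                            stringsAsFactors = FALSE)
      }
      truth <- list(per_feature = truth, expected_spike_fraction = p_spike,
                    n_target = n_target, n_spike = n_spike)
      out[[si]] <- new_mapped_read_set(df, samples$sample_id[si], role,
                                       truth)
    }
    out
  })
}
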