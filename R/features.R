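FEATURE_CLASSES <- c("hotspot", "axis", "centromere", "coldspot")

#' Construct a feature set
#'
#' A `FeatureSet` is a data.frame of classed genomic intervals: DSB hotspots
#' (with a strength score — the Spo11-oligo count proxy), chromosome-axis
#' sites, centromeres and coldspots. Intervals are 0-based half-open;
#' same-class intervals must not overlap; `strength` is present iff the
#' class is `hotspot`.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param class one of `"hotspot"`, `"axis"`, `"centromere"`, `"coldspot"`.
#' @param strength nonnegative hotspot strength (NA for other classes).
#' @param name optional labels; autogenerated per class when missing.
#' @param layout optional [make_genome_layout()] for bounds validation.
#' @return a data.frame of class `FeatureSet` with columns
#'   `chrom, start, end, class, strength, name`.
#' @export
feature_set <- function(chrom, start, end, class, strength = NA_real_,
                        name = NA_character_, layout = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   class = rep_len(as.character(class), n),
                   strength = rep_len(as.numeric(strength), n),
                   name = rep_len(as.character(name), n),
                   stringsAsFactors = FALSE)
  validate_feature_set(df, layout)
}

validate_feature_set <- function(df, layout = NULL) {
  if (nrow(df)) {
    if (!all(df$class %in% FEATURE_CLASSES))
      stop("unknown feature class: ",
           paste(setdiff(df$class, FEATURE_CLASSES), collapse = ", "))
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("feature intervals must satisfy 0 <= start < end")
    if (!is.null(layout)) {
      if (!all(df$chrom %in% layout$chrom_names))
        stop("feature on unknown chromosome")
      if (any(df$end > layout$chrom_lengths[df$chrom]))
        stop("feature interval beyond chromosome end")
    }
    hot <- df$class == "hotspot"
    if (any(hot & (is.na(df$strength) | df$strength < 0)))
      stop("hotspots require a nonnegative strength")
    if (any(!hot & !is.na(df$strength)))
      stop("strength is only defined for hotspots")
    df <- df[order(df$chrom, df$start, df$class), , drop = FALSE]
    for (cl in unique(df$class)) {
      d <- df[df$class == cl, , drop = FALSE]
      for (ch in unique(d$chrom)) {
        e <- d[d$chrom == ch, , drop = FALSE]
        if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
          stop("overlapping ", cl, " intervals on ", ch)
      }
    }
    miss <- is.na(df$name)
    if (any(miss))
      df$name[miss] <- paste0(df$class[miss], "_",
                              ave(seq_len(nrow(df)), df$class,
                                  FUN = seq_along)[miss])
    rownames(df) <- NULL
  }
  class(df) <- c("FeatureSet", "data.frame")
  df
}

# Allocate per-class feature counts across chromosomes. `n` may be a scalar
# (chromosomes drawn with probability proportional to length) or a vector
# over chromosomes. Centromeres are placed one per chromosome, in order.
allocate_counts <- function(n, layout, class) {
  k <- length(layout$chrom_names)
  if (length(n) == k && k > 1L) return(as.integer(n))
  if (length(n) != 1L) stop("count for ", class,
                            " must be scalar or one per chromosome")
  n <- as.integer(n)
  if (n == 0L) return(integer(k))
  if (class == "centromere") {
    if (n > k) stop("at most one centromere per chromosome")
    return(as.integer(seq_len(k) <= n))
  }
  tabulate(sample.int(k, n, replace = TRUE,
                      prob = layout$chrom_lengths), nbins = k)
}

# Place k intervals of width w on [0, L) with pairwise gaps >= gap,
# uniformly over valid configurations (sorted-uniform spacing construction).
place_intervals <- function(k, w, gap, L) {
  if (k == 0L) return(numeric(0))
  slack <- L - k * w - (k - 1) * gap
  if (slack < 0)
    stop("features do not fit: ", k, " x ", w,
         " bp with gap ", gap, " bp exceed chromosome of ", L, " bp")
  u <- sort(runif(k, 0, slack))
  floor(u + (seq_len(k) - 1L) * (w + gap))
}

#' Plant classed features on a genome
#'
#' Generates a seeded random [feature_set()] with the requested number of
#' DSB hotspots, axis sites, centromeres and coldspots. Same-class
#' intervals are separated by at least `min_gap` bp; hotspot strengths are
#' drawn from `strength_sampler` (default log-normal, emulating the
#' heavy-tailed Spo11-oligo count distribution). Centromeres are placed one
#' per chromosome.
#'
#' @param layout a [make_genome_layout()] object.
#' @param n_hotspots,n_axis,n_centromere,n_coldspots counts per class;
#'   scalar (distributed across chromosomes proportional to length) or a
#'   vector with one count per chromosome.
#' @param widths named list/vector of interval widths in bp per class.
#' @param strength_sampler `function(n)` returning n positive strengths;
#'   default `rlnorm(n, meanlog = 5, sdlog = 1.2)`.
#' @param min_gap minimum bp between same-class intervals.
#' @param seed integer seed (RNG state is restored afterwards).
#' @return a `FeatureSet`.
#' @examples
#' layout <- make_genome_layout(c(1e6, 5e5))
#' fs <- plant_features(layout, n_hotspots = 25, n_coldspots = 25, seed = 1)
#' table(fs$class)
#' @export
plant_features <- function(layout, n_hotspots = 0, n_axis = 0,
                           n_centromere = 0, n_coldspots = 0,
                           widths = c(hotspot = 500, axis = 800,
                                      centromere = 200, coldspot = 1000),
                           strength_sampler = NULL, min_gap = 1000,
                           seed = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (is.null(strength_sampler))
    strength_sampler <- function(n) rlnorm(n, meanlog = 5, sdlog = 1.2)
  widths <- unlist(widths)
  counts <- list(hotspot = n_hotspots, axis = n_axis,
                 centromere = n_centromere, coldspot = n_coldspots)
  with_seed(seed, {
    rows <- list()
    for (cl in FEATURE_CLASSES) {
      per_chrom <- allocate_counts(counts[[cl]], layout, cl)
      w <- widths[[cl]]
      for (i in seq_along(layout$chrom_names)) {
        k <- per_chrom[i]
        if (k == 0L) next
        starts <- place_intervals(k, w, min_gap, layout$chrom_lengths[i])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = layout$chrom_names[i], start = starts, end = starts + w,
          class = cl, strength = NA_real_, name = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 class = character(0), strength = numeric(0),
                 name = character(0), stringsAsFactors = FALSE)
    hot <- which(df$class == "hotspot")
    if (length(hot)) {
      s <- strength_sampler(length(hot))
      if (any(!is.finite(s)) || any(s < 0))
        stop("strength_sampler produced invalid strengths")
      df$strength[hot] <- s
    }
    validate_feature_set(df, layout)
  })
}

#' Plant heterozygous SNP markers
#'
#' Generates a seeded `SNPMap` (per-chromosome sorted unique positions) with
#' Poisson-distributed marker counts. `density_per_kb` is either a single
#' genome-wide density or a data.frame with columns
#' `chrom, start, end, density_per_kb` of region-specific densities;
#' uncovered regions fall back to `baseline_per_kb`.
#'
#' @param layout a [make_genome_layout()] object.
#' @param density_per_kb scalar density (SNPs per kb) or region data.frame.
#' @param baseline_per_kb density outside listed regions (regional mode).
#' @param seed integer seed.
#' @return object of class `SNPMap`: a named list of sorted integer
#'   position vectors (0-based), with the layout attached as an attribute.
#' @export
plant_snps <- function(layout, density_per_kb = 4, baseline_per_kb = 0,
                       seed = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  regional <- is.data.frame(density_per_kb)
  if (!regional && (!is.finite(density_per_kb) || density_per_kb < 0))
    stop("density must be nonnegative")
  if (regional && any(density_per_kb$density_per_kb < 0))
    stop("density must be nonnegative")
  if (baseline_per_kb < 0) stop("density must be nonnegative")
  with_seed(seed, {
    out <- lapply(seq_along(layout$chrom_names), function(i) {
      ch <- layout$chrom_names[i]
      L <- layout$chrom_lengths[i]
      segs <- if (!regional) {
        data.frame(start = 0, end = L, d = density_per_kb)
      } else {
        r <- density_per_kb[density_per_kb$chrom == ch, , drop = FALSE]
        r <- r[order(r$start), , drop = FALSE]
        bounds <- sort(unique(pmin(pmax(c(0, r$start, r$end, L), 0), L)))
        s <- bounds[-length(bounds)]
        e <- bounds[-1L]
        d <- rep(baseline_per_kb, length(s))
        for (j in seq_len(nrow(r)))
          d[s >= r$start[j] & e <= r$end[j]] <- r$density_per_kb[j]
        data.frame(start = s, end = e, d = d)
      }
      pos <- unlist(lapply(seq_len(nrow(segs)), function(j) {
        len <- segs$end[j] - segs$start[j]
        if (len <= 0 || segs$d[j] == 0) return(integer(0))
        n <- rpois(1L, segs$d[j] * len / 1000)
        n <- min(n, len)
        if (n == 0L) return(integer(0))
        segs$start[j] + sample.int(len, n) - 1L
      }))
      sort(unique(as.integer(pos)))
    })
    names(out) <- layout$chrom_names
    structure(out, layout = layout, class = "SNPMap")
  })
}

#' Simulate tetrad crossover sites
#'
#' Draws crossover midpoints for `n_tetrads` meioses. Each crossover lands
#' in a DSB hotspot with probability `1 - uniform_frac` (hotspots chosen
#' with probability proportional to `strength^hotspot_weighting`, position
#' uniform within the hotspot) and uniformly on the genome otherwise. The
#' genome-wide crossover rate per tetrad is `rate_per_mb` per Mb.
#'
#' @param features a [feature_set()] with hotspots.
#' @param n_tetrads number of tetrads (stored with the output).
#' @param hotspot_weighting exponent on hotspot strength.
#' @param layout a [make_genome_layout()] object.
#' @param rate_per_mb expected crossovers per tetrad per Mb (default 7.5,
#'   the budding-yeast genome-wide average of ~90 crossovers over ~12 Mb).
#' @param uniform_frac fraction of crossovers placed uniformly at random.
#' @param seed integer seed.
#' @return object of class `CrossoverSet`: data.frame
#'   `tetrad_id, chrom, pos` with attribute `n_tetrads`.
#' @export
simulate_crossovers <- function(features, n_tetrads, layout,
                                hotspot_weighting = 1, rate_per_mb = 7.5,
                                uniform_frac = 0.1, seed = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (n_tetrads < 0) stop("n_tetrads must be nonnegative")
  hot <- features[features$class == "hotspot", , drop = FALSE]
  with_seed(seed, {
    G <- genome_size(layout)
    mean_per_tetrad <- rate_per_mb * G / 1e6
    rows <- list()
    for (t in seq_len(n_tetrads)) {
      n <- rpois(1L, mean_per_tetrad)
      if (n == 0L) next
      from_hot <- nrow(hot) > 0 & runif(n) > uniform_frac
      chrom <- character(n)
      pos <- numeric(n)
      nh <- sum(from_hot)
      if (nh > 0L) {
        wgt <- hot$strength^hotspot_weighting
        idx <- sample.int(nrow(hot), nh, replace = TRUE, prob = wgt)
        chrom[from_hot] <- hot$chrom[idx]
        pos[from_hot] <- floor(runif(nh, hot$start[idx], hot$end[idx]))
      }
      nu <- n - nh
      if (nu > 0L) {
        ci <- sample.int(length(layout$chrom_names), nu, replace = TRUE,
                         prob = layout$chrom_lengths)
        chrom[!from_hot] <- layout$chrom_names[ci]
        pos[!from_hot] <- floor(runif(nu, 0, layout$chrom_lengths[ci]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tetrad_id = t, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(tetrad_id = integer(0), chrom = character(0),
                 pos = numeric(0), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    structure(df, n_tetrads = as.integer(n_tetrads),
              class = c("CrossoverSet", "data.frame"))
  })
}
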