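#' Per-chromosome binding density (RPM/kb)
#'
#' Counts uniquely mapped target reads per chromosome, discarding reads
#' inside the layout's exclusion intervals (e.g. the rDNA array), and
#' expresses density as reads per million mapped reads per kilobase of
#' usable (non-excluded) sequence.
#'
#' @param reads a `MappedReadSet`.
#' @param layout a [make_genome_layout()] object.
#' @param total_mapped library size used for the per-million scaling;
#'   defaults to the sample's unique target read count.
#' @return data.frame with one row per chromosome: `chrom`,
#'   `usable_length` (bp), `reads` (count in usable region) and `density`
#'   (RPM/kb).
#' @export
density_by_chromosome <- function(reads, layout, total_mapped = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  keep <- reads$status == "target_unique"
  chrom <- reads$chrom[keep]
  pos <- reads$pos[keep]
  if (is.null(total_mapped)) total_mapped <- sum(keep)
  if (!is.finite(total_mapped) || total_mapped <= 0)
    stop("total mapped read count must be positive")
  exbp <- excluded_bp(layout)
  ex <- layout$exclusions
  counts <- vapply(layout$chrom_names, function(ch) {
    p <- pos[chrom == ch]
    if (!length(p)) return(0)
    drop <- rep(FALSE, length(p))
    e <- ex[ex$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(e)))
      drop <- drop | (p >= e$start[j] & p < e$end[j])
    sum(!drop)
  }, 0)
  usable <- layout$chrom_lengths - exbp
  data.frame(chrom = layout$chrom_names,
             usable_length = as.numeric(usable),
             reads = as.numeric(counts),
             density = (counts / total_mapped * 1e6) / (usable / 1000),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation with significance
#'
#' Product-moment correlation between chromosome sizes and binding
#' densities (or any paired measurements), with the two-sided p-value
#' from the t-transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with elements `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, the workhorse behind
#' the study's violin/box/density comparisons. The exact null
#' distribution is enumerated over all rank assignments when the combined
#' sample is small (`n_a + n_b <= 12`) and tie-free; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return list with `W` (the Mann-Whitney U statistic of `a`), `p`
#'   (two-sided) and `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4)) # exact p = 1/3
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  comb <- c(a, b)
  no_ties <- length(unique(comb)) == n
  r <- rank(comb)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  use_exact <- switch(mode,
                      auto = n <= 12 && no_ties,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    if (!no_ties) stop("exact mode requires tie-free samples")
    pmf <- exact_u_distribution(na, nb)
    lo <- sum(pmf[seq_len(U + 1L)])              # P(U <= u)
    hi <- sum(pmf[(U + 1L):length(pmf)])         # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    return(list(W = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(comb)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(W = U, p = 1, method = "normal"))
  d <- U - mu
  z <- if (d == 0) 0 else (d - 0.5 * sign(d)) / sqrt(sigma2)
  list(W = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

# Exact Mann-Whitney U pmf over all C(n, na) equally likely rank subsets
# (dynamic programming over the rank-sum distribution). Returns a vector
# of probabilities for U = 0 .. na*nb.
exact_u_distribution <- function(na, nb) {
  # counts[u + 1] = number of ways to achieve U = u
  umax <- na * nb
  counts <- numeric(umax + 1)
  # DP over items: ways to choose from ranks with given U; classic
  # Gaussian binomial coefficient recursion
  dp <- matrix(0, nrow = na + 1, ncol = umax + 1)
  dp[1, 1] <- 1
  for (r in seq_len(na + nb)) {
    for (k in rev(seq_len(na))) {
      shift <- r - k          # adding rank r as k-th chosen element
      if (shift < 0) next
      add <- dp[k, ]
      # U contribution of choosing rank r as the k-th smallest: r - k
      idx <- seq_len(umax + 1 - shift)
      dp[k + 1, idx + shift] <- dp[k + 1, idx + shift] + dp[k, idx]
    }
  }
  counts <- dp[na + 1, ]
  counts / sum(counts)
}

#' Classify hotspots by binding of two proteins
#'
#' A hotspot is bound by a protein iff it overlaps that protein's peak
#' set by at least 1 bp. Hotspots are partitioned into `both`, `A_only`,
#' `B_only` and `neither`, and the strengths (Spo11-oligo proxies) of the
#' A-specific and B-specific hotspots are compared by
#' [wilcoxon_rank_sum()] — the analysis that reveals whether one protein
#' favors weaker DSB hotspots than the other.
#'
#' @param hotspots a [feature_set()] restricted to (or containing)
#'   hotspots with strengths.
#' @param peaks_A,peaks_B `PeakSet`s of the two proteins.
#' @return list with `classes` (data.frame `name, chrom, start, end,
#'   strength, class`) and `comparison` (list `defined, median_A_only,
#'   median_B_only, W, p`, or `defined = FALSE` with a `reason` when a
#'   specific class is empty).
#' @export
classify_hotspot_binding <- function(hotspots, peaks_A, peaks_B) {
  hot <- hotspots[hotspots$class == "hotspot", , drop = FALSE]
  if (nrow(hot) == 0L) stop("no hotspots to classify")
  if (any(is.na(hot$strength))) stop("hotspot strengths are required")
  inA <- overlaps_any(hot, peaks_A)
  inB <- overlaps_any(hot, peaks_B)
  cls <- ifelse(inA & inB, "both",
                ifelse(inA, "A_only", ifelse(inB, "B_only", "neither")))
  classes <- data.frame(name = hot$name, chrom = hot$chrom,
                        start = hot$start, end = hot$end,
                        strength = hot$strength, class = cls,
                        stringsAsFactors = FALSE, row.names = NULL)
  sA <- hot$strength[cls == "A_only"]
  sB <- hot$strength[cls == "B_only"]
  comparison <- if (!length(sA) || !length(sB)) {
    list(defined = FALSE,
         reason = "no hotspots specific to one of the proteins")
  } else {
    wt <- wilcoxon_rank_sum(sA, sB)
    list(defined = TRUE, median_A_only = median(sA),
         median_B_only = median(sB), W = wt$W, p = wt$p)
  }
  list(classes = classes, comparison = comparison)
}

#' SNP density at peaks versus the genome
#'
#' Computes heterozygous-marker density (SNPs per kb) inside each peak
#' and compares it to the genome background, tiled into non-overlapping
#' `tile_size`-bp windows (full tiles only; tiles overlapping layout
#' exclusions are dropped). The comparison is a two-sided
#' [wilcoxon_rank_sum()] of peak densities against tile densities —
#' non-significant when binding is independent of heterozygosity.
#'
#' @param snps a [plant_snps()] map (or any `SNPMap`).
#' @param peaks a `PeakSet`.
#' @param layout a [make_genome_layout()] object.
#' @param tile_size background tile width in bp (default 1000, matching
#'   the per-kb unit).
#' @return list with `per_peak` (data.frame `chrom, start, end, snps,
#'   density`), `genome_mean`, `genome_median`, `tile_densities` and
#'   `test` (the rank-sum result).
#' @export
snp_density_analysis <- function(snps, peaks, layout, tile_size = 1000) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (nrow(peaks) == 0L) stop("empty peak set")
  if (any(peaks$end <= peaks$start)) stop("zero-width peak")
  cnt <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- peaks$chrom == ch
    cnt[i] <- count_in_intervals(snps[[ch]] %||% integer(0),
                                 peaks$start[i], peaks$end[i])
  }
  per_peak <- data.frame(chrom = peaks$chrom, start = peaks$start,
                         end = peaks$end, snps = cnt,
                         density = cnt / ((peaks$end - peaks$start) / 1000),
                         stringsAsFactors = FALSE, row.names = NULL)
  tiles <- list()
  ex <- layout$exclusions
  for (ch in layout$chrom_names) {
    L <- layout$chrom_lengths[[ch]]
    if (L < tile_size) next
    s <- seq(0, L - tile_size, by = tile_size)
    e <- s + tile_size
    keep <- rep(TRUE, length(s))
    exc <- ex[ex$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(exc)))
      keep <- keep & !(s < exc$end[j] & e > exc$start[j])
    if (!any(keep)) next
    tc <- count_in_intervals(snps[[ch]] %||% integer(0), s[keep], e[keep])
    tiles[[ch]] <- tc / (tile_size / 1000)
  }
  tile_d <- unlist(tiles, use.names = FALSE)
  if (!length(tile_d)) stop("no background tiles available")
  list(per_peak = per_peak,
       genome_mean = mean(tile_d),
       genome_median = median(tile_d),
       tile_densities = tile_d,
       test = wilcoxon_rank_sum(per_peak$density, tile_d, mode = "normal"))
}

#' Bin SNP counts into a coverage-style track
#'
#' Counts markers per fixed-width bin (default 100 bp), for visualization
#' alongside binding tracks. Display scalings (e.g. doubling counts) are
#' writer-side options of [write_bedgraph()], never applied here.
#'
#' @param snps a `SNPMap`.
#' @param layout a [make_genome_layout()] object.
#' @param bin_size bin width in bp.
#' @return a raw-count [binned_track()].
#' @export
snp_bin_track <- function(snps, layout, bin_size = 100) {
  nb <- ceiling(layout$chrom_lengths / bin_size)
  values <- lapply(layout$chrom_names, function(ch) {
    p <- snps[[ch]] %||% integer(0)
    tabulate(floor(p / bin_size) + 1L, nbins = nb[[ch]])
  })
  names(values) <- layout$chrom_names
  binned_track(values, layout, bin_size, state = "raw_counts",
               provenance = list(source = "snp_map"))
}

#' Crossover co-occupancy by two peak sets
#'
#' Classifies each crossover site (midpoint +/- `site_window` / 2) by
#' whether it overlaps peaks of protein A, protein B, both or neither
#' (>= 1 bp overlap). Fractions sum to 1.
#'
#' @param crossovers a [simulate_crossovers()] set (or any data.frame
#'   with `chrom, pos`).
#' @param peaks_A,peaks_B `PeakSet`s.
#' @param site_window window width around the crossover midpoint in bp
#'   (default 2000; tetrad crossover resolution).
#' @return list with `fractions` and `counts` (named over
#'   `both, A_only, B_only, neither`) and `n`.
#' @export
crossover_cooccupancy <- function(crossovers, peaks_A, peaks_B,
                                  site_window = 2000) {
  if (nrow(crossovers) == 0L) stop("empty crossover set")
  half <- site_window / 2
  sites <- data.frame(chrom = crossovers$chrom,
                      start = pmax(crossovers$pos - half, 0),
                      end = crossovers$pos + half,
                      stringsAsFactors = FALSE)
  inA <- overlaps_any(sites, peaks_A)
  inB <- overlaps_any(sites, peaks_B)
  cls <- factor(ifelse(inA & inB, "both",
                       ifelse(inA, "A_only",
                              ifelse(inB, "B_only", "neither"))),
                levels = c("both", "A_only", "B_only", "neither"))
  counts <- table(cls)
  list(fractions = setNames(as.numeric(counts) / nrow(sites),
                            names(counts)),
       counts = setNames(as.integer(counts), names(counts)),
       n = nrow(sites))
}

#' ChIP-qPCR fold enrichment
#'
#' Normalizes IP quantities to input DNA, then to the DSB coldspot locus,
#' then to the untagged control:
#' `FE(locus) = [r(locus, tagged) / r(cold, tagged)] /
#' [r(locus, untagged) / r(cold, untagged)]` with `r = ip / input`
#' (replicate measurements of a locus/strain pair are averaged on the
#' ratio scale). The coldspot itself has FE = 1 by construction.
#'
#' @param measurements data.frame with columns `locus`, `strain`
#'   (`"tagged"` or `"untagged"`), `ip_quantity`, `input_quantity`
#'   (positive linear units from standard-curve quantification).
#' @param coldspot_locus name of the coldspot reference locus.
#' @return data.frame `locus, fold_enrichment`.
#' @export
qpcr_enrichment <- function(measurements, coldspot_locus) {
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  need <- c("locus", "strain", "ip_quantity", "input_quantity")
  if (!all(need %in% names(m))) stop("missing qPCR columns")
  if (!all(m$strain %in% c("tagged", "untagged")))
    stop("strain must be 'tagged' or 'untagged'")
  if (any(m$ip_quantity <= 0) || any(m$input_quantity <= 0))
    stop("qPCR quantities must be positive")
  if (!coldspot_locus %in% m$locus) stop("missing coldspot measurements")
  m$ratio <- m$ip_quantity / m$input_quantity
  agg <- stats::aggregate(ratio ~ locus + strain, data = m, FUN = mean)
  get_ratio <- function(locus, strain) {
    v <- agg$ratio[agg$locus == locus & agg$strain == strain]
    if (!length(v)) stop("missing ", strain, " measurement for ", locus)
    v
  }
  loci <- unique(m$locus)
  cold_t <- get_ratio(coldspot_locus, "tagged")
  cold_u <- get_ratio(coldspot_locus, "untagged")
  fe <- vapply(loci, function(lc) {
    (get_ratio(lc, "tagged") / cold_t) / (get_ratio(lc, "untagged") / cold_u)
  }, 0)
  data.frame(locus = loci, fold_enrichment = unname(fe),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Centromere distance of features, compared between groups
#'
#' Distance of each feature midpoint from its chromosome's centromere
#' midpoint (requires exactly one centromere record per chromosome in
#' `features`), with a rank-sum comparison between two groups of
#' features (e.g. hotspots bound uniquely by each of two proteins).
#'
#' @param features a [feature_set()] containing centromeres plus the
#'   features to measure.
#' @param group_labels vector (one per non-centromere feature row, in
#'   `features` order) with exactly two distinct non-NA values; NA rows
#'   are measured but not compared.
#' @return list with `distances` (data.frame `name, chrom, distance,
#'   group`) and `comparison` (rank-sum result plus group medians).
#' @export
centromere_distance <- function(features, group_labels) {
  cen <- features[features$class == "centromere", , drop = FALSE]
  rest <- features[features$class != "centromere", , drop = FALSE]
  if (any(duplicated(cen$chrom)))
    stop("more than one centromere on a chromosome")
  if (length(group_labels) != nrow(rest))
    stop("one group label per non-centromere feature is required")
  missing_cen <- setdiff(unique(rest$chrom), cen$chrom)
  if (length(missing_cen))
    stop("chromosome lacking a centromere record: ",
         paste(missing_cen, collapse = ", "))
  cen_mid <- setNames(floor((cen$start + cen$end) / 2), cen$chrom)
  mid <- floor((rest$start + rest$end) / 2)
  d <- abs(mid - cen_mid[rest$chrom])
  distances <- data.frame(name = rest$name, chrom = rest$chrom,
                          distance = as.numeric(d),
                          group = as.character(group_labels),
                          stringsAsFactors = FALSE, row.names = NULL)
  grp <- unique(stats::na.omit(distances$group))
  comparison <- if (length(grp) != 2L) {
    list(defined = FALSE, reason = "need exactly two groups to compare")
  } else {
    dA <- distances$distance[distances$group %in% grp[1L]]
    dB <- distances$distance[distances$group %in% grp[2L]]
    wt <- wilcoxon_rank_sum(dA, dB)
    list(defined = TRUE, groups = grp, median_1 = median(dA),
         median_2 = median(dB), W = wt$W, p = wt$p)
  }
  list(distances = distances, comparison = comparison)
}
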