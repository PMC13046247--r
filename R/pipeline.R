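#' Build a validated run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: genome,
#' feature and model settings for the simulator, the sample sheet, and
#' the analysis parameters (bin size, smoothing bandwidth, peak-calling
#' threshold, overlap windows). All validation failures are reported at
#' once.
#'
#' @param seed global integer seed; per-stage seeds are derived from it
#'   by stable hashing of the stage name.
#' @param out_dir output directory for all stage artifacts.
#' @param genome list with `chrom_lengths` (required), optional
#'   `chrom_names` and `exclusions`.
#' @param features list of arguments for [plant_features()].
#' @param snps list with `density_per_kb` (NULL disables SNP planting).
#' @param model list of arguments for [occupancy_model()].
#' @param n_reads reads per sample for the simulator.
#' @param samples sample sheet data.frame (`sample_id`, `role`).
#' @param params analysis parameters: `bin_size`, `bandwidth`, `p_max`,
#'   `merge_gap`, `min_width`, `site_window`, `pseudocount`, `flank`.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("meiocal_run_"),
                       genome = list(chrom_lengths = c(6e5, 4e5)),
                       features = list(n_hotspots = 40, n_axis = 30,
                                       n_centromere = 2, n_coldspots = 10),
                       snps = list(density_per_kb = 4),
                       model = list(),
                       n_reads = 5e4,
                       samples = NULL,
                       params = list()) {
  defaults <- list(bin_size = 10, bandwidth = 1000, p_max = 1e-5,
                   merge_gap = 100, min_width = 50, site_window = 2000,
                   pseudocount = 0.5, flank = 500)
  defaults[names(params)] <- params
  params <- defaults
  if (is.null(samples))
    samples <- data.frame(
      sample_id = c("chip_rep1", "chip_rep2", "untagged"),
      role = c("chip", "chip", "untagged"), stringsAsFactors = FALSE)
  errs <- character(0)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    errs <- c(errs, "seed must be a single integer")
  if (is.null(genome$chrom_lengths) || any(genome$chrom_lengths <= 0))
    errs <- c(errs, "genome$chrom_lengths must be positive")
  if (!is.numeric(n_reads) || any(n_reads <= 0))
    errs <- c(errs, "n_reads must be positive")
  if (!all(c("sample_id", "role") %in% names(samples)) ||
      !all(samples$role %in% c("chip", "untagged")))
    errs <- c(errs, "samples must have sample_id and role in {chip, untagged}")
  else if (sum(samples$role == "untagged") != 1L)
    errs <- c(errs, "exactly one untagged sample is required")
  if (params$bin_size < 1) errs <- c(errs, "bin_size must be >= 1")
  if (params$bandwidth <= 0) errs <- c(errs, "bandwidth must be positive")
  if (params$p_max <= 0 || params$p_max >= 1)
    errs <- c(errs, "p_max must be in (0, 1)")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, genome = genome,
              features = features, snps = snps, model = model,
              n_reads = n_reads, samples = samples, params = params)
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$samples)) {
    y$samples <- do.call(rbind, lapply(y$samples, function(s)
      data.frame(sample_id = s$sample_id, role = s$role,
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(y$genome$exclusions))
    y$genome$exclusions <- do.call(rbind, lapply(y$genome$exclusions,
                                                 as.data.frame))
  do.call(run_config, y)
}

config_layout <- function(config) {
  make_genome_layout(config$genome$chrom_lengths,
                     config$genome$chrom_names,
                     config$genome$exclusions)
}

provenance_header <- function(config, stage) {
  # hash the scientific content only: where outputs land is not identity
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  paste0("# meiocal=", as.character(utils::packageVersion("meiocal")),
         " config_hash=", stable_hash(hashable),
         " seed=", config$seed, " stage=", stage)
}

write_report <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, stage), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact ", basename(path),
         "; run the '", producer, "' stage first")
  path
}

#' Run the calibrated ChIP-seq pipeline
#'
#' Executes the requested stages, chaining artifacts through
#' `config$out_dir`: `simulate` (synthetic genome, features, SNPs,
#' reads), `calibrate` (scaling factors, binned/calibrated/smoothed
#' tracks), `callpeaks` (local-Poisson peaks from pooled replicates vs
#' the untagged control), `annotate` (Venn classification against the
#' feature map) and `stats` (chromosome-size density with Pearson
#' correlation, peak widths, SNP-density comparison). Every report
#' carries a provenance header (package version, config hash, seed) and
#' reruns with the same config and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "calibrate", "callpeaks", "annotate", "stats")`.
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "calibrate", "callpeaks",
                                    "annotate", "stats")) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out, f)
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  layout <- config_layout(config)
  bs <- config$params$bin_size

  if ("simulate" %in% stages) {
    fs <- do.call(plant_features,
                  c(list(layout = layout,
                         seed = derive_seed(config$seed, "features")),
                    config$features))
    write_bed(fs, pth("features.bed"))
    if (!is.null(config$snps$density_per_kb)) {
      sm <- plant_snps(layout, config$snps$density_per_kb,
                       seed = derive_seed(config$seed, "snps"))
      write_snps_tsv(sm, pth("snps.tsv"))
    }
    model <- do.call(occupancy_model, config$model)
    reads <- simulate_experiment(layout, fs, model, config$n_reads,
                                 samples = config$samples,
                                 seed = derive_seed(config$seed, "reads"))
    write_reads_tsv(reads, pth("reads.tsv"))
    writeLines(paste(layout$chrom_names, format_num(layout$chrom_lengths),
                     sep = "\t"), pth("genome.chrom.sizes"))
    note("simulate: ", nrow(fs), " features, ",
         sum(vapply(reads, nrow, 0)), " reads over ",
         length(reads), " samples")
    written <- c(written, pth(c("features.bed", "reads.tsv",
                                "genome.chrom.sizes")))
  }

  sample_sheet <- config$samples
  chip_ids <- sample_sheet$sample_id[sample_sheet$role == "chip"]
  untagged_id <- sample_sheet$sample_id[sample_sheet$role == "untagged"]

  load_reads <- function() {
    reads <- read_reads_tsv(require_artifact(pth("reads.tsv"), "simulate"))
    if (inherits(reads, "MappedReadSet"))
      reads <- setNames(list(reads), attr(reads, "sample_id"))
    reads
  }

  if ("calibrate" %in% stages) {
    reads <- load_reads()
    tracks <- lapply(reads, bin_reads, layout = layout, bin_size = bs)
    unt_track <- tracks[[untagged_id]]
    unt_cov <- track_mean_coverage(unt_track)
    sf <- lapply(names(tracks), function(id) {
      cnt <- count_unique_reads(reads[[id]])
      compute_scaling(cnt[["n_target_unique"]], cnt[["n_spike_unique"]],
                      unt_cov, sample_id = id)
    })
    names(sf) <- names(tracks)
    sf_df <- data.frame(sample_id = names(sf),
                        n_target_unique = vapply(reads, function(r)
                          count_unique_reads(r)[["n_target_unique"]], 0),
                        n_spike_unique = vapply(reads, function(r)
                          count_unique_reads(r)[["n_spike_unique"]], 0),
                        sf1 = vapply(sf, `[[`, 0, "sf1"),
                        sf2 = vapply(sf, `[[`, 0, "sf2"),
                        row.names = NULL, stringsAsFactors = FALSE)
    write_report(sf_df, pth("scaling_factors.tsv"), config, "calibrate")
    for (i in seq_len(nrow(sf_df)))
      note("calibrate: ", sf_df$sample_id[i],
           " SF1=", sprintf("%.4f", sf_df$sf1[i]),
           " SF2=", sprintf("%.4f", sf_df$sf2[i]))
    calibrated <- lapply(chip_ids, function(id)
      calibrate(tracks[[id]], unt_track, sf[[id]], sf[[untagged_id]]))
    avg <- average_replicates(calibrated)
    smoothed <- smooth_track(avg, config$params$bandwidth)
    write_bedgraph(smoothed, pth("calibrated_smoothed.bedgraph"))
    pooled <- tracks[[chip_ids[1L]]]
    if (length(chip_ids) > 1L) {
      vals <- lapply(names(pooled$values), function(ch)
        Reduce(`+`, lapply(chip_ids,
                           function(id) tracks[[id]]$values[[ch]])))
      names(vals) <- names(pooled$values)
      pooled <- binned_track(vals, layout, bs, state = "raw_counts",
                             provenance = list(sample_id = "pooled_chip"))
    }
    write_bedgraph(pooled, pth("pooled_chip_counts.bedgraph"))
    write_bedgraph(unt_track, pth("untagged_counts.bedgraph"))
    written <- c(written, pth(c("scaling_factors.tsv",
                                "calibrated_smoothed.bedgraph",
                                "pooled_chip_counts.bedgraph",
                                "untagged_counts.bedgraph")))
  }

  if ("callpeaks" %in% stages) {
    pooled <- read_bedgraph(
      require_artifact(pth("pooled_chip_counts.bedgraph"), "calibrate"),
      layout, bs)
    unt <- read_bedgraph(
      require_artifact(pth("untagged_counts.bedgraph"), "calibrate"),
      layout, bs)
    params <- peak_params(p_max = config$params$p_max,
                          merge_gap = config$params$merge_gap,
                          min_width = config$params$min_width)
    peaks <- call_peaks(pooled, unt, params)
    note("callpeaks: ", nrow(peaks), " peaks at p <= ",
         format(config$params$p_max))
    write_report(as.data.frame(peaks), pth("peaks.tsv"), config,
                 "callpeaks")
    write_bed(peaks, pth("peaks.bed"))
    written <- c(written, pth(c("peaks.tsv", "peaks.bed")))
  }

  if ("annotate" %in% stages) {
    peaks <- new_peak_set(read_report(
      require_artifact(pth("peaks.tsv"), "callpeaks")))
    fs <- read_bed(require_artifact(pth("features.bed"), "simulate"),
                   type = "features", layout = layout)
    ann <- annotate_peaks(peaks, fs)
    write_report(as.data.frame(ann$peaks), pth("peaks_annotated.tsv"),
                 config, "annotate")
    cc <- data.frame(label = names(ann$category_counts),
                     count = ann$category_counts, row.names = NULL,
                     stringsAsFactors = FALSE)
    write_report(cc, pth("category_counts.tsv"), config, "annotate")
    note("annotate: ", paste(cc$label, cc$count, sep = "=",
                             collapse = " "))
    written <- c(written, pth(c("peaks_annotated.tsv",
                                "category_counts.tsv")))
  }

  if ("stats" %in% stages) {
    reads <- load_reads()
    peaks <- new_peak_set(read_report(
      require_artifact(pth("peaks.tsv"), "callpeaks")))
    pooled_reads <- do.call(rbind, lapply(chip_ids, function(id)
      as.data.frame(reads[[id]])))
    dens <- density_by_chromosome(pooled_reads, layout)
    write_report(dens, pth("density_by_chromosome.tsv"), config, "stats")
    reports <- list()
    if (nrow(dens) >= 3L && stats::sd(dens$usable_length) > 0) {
      pc <- pearson_correlation(dens$usable_length, dens$density)
      reports$size_density_pearson_r <- pc$r
      reports$size_density_pearson_p <- pc$p
    }
    if (nrow(peaks)) {
      pw <- peak_width_stats(peaks)
      reports$peak_width_median_bp <- pw$median
      reports$peak_width_mean_bp <- pw$mean
    }
    if (file.exists(pth("snps.tsv")) && nrow(peaks)) {
      sm <- read_snps_tsv(pth("snps.tsv"), layout)
      sd_an <- snp_density_analysis(sm, peaks, layout)
      reports$snp_genome_mean_per_kb <- sd_an$genome_mean
      reports$snp_genome_median_per_kb <- sd_an$genome_median
      reports$snp_peak_mean_per_kb <- mean(sd_an$per_peak$density)
      reports$snp_peak_median_per_kb <- median(sd_an$per_peak$density)
      reports$snp_peak_vs_genome_p <- sd_an$test$p
    }
    summary_df <- data.frame(metric = names(reports),
                             value = vapply(reports, identity, 0),
                             row.names = NULL, stringsAsFactors = FALSE)
    write_report(summary_df, pth("stats_summary.tsv"), config, "stats")
    note("stats: ", nrow(summary_df), " summary metrics")
    written <- c(written, pth(c("density_by_chromosome.tsv",
                                "stats_summary.tsv")))
  }

  writeLines(c(provenance_header(config, paste(stages, collapse = "+")),
               log_lines), pth("run_log.txt"))
  written <- c(written, pth("run_log.txt"))
  invisible(setNames(as.list(written), basename(written)))
}
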