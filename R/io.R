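# Readers and writers for the standard text formats the pipeline speaks:
# BED, bedGraph, chrom.sizes, reads TSV, SNP/crossover TSV, YAML config.
# All coordinates on disk are BED-native (0-based half-open) unless a
# reader is told the file uses published 1-based inclusive coordinates.

#' Read a chrom.sizes file
#'
#' @param path two-column TSV (chrom, length).
#' @param exclusions optional exclusion data.frame passed through to
#'   [make_genome_layout()].
#' @return a `GenomeLayout`.
#' @export
read_chrom_sizes <- function(path, exclusions = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  make_genome_layout(df$length, df$chrom, exclusions = exclusions)
}

parse_bed_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (length(fields) && any(ncol < 3L))
    stop("malformed BED line ", which(ncol < 3L)[1L], " in ", path,
         ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path,
         ": non-numeric coordinates")
  list(chrom = vapply(fields, `[`, "", 1L), start = start, end = end,
       name = if (all(ncol >= 4L)) vapply(fields, `[`, "", 4L) else NULL,
       score = if (all(ncol >= 5L))
         suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
       else NULL)
}

#' Read a BED file as a feature set or peak set
#'
#' BED3/BED6, 0-based half-open. For `type = "features"` the class of
#' each record comes from the `class` argument (one class for the whole
#' file, the usual case of per-class maps) or, when `class = NULL`, from
#' the BED name column; the score column is taken as the strength for
#' hotspots. For `type = "peaks"` the name column is the annotation
#' label (if present) and the score column is `-log10(p)`.
#'
#' Set `one_based = TRUE` for files using published 1-based inclusive
#' coordinates; starts are shifted by -1 on ingestion.
#'
#' @param path BED file path.
#' @param type `"features"` or `"peaks"`.
#' @param class feature class for the whole file, or NULL.
#' @param one_based whether the file uses 1-based inclusive coordinates.
#' @param layout optional layout for bounds validation.
#' @return a `FeatureSet` or `PeakSet`.
#' @export
read_bed <- function(path, type = c("features", "peaks"), class = NULL,
                     one_based = FALSE, layout = NULL) {
  type <- match.arg(type)
  b <- parse_bed_lines(path)
  if (one_based) b$start <- b$start - 1
  bad <- which(b$end <= b$start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path, ": end <= start")
  if (!is.null(layout)) {
    if (!all(b$chrom %in% layout$chrom_names))
      stop("BED record on chromosome absent from layout")
    if (any(b$start < 0) || any(b$end > layout$chrom_lengths[b$chrom]))
      stop("BED record outside chromosome bounds")
  }
  if (type == "features") {
    cls <- if (!is.null(class)) rep(class, length(b$chrom)) else b$name
    if (is.null(cls)) stop("feature class missing: no name column and no ",
                           "class argument")
    strength <- ifelse(cls == "hotspot",
                       if (is.null(b$score)) NA_real_ else b$score,
                       NA_real_)
    return(feature_set(b$chrom, b$start, b$end, cls, strength,
                       layout = layout))
  }
  p <- if (is.null(b$score)) rep(NA_real_, length(b$chrom)) else
    10^(-b$score)
  new_peak_set(data.frame(
    chrom = b$chrom, start = b$start, end = b$end,
    summit = floor((b$start + b$end) / 2), p_value = p,
    q_value = NA_real_,
    label = if (is.null(b$name)) NA_character_ else b$name,
    stringsAsFactors = FALSE))
}

#' Write a feature set or peak set as BED6
#'
#' Features: name column carries the class, score the hotspot strength
#' (0 otherwise). Peaks: name column carries the label, score
#' `-log10(p)`.
#'
#' @param x a `FeatureSet` or `PeakSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "FeatureSet")) {
    score <- ifelse(is.na(x$strength), 0, x$strength)
    df <- data.frame(x$chrom, format_num(x$start), format_num(x$end),
                     x$class, format_num(score), ".")
  } else {
    score <- ifelse(is.na(x$p_value) | x$p_value <= 0, 999,
                    -log10(x$p_value))
    df <- data.frame(x$chrom, format_num(x$start), format_num(x$end),
                     ifelse(is.na(x$label), ".", x$label),
                     format_num(score), ".")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         sprintf("%.0f", x), sprintf("%.10g", x))
}

#' Read mapped reads from TSV
#'
#' Columns `chrom, pos, strand, status, sample_id`; `.` encodes a missing
#' chrom/pos/strand (spike-in reads). Statuses are validated against
#' `target_unique`, `spike_unique`, `ambiguous`, `unmapped`.
#'
#' @param path TSV path (with header).
#' @return a single `MappedReadSet` when the file holds one sample, else
#'   a named list of them.
#' @export
read_reads_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "character", "character"),
                   na.strings = character(0))
  need <- c("chrom", "pos", "strand", "status", "sample_id")
  if (!all(need %in% names(df)))
    stop("reads TSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty reads file: ", path)
    return(new_mapped_read_set(
      data.frame(chrom = character(0), pos = numeric(0),
                 strand = character(0), status = character(0),
                 stringsAsFactors = FALSE), sample_id = NA_character_))
  }
  bad <- setdiff(unique(df$status), READ_STATUSES)
  if (length(bad)) stop("unknown read status token: ",
                        paste(bad, collapse = ", "))
  df$chrom[df$chrom == "."] <- NA_character_
  df$strand[df$strand == "."] <- NA_character_
  df$pos <- suppressWarnings(as.numeric(ifelse(df$pos == ".", NA, df$pos)))
  sets <- lapply(split(seq_len(nrow(df)), df$sample_id), function(i) {
    new_mapped_read_set(
      data.frame(chrom = df$chrom[i], pos = df$pos[i],
                 strand = df$strand[i], status = df$status[i],
                 stringsAsFactors = FALSE, row.names = NULL),
      sample_id = df$sample_id[i][1L])
  })
  if (length(sets) == 1L) sets[[1L]] else sets
}

#' Write mapped reads to TSV
#'
#' @param reads a `MappedReadSet` or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  if (inherits(reads, "MappedReadSet")) reads <- list(reads)
  rows <- lapply(reads, function(r) {
    data.frame(chrom = ifelse(is.na(r$chrom), ".", r$chrom),
               pos = ifelse(is.na(r$pos), ".", format_num(r$pos)),
               strand = ifelse(is.na(r$strand), ".", r$strand),
               status = r$status,
               sample_id = attr(r, "sample_id"),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Four-column bedGraph (0-based half-open), runs of equal value merged,
#' chromosomes in track order. `scale` applies a display-only
#' multiplier (e.g. the x2 used for plotting 100-bp SNP counts); it never
#' feeds back into statistics.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @param scale display multiplier (default 1).
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path, scale = 1) {
  stopifnot(inherits(track, "BinnedTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]] * scale
    L <- track$layout$chrom_lengths[[ch]]
    r <- rle(v)
    ends <- pmin(cumsum(r$lengths) * bs, L)
    starts <- c(0, head(ends, -1L))
    writeLines(paste(ch, format_num(starts), format_num(ends),
                     sprintf("%.6g", r$values), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a binned track
#'
#' Interval boundaries must align to the bin grid (the last interval of
#' a chromosome may end at the chromosome end).
#'
#' @param path bedGraph path.
#' @param layout a [make_genome_layout()] object.
#' @param bin_size bin width in bp.
#' @param state state flag for the resulting track.
#' @return a [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_size = 10,
                          state = "raw_counts") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"))
  nb <- ceiling(layout$chrom_lengths / bin_size)
  values <- lapply(layout$chrom_names, function(ch) numeric(nb[[ch]]))
  names(values) <- layout$chrom_names
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% layout$chrom_names)
      stop("bedGraph chromosome absent from layout: ", ch)
    if (df$start[i] %% bin_size != 0)
      stop("bedGraph interval not aligned to the bin grid (line ", i, ")")
    b0 <- df$start[i] / bin_size + 1L
    b1 <- ceiling(df$end[i] / bin_size)
    values[[ch]][b0:b1] <- df$value[i]
  }
  binned_track(values, layout, bin_size, state = state)
}

#' Write a SNP map as TSV
#' @param snps a `SNPMap`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_snps_tsv <- function(snps, path) {
  rows <- lapply(names(snps), function(ch)
    if (length(snps[[ch]]))
      data.frame(chrom = ch, pos = snps[[ch]], stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), pos = integer(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP map from TSV (columns chrom, pos)
#' @param path TSV path.
#' @param layout a `GenomeLayout`.
#' @return a `SNPMap`.
#' @export
read_snps_tsv <- function(path, layout) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric"))
  if (nrow(df) && (!all(df$chrom %in% layout$chrom_names) ||
                   any(df$pos < 0) ||
                   any(df$pos >= layout$chrom_lengths[df$chrom])))
    stop("SNP position outside the layout")
  out <- lapply(layout$chrom_names, function(ch)
    sort(unique(as.integer(df$pos[df$chrom == ch]))))
  names(out) <- layout$chrom_names
  structure(out, layout = layout, class = "SNPMap")
}

#' Write crossovers as TSV
#' @param crossovers a `CrossoverSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_crossovers_tsv <- function(crossovers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_tetrads=", attr(crossovers, "n_tetrads")), con)
  write.table(as.data.frame(crossovers), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read crossovers from TSV
#' @param path TSV path (optional `# n_tetrads=` header).
#' @param layout optional layout for bounds validation.
#' @return a `CrossoverSet`.
#' @export
read_crossovers_tsv <- function(path, layout = NULL) {
  first <- readLines(path, n = 1L)
  n_tetrads <- if (grepl("^# n_tetrads=", first))
    as.integer(sub("^# n_tetrads=", "", first)) else NA_integer_
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c("integer", "character", "numeric"))
  if (!is.null(layout) && nrow(df) &&
      (any(df$pos < 0) || !all(df$chrom %in% layout$chrom_names) ||
       any(df$pos >= layout$chrom_lengths[df$chrom])))
    stop("crossover position outside the layout")
  if (is.na(n_tetrads)) n_tetrads <- max(df$tetrad_id, 0L)
  structure(df, n_tetrads = n_tetrads,
            class = c("CrossoverSet", "data.frame"))
}
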