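#' Genome layout
#'
#' A `GenomeLayout` records chromosome names and lengths plus optional
#' exclusion intervals (for example the highly repetitive rDNA array) that
#' are left out of density statistics.
#'
#' Coordinates are 0-based half-open throughout the package (BED
#' convention); published 1-based inclusive coordinates must be converted on
#' ingestion (see [read_bed()]).
#'
#' @param chrom_lengths positive numeric vector of chromosome lengths in bp.
#' @param chrom_names optional character vector of chromosome names; defaults
#'   to `chrI`, `chrII`, ... (roman numerals up to 20, then `chr<n>`).
#' @param exclusions optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) of intervals excluded from density
#'   statistics. Must lie within their chromosome and be non-overlapping
#'   per chromosome.
#' @return an object of class `GenomeLayout`: a list with elements
#'   `chrom_names`, `chrom_lengths` (named numeric) and `exclusions`.
#' @examples
#' layout <- make_genome_layout(c(1e6, 5e5))
#' genome_size(layout)
#' @export
make_genome_layout <- function(chrom_lengths, chrom_names = NULL,
                               exclusions = NULL) {
  if (length(chrom_lengths) == 0L)
    stop("at least one chromosome is required")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  n <- length(chrom_lengths)
  if (is.null(chrom_names)) chrom_names <- default_chrom_names(n)
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) != n) stop("chrom_names length mismatch")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  names(chrom_lengths) <- chrom_names

  if (is.null(exclusions)) {
    exclusions <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), stringsAsFactors = FALSE)
  } else {
    exclusions <- as.data.frame(exclusions, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(exclusions)))
      stop("exclusions must have columns chrom, start, end")
    exclusions <- exclusions[need]
    exclusions$chrom <- as.character(exclusions$chrom)
    if (!all(exclusions$chrom %in% chrom_names))
      stop("exclusion on unknown chromosome: ",
           paste(setdiff(exclusions$chrom, chrom_names), collapse = ", "))
    if (any(exclusions$start < 0) ||
        any(exclusions$end > chrom_lengths[exclusions$chrom]))
      stop("exclusion interval out of chromosome bounds")
    if (any(exclusions$end <= exclusions$start))
      stop("exclusion intervals must satisfy start < end")
    exclusions <- exclusions[order(exclusions$chrom, exclusions$start), ,
                             drop = FALSE]
    rownames(exclusions) <- NULL
    for (ch in unique(exclusions$chrom)) {
      e <- exclusions[exclusions$chrom == ch, , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        stop("overlapping exclusion intervals on ", ch)
    }
  }
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = chrom_lengths,
                 exclusions = exclusions),
            class = "GenomeLayout")
}

default_chrom_names <- function(n) {
  romans <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
              "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
              "XIX", "XX")
  if (n <= length(romans)) paste0("chr", romans[seq_len(n)])
  else paste0("chr", seq_len(n))
}

#' Total genome size of a layout
#' @param layout a [make_genome_layout()] object.
#' @return total genome size in bp.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(layout$chrom_lengths)
}

# bp excluded per chromosome (named vector over all chromosomes).
excluded_bp <- function(layout) {
  out <- setNames(numeric(length(layout$chrom_names)), layout$chrom_names)
  ex <- layout$exclusions
  if (nrow(ex)) {
    agg <- tapply(ex$end - ex$start, ex$chrom, sum)
    out[names(agg)] <- agg
  }
  out
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  if (nrow(x$exclusions))
    cat("  exclusions:", nrow(x$exclusions), "interval(s),",
        format(sum(x$exclusions$end - x$exclusions$start), big.mark = ","),
        "bp\n")
  invisible(x)
}
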