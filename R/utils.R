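# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so seeded generators do not disturb the global stream.
#' A `NULL` seed evaluates `code` with the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string/object hash (order-dependent polynomial hash).
# Used for provenance config hashes and per-stage seed derivation; not
# cryptographic.
stable_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  ints <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (v in ints) h <- (h * 31 + v) %% m
  as.integer(h)
}

# Derive a per-stage seed from a global seed and a stage label, kept within
# the 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(stage)) %% 2147483647)
}

# Centered running mean over a window of `w` bins, renormalized over the
# available bins at vector edges.
running_mean <- function(v, w) {
  n <- length(v)
  h <- max(0L, as.integer(w) %/% 2L)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Build a pair of GRanges on a common seqlevel universe from 0-based
# half-open interval data.frames (columns chrom, start, end).
granges_pair <- function(a, b) {
  lv <- union(unique(as.character(a$chrom)), unique(as.character(b$chrom)))
  mk <- function(d) {
    GenomicRanges::GRanges(
      seqnames = factor(as.character(d$chrom), levels = lv),
      ranges = IRanges::IRanges(start = d$start + 1L, end = pmax(d$end, d$start + 1L))
    )
  }
  list(a = mk(a), b = mk(b))
}

# TRUE for each row of `a` overlapping >= 1 bp with some row of `b`.
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (is.null(b) || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  gr <- granges_pair(a, b)
  GenomicRanges::countOverlaps(gr$a, gr$b, minoverlap = 1L) > 0L
}

# Count of elements of sorted integer vector `pos` falling in [start, end)
# (0-based half-open), vectorized over intervals.
count_in_intervals <- function(pos, start, end) {
  if (length(pos) == 0L) return(integer(length(start)))
  findInterval(end - 1, pos) - findInterval(start - 1, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
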