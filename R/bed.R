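#' Read BED intervals as peaks or aligned reads
#'
#' Parses BED3+ text (chrom, start, end, and optionally name, score,
#' strand), 0-based half-open. Coordinate-order violations and
#' out-of-bounds intervals are rejected with an error naming the line —
#' never silently repaired.
#'
#' @param path Path to a BED file. Blank lines and lines starting with
#'   `#`, `track`, or `browser` are ignored.
#' @param genome A `genome_model`; every interval must lie within its
#'   chromosome bounds.
#' @param what `"peaks"` (default) or `"reads"`. For reads the result also
#'   carries a `"depth"` attribute equal to the record count (the total
#'   mapped-read depth used for normalization).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` for peaks, or `chrom`, `start`, `end`, `strand` for reads.
#' @export
read_bed_intervals <- function(path, genome, what = c("peaks", "reads")) {
  what <- match.arg(what)
  check_nonempty_genome(genome)
  lines <- readLines(path, warn = FALSE)
  t <- trimws(lines)
  keep <- which(nzchar(t) & !startsWith(t, "#") &
                  !startsWith(t, "track") & !startsWith(t, "browser"))
  n <- length(keep)
  chrom <- character(n); start <- double(n); end <- double(n)
  name <- rep(NA_character_, n); score <- rep(NA_real_, n)
  strand <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    i <- keep[[k]]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) abort(paste0(path, ": line ", i, ": expected at least 3 BED columns"))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) abort(paste0(path, ": line ", i, ": non-numeric coordinates"))
    if (s >= e) abort(paste0(path, ": line ", i, ": start (", f[2],
                             ") must be < end (", f[3], ")"))
    L <- tryCatch(chrom_length(genome, f[1]), error = function(err)
      abort(paste0(path, ": line ", i, ": unknown chromosome '", f[1], "'")))
    if (s < 0 || e > L) abort(paste0(path, ": line ", i, ": interval outside chromosome bounds"))
    chrom[k] <- f[1]; start[k] <- s; end[k] <- e
    if (length(f) >= 4L) name[k] <- f[4]
    if (length(f) >= 5L) score[k] <- suppressWarnings(as.numeric(f[5]))
    if (length(f) >= 6L && f[6] %in% c("+", "-")) strand[k] <- f[6]
  }
  if (what == "peaks") {
    tibble(chrom = chrom, start = start, end = end,
           name = name, score = score, strand = strand)
  } else {
    out <- tibble(chrom = chrom, start = start, end = end, strand = strand)
    attr(out, "depth") <- n
    out
  }
}

#' @rdname read_bed_intervals
#' @export
read_peaks <- function(path, genome) read_bed_intervals(path, genome, "peaks")

#' @rdname read_bed_intervals
#' @export
read_reads <- function(path, genome) read_bed_intervals(path, genome, "reads")

#' Write intervals to BED
#'
#' Writes `chrom`, `start`, `end` plus any of `name`, `score`, `strand`
#' present in the input, producing BED3-BED6. Coordinates round-trip
#' exactly through [read_bed_intervals()].
#'
#' @param x A tibble of intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  cols <- list(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  get_col <- function(col, fill) if (col %in% names(x)) x[[col]] else rep(fill, n)
  has <- function(col) col %in% names(x) && !all(is.na(x[[col]]))
  ncol_out <- 3L
  if (has("name") || has("score") || has("strand")) ncol_out <- 4L
  if (has("score") || has("strand")) ncol_out <- 5L
  if (has("strand")) ncol_out <- 6L
  if (ncol_out >= 4L) {
    nm <- get_col("name", NA_character_)
    cols <- c(cols, list(ifelse(is.na(nm), ".", nm)))
  }
  if (ncol_out >= 5L) {
    sc <- get_col("score", NA_real_)
    cols <- c(cols, list(ifelse(is.na(sc), "0",
                                format(sc, scientific = FALSE, trim = TRUE))))
  }
  if (ncol_out >= 6L) {
    st <- get_col("strand", NA_character_)
    cols <- c(cols, list(ifelse(is.na(st), ".", st)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Total mapped-read depth of a read set
#'
#' The depth is the record count, taken from the `"depth"` attribute when
#' present (set by [read_reads()] and the simulator) and from the row count
#' otherwise.
#'
#' @param reads A reads tibble.
#' @return A single number.
#' @export
read_depth <- function(reads) {
  attr(reads, "depth") %||% nrow(reads)
}

## read midpoints, 0-based (floor of interval midpoint)
read_midpoints <- function(reads) {
  floor((reads$start + reads$end) / 2)
}
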