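#' Build a genome model from chromosome names and lengths
#'
#' A genome model is the coordinate frame shared by every other function in
#' the package: a tibble with one row per chromosome (`chrom`, `length`),
#' optionally carrying the nucleotide sequences as a
#' [Biostrings::DNAStringSet] attribute. Coordinates everywhere in the
#' package are 0-based half-open, so a chromosome of length `L` covers
#' positions `[0, L)`.
#'
#' @param chroms A data frame with columns `chrom` (character, unique) and
#'   `length` (positive integer bases).
#' @param sequences Optional named [Biostrings::DNAStringSet] (or named
#'   character vector) with one entry per chromosome; widths must equal the
#'   declared lengths.
#' @return A tibble of class `genome_model` with columns `chrom` and
#'   `length`; sequences, when given, are stored in the `"sequences"`
#'   attribute.
#' @examples
#' genome_model(data.frame(chrom = "chrT", length = 10000))
#' @export
genome_model <- function(chroms, sequences = NULL) {
  chroms <- as_tibble(chroms)
  if (!all(c("chrom", "length") %in% names(chroms))) {
    abort("`chroms` must have columns `chrom` and `length`")
  }
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.double(chroms$length)
  if (anyDuplicated(chroms$chrom)) {
    abort(paste0("duplicate chromosome name: ",
                 chroms$chrom[duplicated(chroms$chrom)][1]))
  }
  if (nrow(chroms) && any(!is.finite(chroms$length) | chroms$length <= 0 |
                          chroms$length != floor(chroms$length))) {
    abort("chromosome lengths must be positive integers")
  }
  g <- chroms[, c("chrom", "length")]
  if (!is.null(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
    if (is.null(names(sequences)) || !setequal(names(sequences), g$chrom)) {
      abort("`sequences` must be named by chromosome, one per chromosome")
    }
    sequences <- sequences[g$chrom]
    w <- Biostrings::width(sequences)
    if (any(w != g$length)) {
      bad <- g$chrom[w != g$length][1]
      abort(paste0("sequence length for ", bad, " does not match declared length"))
    }
    attr(g, "sequences") <- sequences
  }
  class(g) <- c("genome_model", class(g))
  g
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to whitespace-delimited text with columns
#'   (chromosome name, length in bases). Blank lines and `#` comments are
#'   ignored.
#' @return A `genome_model` tibble (lengths only). An empty file yields an
#'   empty genome model; downstream operations that need chromosomes will
#'   reject it.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 2L) {
      abort(paste0(path, ": line ", i, ": expected two columns (name, length)"))
    }
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len) || len <= 0 || len != floor(len)) {
      abort(paste0(path, ": line ", i, ": length must be a positive integer, got '",
                   f[2], "'"))
    }
    tibble(chrom = f[1], length = len)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(chrom = character(), length = double())
  if (anyDuplicated(out$chrom)) {
    dup <- out$chrom[duplicated(out$chrom)][1]
    abort(paste0(path, ": duplicate chromosome name '", dup, "'"))
  }
  genome_model(out)
}

#' Attach FASTA sequences to a genome model
#'
#' @param genome A `genome_model` (or `NULL` to derive chromosomes and
#'   lengths from the FASTA itself).
#' @param path Path to a FASTA file whose record names match the genome's
#'   chromosome names.
#' @return The genome model with sequences attached (widths are validated
#'   against the declared lengths).
#' @export
read_genome_fasta <- function(path, genome = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(genome)) {
    genome <- tibble(chrom = names(seqs),
                     length = as.double(Biostrings::width(seqs)))
  }
  genome_model(genome[, c("chrom", "length")], sequences = seqs)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x), " chromosome(s), ",
      format(sum(x$length), big.mark = ","), " bases",
      if (!is.null(attr(x, "sequences"))) ", with sequences" else "",
      "\n", sep = "")
  NextMethod()
}

genome_sequences <- function(genome) {
  s <- attr(genome, "sequences")
  if (is.null(s)) abort("this operation needs genome sequences; attach them with read_genome_fasta()")
  s
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) abort(paste0("unknown chromosome: ", chrom[is.na(i)][1]))
  genome$length[i]
}

check_nonempty_genome <- function(genome) {
  if (!nrow(genome)) abort("genome model has no chromosomes")
  invisible(genome)
}

## Extract [start, end) (0-based half-open) from a chromosome sequence as a
## plain character string, truncating at chromosome bounds.
extract_window_seq <- function(genome, chrom, start, end) {
  L <- chrom_length(genome, chrom)
  start <- max(0, start)
  end <- min(L, end)
  if (end <= start) return("")
  as.character(Biostrings::subseq(genome_sequences(genome)[[chrom]],
                                  start = start + 1L, end = end))
}
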