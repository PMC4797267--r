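#' Read transcript models from a refGene-flat table
#'
#' Parses the tab-separated refGene dialect with columns
#' (name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonStarts,
#' exonEnds), where the exon columns are comma-terminated lists of 0-based
#' half-open coordinates. One row is one transcript; isoforms are kept
#' separate — overlap between transcripts is resolved later by annotation
#' priority, never by merging.
#'
#' Transcripts on chromosomes absent from `genome` are dropped with a single
#' warning; the number dropped is recorded in the `"n_skipped"` attribute.
#' Structural violations (reversed bounds, mismatched exon lists, exons
#' outside the transcript, unsorted or overlapping exons, CDS outside the
#' exons) are errors naming the offending line.
#'
#' @param path Path to the tab-separated table. Blank lines and `#` comments
#'   are ignored.
#' @param genome A `genome_model` used to validate chromosomes and bounds.
#' @return A tibble with one row per transcript: `gene`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, and list-columns
#'   `exon_starts`, `exon_ends`. Non-coding transcripts have
#'   `cds_start == cds_end`.
#' @export
read_gene_models <- function(path, genome) {
  check_nonempty_genome(genome)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  skipped <- 0L
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[[k]]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      abort(paste0(path, ": line ", i, ": expected 9 tab-separated columns"))
    }
    if (!f[3] %in% c("+", "-")) {
      abort(paste0(path, ": line ", i, ": strand must be '+' or '-', got '", f[3], "'"))
    }
    if (!f[2] %in% genome$chrom) {
      skipped <- skipped + 1L
      next
    }
    num <- suppressWarnings(as.numeric(f[4:7]))
    if (anyNA(num)) abort(paste0(path, ": line ", i, ": non-numeric coordinate"))
    es <- parse_coord_list(f[8], path, i)
    ee <- parse_coord_list(f[9], path, i)
    if (length(es) != length(ee)) {
      abort(paste0(path, ": line ", i, ": exonStarts has ", length(es),
                   " entries but exonEnds has ", length(ee)))
    }
    g <- tibble(gene = f[1], chrom = f[2], strand = f[3],
                tx_start = num[1], tx_end = num[2],
                cds_start = num[3], cds_end = num[4],
                exon_starts = list(es), exon_ends = list(ee))
    validate_gene_model(g, genome, where = paste0(path, ": line ", i))
    rows[[k]] <- g
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_gene_models()
  if (skipped > 0L) {
    warn(paste0(skipped, " transcript(s) on chromosomes absent from the genome were skipped"))
  }
  attr(out, "n_skipped") <- skipped
  out
}

empty_gene_models <- function() {
  tibble(gene = character(), chrom = character(), strand = character(),
         tx_start = double(), tx_end = double(),
         cds_start = double(), cds_end = double(),
         exon_starts = list(), exon_ends = list())
}

parse_coord_list <- function(x, path, i) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v)) abort(paste0(path, ": line ", i, ": malformed exon coordinate list '", x, "'"))
  v
}

validate_gene_model <- function(g, genome, where = "gene model") {
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  bad <- function(msg) abort(paste0(where, ": ", msg))
  if (!(g$tx_start < g$tx_end)) bad("txStart must be < txEnd")
  if (!(g$cds_start <= g$cds_end)) bad("cdsStart must be <= cdsEnd")
  L <- chrom_length(genome, g$chrom)
  if (g$tx_start < 0 || g$tx_end > L) bad("transcript outside chromosome bounds")
  if (length(es)) {
    if (any(ee <= es)) bad("exon with start >= end")
    if (any(es < g$tx_start) || any(ee > g$tx_end)) bad("exon outside transcript bounds")
    if (is.unsorted(es, strictly = TRUE)) bad("exons must be sorted")
    if (length(es) > 1L && any(es[-1] < ee[-length(ee)])) bad("exons must not overlap")
    if (g$cds_start < g$cds_end) {
      cov <- any(es <= g$cds_start & ee > g$cds_start) &&
        any(es < g$cds_end & ee >= g$cds_end)
      if (!cov) bad("CDS bounds not covered by exons")
    }
  }
  invisible(g)
}

#' Write gene models back to refGene-flat text
#'
#' @param genes A gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  fmt_list <- function(v) vapply(v, function(x) paste0(paste(format(x, scientific = FALSE, trim = TRUE), collapse = ","), ","), character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s\t%s",
                   genes$gene, genes$chrom, genes$strand,
                   as.integer(genes$tx_start), as.integer(genes$tx_end),
                   as.integer(genes$cds_start), as.integer(genes$cds_end),
                   fmt_list(genes$exon_starts), fmt_list(genes$exon_ends))
  writeLines(lines, path)
  invisible(path)
}
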