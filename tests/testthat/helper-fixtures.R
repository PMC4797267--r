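# Shared fixtures, built in code at test time.

# A 20-kb single-chromosome genome with one + strand and one - strand
# coding transcript, used by the annotation tests.
fixture_genome <- function() {
  genome_model(tibble::tibble(chrom = "chrT", length = 20000))
}

fixture_genes <- function() {
  tibble::tibble(
    gene = c("plus_gene", "minus_gene"),
    chrom = "chrT",
    strand = c("+", "-"),
    tx_start = c(2000, 12000), tx_end = c(5000, 15000),
    cds_start = c(2200, 12500), cds_end = c(4500, 14500),
    exon_starts = list(c(2000, 4000), c(12000, 14000)),
    exon_ends = list(c(2500, 5000), c(13000, 15000))
  )
}

# A small, fast simulator configuration for property tests.
fast_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_induced = 15, n_repressed = 15, n_common = 15,
               genome_length = 3e5, n_genes = 15, depth_a = 3e4, depth_b = 3e4,
               background_rate = 1 / 3e5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Strongly informative 8-column test motif: consensus ACGTACGT.
fixture_pwm <- function() {
  counts <- matrix(2, nrow = 4, ncol = 8,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("A", "C", "G", "T", "A", "C", "G", "T")
  for (j in 1:8) counts[consensus[j], j] <- 94
  pwm(counts, name = "test-motif")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
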