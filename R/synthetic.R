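#' Configuration for the two-condition ChIP simulator
#'
#' The generator plants occupancy sites of three known classes on a toy
#' genome and draws reads for an untreated condition A and a treated
#' condition B. Per site, the expected window count is
#' `enrichment x lambda_bg`, where `lambda_bg = depth x background_rate x
#' window` is the expected background count in a comparison window;
#' induced sites have enrichment (1, `effect_fold`) in (A, B), repressed
#' sites the reverse, and common sites `common_enrichment` in both.
#' Background reads top the total up to the configured depth, so the
#' emitted read count equals the depth exactly.
#'
#' @param seed Integer seed; every run with the same config is
#'   byte-identical.
#' @param n_induced,n_repressed,n_common Sites per class (default 50
#'   each).
#' @param genome_length,n_chrom,n_genes Toy genome layout: total length in
#'   bases (default 1 Mb), number of chromosomes (default 1), transcripts
#'   laid out without overlap (default 50). With the defaults, promoters
#'   cover 5% of the genome.
#' @param depth_a,depth_b Total reads per condition (default 1e5 each).
#' @param background_rate Expected background read midpoints per base per
#'   sequenced read (default 1e-6, i.e. uniform coverage of a 1 Mb
#'   genome); with the defaults the background expectation per 200-bp
#'   window is 20 reads.
#' @param fragment_length Half-width in bases of the uniform placement of
#'   site-read midpoints around the site center (default 100, so site
#'   reads fall inside the default comparison window).
#' @param read_length Span of each emitted read interval (default 100).
#' @param effect_fold Enrichment ratio between conditions at induced and
#'   repressed sites; must exceed 4 so classification at the published
#'   4-fold cut is recoverable (default 8).
#' @param common_enrichment Enrichment of common sites in both conditions
#'   (default 6, enough for peak calling).
#' @param motif_fraction Named fractions (induced, repressed, common) of
#'   sites per class that get the motif consensus planted at their center
#'   (default 0.5 for induced, 0 elsewhere).
#' @param promoter_fraction Named fractions of sites per class placed at
#'   gene promoters instead of intergenic space (default 0.5 for induced,
#'   0.05 elsewhere — ten times the genomic promoter background for the
#'   induced class).
#' @param motif A [pwm()] whose consensus is planted (default
#'   [ctcf_like_pwm()]).
#' @param window Comparison window used to calibrate site intensities and
#'   emit peaks (default 200).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_induced = 50, n_repressed = 50,
                       n_common = 50, genome_length = 1e6, n_chrom = 1,
                       n_genes = 50, depth_a = 1e5, depth_b = 1e5,
                       background_rate = 1e-6, fragment_length = 100,
                       read_length = 100, effect_fold = 8,
                       common_enrichment = 6,
                       motif_fraction = c(induced = 0.5, repressed = 0,
                                          common = 0),
                       promoter_fraction = c(induced = 0.5,
                                             repressed = 0.05,
                                             common = 0.05),
                       motif = ctcf_like_pwm(), window = 200) {
  stopifnot(n_induced >= 0, n_repressed >= 0, n_common >= 0,
            depth_a > 0, depth_b > 0, background_rate > 0,
            fragment_length > 0, read_length > 0, n_chrom >= 1,
            genome_length >= 1000, window > 0, window %% 2 == 0)
  if (effect_fold <= 4) {
    abort("`effect_fold` must exceed 4 for classification to be recoverable at the 4-fold cut")
  }
  chk_frac <- function(x, what) {
    if (!all(c("induced", "repressed", "common") %in% names(x)) ||
        any(x < 0 | x > 1)) {
      abort(paste0("`", what, "` must be named fractions in [0, 1] for induced/repressed/common"))
    }
    x[c("induced", "repressed", "common")]
  }
  structure(list(seed = as.integer(seed), n_induced = n_induced,
                 n_repressed = n_repressed, n_common = n_common,
                 genome_length = genome_length, n_chrom = n_chrom,
                 n_genes = n_genes, depth_a = depth_a, depth_b = depth_b,
                 background_rate = background_rate,
                 fragment_length = fragment_length,
                 read_length = read_length, effect_fold = effect_fold,
                 common_enrichment = common_enrichment,
                 motif_fraction = chk_frac(motif_fraction, "motif_fraction"),
                 promoter_fraction = chk_frac(promoter_fraction,
                                              "promoter_fraction"),
                 motif = motif, window = window),
            class = "sim_config")
}

#' Generate the toy genome and its gene models
#'
#' Chromosome sequences are i.i.d. uniform A/C/G/T; transcripts are laid
#' out non-overlapping with 2-6 exons, plausible exon/intron sizes, random
#' strand, and a CDS inside the outer exons (about one in ten transcripts
#' is left non-coding). Deterministic given the config seed; calling this
#' directly reproduces exactly the genome used inside
#' [simulate_chip_experiment()].
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a `genome_model` with sequences) and
#'   `genes` (a gene-model tibble).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  per <- floor(config$genome_length / config$n_chrom)
  chroms <- tibble(chrom = sprintf("chrS%d", seq_len(config$n_chrom)),
                   length = rep(per, config$n_chrom))
  base_codes <- utf8ToInt("ACGT")
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(config$n_chrom), function(i)
    intToUtf8(base_codes[sample.int(4L, per, replace = TRUE)]),
    character(1)))
  names(seqs) <- chroms$chrom
  genome <- genome_model(chroms, sequences = seqs)
  genes <- generate_genes_impl(config, genome)
  list(genome = genome, genes = genes)
}

generate_genes_impl <- function(config, genome) {
  n <- config$n_genes
  if (n == 0) return(empty_gene_models())
  total <- sum(genome$length)
  slot <- floor(total / n)
  if (slot < 6000) {
    abort(paste0(n, " genes do not fit in a genome of ",
                 format(total, scientific = FALSE), " bases"))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gstart_abs <- (i - 1L) * slot
    ## map absolute offset to a chromosome
    cum <- cumsum(genome$length)
    ci <- which(gstart_abs < cum)[1]
    off <- gstart_abs - c(0, cum)[ci]
    room <- min(slot, genome$length[ci] - off) - 3000  # 1.5 kb flanks
    glen <- min(room, sample(3000:8000, 1))
    tx_start <- off + 1500
    tx_end <- tx_start + glen
    n_ex <- sample(2:6, 1)
    ## split the span into alternating exon/intron blocks
    cuts <- sort(sample(seq(200, glen - 200, by = 50), 2 * n_ex - 2))
    bounds <- c(0, cuts, glen)
    es <- tx_start + bounds[seq(1, length(bounds) - 1, by = 2)]
    ee <- tx_start + bounds[seq(2, length(bounds), by = 2)]
    coding <- runif(1) > 0.1
    if (coding) {
      cds_start <- es[1] + floor((ee[1] - es[1]) / 2)
      cds_end <- es[n_ex] + ceiling((ee[n_ex] - es[n_ex]) / 2)
    } else {
      cds_start <- cds_end <- tx_start
    }
    rows[[i]] <- tibble(gene = sprintf("gene_%03d", i),
                        chrom = genome$chrom[ci],
                        strand = sample(c("+", "-"), 1),
                        tx_start = tx_start, tx_end = tx_end,
                        cds_start = cds_start, cds_end = cds_end,
                        exon_starts = list(es), exon_ends = list(ee))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a two-condition ChIP experiment with known ground truth
#'
#' Generates the toy genome, plants sites of the three classes (placed at
#' gene promoters or in intergenic space per the configured fractions,
#' spaced at least 2 kb apart), substitutes the motif consensus into the
#' sequence at motif-positive sites, draws seeded Poisson reads for both
#' conditions plus a background-only input read set, and emits per-
#' condition peak lists (site center +/- 100 for sites whose observed
#' window count clearly exceeds background).
#'
#' @param config A [sim_config()].
#' @return A list with `genome`, `genes`, `truth` (one row per site:
#'   `site`, `chrom`, `center`, `true_class`, `enrichment_a`,
#'   `enrichment_b`, `category_intent`, `has_motif`), `reads_a`,
#'   `reads_b`, `reads_input`, `peaks_a`, `peaks_b`, and the `config`.
#' @export
simulate_chip_experiment <- function(config) {
  withr::with_seed(config$seed, {
    gg <- generate_genome_impl(config)
    genome <- gg$genome; genes <- gg$genes
    truth <- place_truth_sites(config, genome, genes)
    genome <- plant_motifs(config, genome, truth)
    lambda_bg_a <- config$depth_a * config$background_rate * config$window
    lambda_bg_b <- config$depth_b * config$background_rate * config$window
    ra <- draw_reads(config, genome, truth, truth$enrichment_a,
                     config$depth_a, lambda_bg_a)
    rb <- draw_reads(config, genome, truth, truth$enrichment_b,
                     config$depth_b, lambda_bg_b)
    ri <- draw_reads(config, genome, truth[0, ], numeric(0),
                     round((config$depth_a + config$depth_b) / 2), 0)
    pa <- emit_peaks(config, truth, ra, lambda_bg_a)
    pb <- emit_peaks(config, truth, rb, lambda_bg_b)
    list(genome = genome, genes = genes, truth = truth,
         reads_a = ra, reads_b = rb, reads_input = ri,
         peaks_a = pa, peaks_b = pb, config = config)
  })
}

place_truth_sites <- function(config, genome, genes) {
  classes <- rep(c("induced", "repressed", "common"),
                 c(config$n_induced, config$n_repressed, config$n_common))
  n <- length(classes)
  if (!n) {
    return(tibble(site = character(), chrom = character(), center = double(),
                  true_class = character(), enrichment_a = double(),
                  enrichment_b = double(), category_intent = character(),
                  has_motif = logical()))
  }
  ## promoter slots: midpoints of each gene's upstream kilobase
  proms <- if (nrow(genes)) {
    fwd <- genes$strand == "+"
    tibble(chrom = genes$chrom,
           center = ifelse(fwd, genes$tx_start - 500, genes$tx_end + 500))
  } else tibble(chrom = character(), center = double())
  ## intergenic slots: a 2-kb grid excluding gene bodies +/- 1.5 kb
  grid <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(ci)
    tibble(chrom = genome$chrom[ci],
           center = seq(1000, genome$length[ci] - 1000, by = 2000))))
  if (nrow(genes)) {
    gr_grid <- GenomicRanges::GRanges(grid$chrom,
                                      IRanges::IRanges(grid$center + 1,
                                                       grid$center + 1))
    gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$tx_start - 1500 + 1,
                                                        genes$tx_end + 1500))
    grid <- grid[!IRanges::overlapsAny(gr_grid, gr_genes), , drop = FALSE]
  }
  out <- vector("list", 3L)
  prom_pool <- sample(seq_len(nrow(proms)))
  inter_pool <- sample(seq_len(nrow(grid)))
  for (k in 1:3) {
    cl <- c("induced", "repressed", "common")[k]
    n_cl <- sum(classes == cl)
    if (!n_cl) next
    n_prom <- round(config$promoter_fraction[[cl]] * n_cl)
    n_prom <- min(n_prom, length(prom_pool))
    n_int <- n_cl - n_prom
    if (n_int > length(inter_pool)) {
      abort("not enough intergenic space for the requested sites")
    }
    take_p <- prom_pool[seq_len(n_prom)]
    prom_pool <- prom_pool[-seq_len(max(1, n_prom))[seq_len(n_prom)]]
    take_i <- inter_pool[seq_len(n_int)]
    inter_pool <- inter_pool[-seq_len(max(1, n_int))[seq_len(n_int)]]
    pos <- dplyr::bind_rows(
      if (n_prom) tibble(chrom = proms$chrom[take_p],
                         center = proms$center[take_p],
                         category_intent = "promoter"),
      if (n_int) tibble(chrom = grid$chrom[take_i],
                        center = grid$center[take_i],
                        category_intent = "intergenic"))
    enr <- switch(cl,
                  induced = c(1, config$effect_fold),
                  repressed = c(config$effect_fold, 1),
                  common = c(config$common_enrichment,
                             config$common_enrichment))
    pos$true_class <- cl
    pos$enrichment_a <- enr[1]
    pos$enrichment_b <- enr[2]
    pos$has_motif <- seq_len(nrow(pos)) %in%
      sample(nrow(pos), round(config$motif_fraction[[cl]] * nrow(pos)))
    out[[k]] <- pos
  }
  truth <- dplyr::bind_rows(out)
  truth <- dplyr::arrange(truth, .data$chrom, .data$center)
  truth$site <- sprintf("site_%03d", seq_len(nrow(truth)))
  truth[, c("site", "chrom", "center", "true_class", "enrichment_a",
            "enrichment_b", "category_intent", "has_motif")]
}

plant_motifs <- function(config, genome, truth) {
  idx <- which(truth$has_motif)
  if (!length(idx)) return(genome)
  consensus <- pwm_consensus(config$motif)
  L <- nchar(consensus)
  if (L > 2 * config$fragment_length) {
    abort("motif longer than twice the fragment length")
  }
  seqs <- genome_sequences(genome)
  for (i in idx) {
    ch <- truth$chrom[i]
    at <- truth$center[i] - floor(L / 2)  # 0-based
    seqs[[ch]] <- Biostrings::replaceAt(
      seqs[[ch]], IRanges::IRanges(at + 1, at + L), consensus)
  }
  genome_model(tibble(chrom = genome$chrom, length = genome$length),
               sequences = seqs)
}

draw_reads <- function(config, genome, truth, enrichment, depth, lambda_bg) {
  n_site <- if (nrow(truth)) rpois(nrow(truth), pmax(0, enrichment - 1) * lambda_bg)
            else integer(0)
  n_bg <- depth - sum(n_site)
  if (n_bg < 0) {
    abort("site reads exceed the configured depth; lower enrichment or raise depth")
  }
  half_read <- floor(config$read_length / 2)
  ## background midpoints uniform over the genome, kept off the edges
  cum <- c(0, cumsum(genome$length))
  abs_pos <- floor(runif(n_bg) * (sum(genome$length) - config$read_length)) +
    half_read
  ci <- findInterval(abs_pos, cum, left.open = FALSE)
  bg <- tibble(chrom = genome$chrom[ci], mid = abs_pos - cum[ci])
  site_mids <- if (sum(n_site)) {
    tibble(chrom = rep(truth$chrom, n_site),
           mid = rep(truth$center, n_site) +
             floor(runif(sum(n_site), -config$fragment_length,
                         config$fragment_length)))
  } else tibble(chrom = character(), mid = double())
  all_mids <- dplyr::bind_rows(bg, site_mids)
  maxlen <- chrom_length(genome, all_mids$chrom)
  all_mids$mid <- pmin(pmax(all_mids$mid, half_read), maxlen - half_read)
  reads <- tibble(chrom = all_mids$chrom,
                  start = all_mids$mid - half_read,
                  end = all_mids$mid - half_read + config$read_length,
                  strand = sample(c("+", "-"), nrow(all_mids), replace = TRUE))
  reads <- dplyr::arrange(reads, .data$chrom, .data$start)
  attr(reads, "depth") <- nrow(reads)
  reads
}

emit_peaks <- function(config, truth, reads, lambda_bg) {
  if (!nrow(truth)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character()))
  }
  counts <- window_counts_at(reads, truth, config$window)
  minimal <- qpois(1 - 1e-6, lambda_bg)
  keep <- counts >= pmax(minimal, 5)
  tibble(chrom = truth$chrom[keep], start = truth$center[keep] - 100,
         end = truth$center[keep] + 100, name = truth$site[keep],
         score = as.double(counts[keep]), strand = NA_character_)
}

#' Write a truth table as TSV
#' @param truth The `truth` tibble from [simulate_chip_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  hdr <- paste(names(truth), collapse = "\t")
  body <- do.call(paste, c(lapply(truth, as.character), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
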