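#' The seven-category genomic annotation scheme
#'
#' Categories, in fixed priority order: promoter (1 kb upstream of the
#' transcription start site), TTS (1 kb downstream of the transcription
#' termination site), 5' UTR, 3' UTR, exon (CDS-overlapping exonic
#' sequence), intron, and intergenic (the rest). When a base or site falls
#' in several categories through overlapping transcripts, the earliest
#' category in this order wins.
#'
#' @param promoter_upstream Bases upstream of the TSS counted as promoter
#'   (default 1000).
#' @param tts_downstream Bases downstream of the transcription end counted
#'   as TTS (default 1000).
#' @return A list of class `category_scheme` with the ordered `categories`.
#' @export
category_scheme <- function(promoter_upstream = 1000, tts_downstream = 1000) {
  if (promoter_upstream <= 0 || tts_downstream <= 0) {
    abort("promoter_upstream and tts_downstream must be > 0")
  }
  structure(list(
    categories = c("promoter", "TTS", "utr5", "utr3", "exon", "intron",
                   "intergenic"),
    promoter_upstream = promoter_upstream,
    tts_downstream = tts_downstream
  ), class = "category_scheme")
}

## Raw (pre-priority) intervals per category for one gene, 0-based
## half-open, strand-aware, clipped to chromosome bounds. Non-coding
## transcripts (cds_start == cds_end) contribute promoter/TTS/exon/intron
## but no UTR bases.
gene_category_intervals <- function(g, scheme, chrom_len) {
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  if (!length(es)) { es <- g$tx_start; ee <- g$tx_end }
  fwd <- g$strand == "+"
  prom <- if (fwd) c(g$tx_start - scheme$promoter_upstream, g$tx_start)
          else c(g$tx_end, g$tx_end + scheme$promoter_upstream)
  tts <- if (fwd) c(g$tx_end, g$tx_end + scheme$tts_downstream)
         else c(g$tx_start - scheme$tts_downstream, g$tx_start)
  clip <- function(iv) {
    s <- max(0, iv[1]); e <- min(chrom_len, iv[2])
    if (e > s) cbind(s, e) else NULL
  }
  coding <- g$cds_start < g$cds_end
  cs <- if (coding) g$cds_start else g$tx_start
  ce <- if (coding) g$cds_end else g$tx_end
  ## intersect exons with a [lo, hi) band
  band <- function(lo, hi) {
    s <- pmax(es, lo); e <- pmin(ee, hi)
    k <- e > s
    if (any(k)) cbind(s[k], e[k]) else NULL
  }
  utr_left <- band(g$tx_start, cs)   # exonic sequence 5' of CDS in genome order
  utr_right <- band(ce, g$tx_end)
  list(
    promoter = clip(prom),
    TTS = clip(tts),
    utr5 = if (!coding) NULL else if (fwd) utr_left else utr_right,
    utr3 = if (!coding) NULL else if (fwd) utr_right else utr_left,
    exon = band(cs, ce),
    intron = cbind(g$tx_start, g$tx_end)  # refined to non-exonic by priority
  )
}

#' Disjoint category ranges covering the whole genome
#'
#' Builds one [GenomicRanges::GRanges] per category, priority-resolved so
#' the seven sets partition the genome base-wise: promoter ranges are taken
#' as-is, each later category keeps only bases not claimed by an earlier
#' one, and intergenic is the remainder. Both site annotation and the
#' genomic background fractions are computed from this single partition, so
#' they can never disagree.
#'
#' @param genes A gene-model tibble ([read_gene_models()]).
#' @param genome A `genome_model`.
#' @param scheme A [category_scheme()].
#' @return A named list of `GRanges` (1-based closed, as usual for
#'   Bioconductor containers), one per category.
#' @export
build_category_ranges <- function(genes, genome, scheme = category_scheme()) {
  check_nonempty_genome(genome)
  seqinfo <- GenomeInfoDb::Seqinfo(genome$chrom, genome$length)
  raw <- stats::setNames(vector("list", 6L), scheme$categories[1:6])
  for (nm in names(raw)) raw[[nm]] <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ivs <- gene_category_intervals(g, scheme, chrom_length(genome, g$chrom))
    for (nm in names(ivs)) {
      if (!is.null(ivs[[nm]])) {
        raw[[nm]][[length(raw[[nm]]) + 1L]] <-
          GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(ivs[[nm]][, 1] + 1,
                                                  ivs[[nm]][, 2]),
                                 seqinfo = seqinfo)
      }
    }
  }
  empty <- GenomicRanges::GRanges(seqinfo = seqinfo)
  out <- list()
  claimed <- empty
  for (nm in scheme$categories[1:6]) {
    this <- if (length(raw[[nm]])) {
      GenomicRanges::reduce(do.call(c, raw[[nm]]))
    } else empty
    this <- GenomicRanges::setdiff(this, claimed)
    out[[nm]] <- this
    claimed <- GenomicRanges::reduce(c(claimed, this))
  }
  whole <- GenomicRanges::GRanges(genome$chrom,
                                  IRanges::IRanges(1, genome$length),
                                  seqinfo = seqinfo)
  out[["intergenic"]] <- GenomicRanges::setdiff(whole, claimed)
  out
}

#' Annotate site positions with their genomic category
#'
#' @param sites A tibble with `chrom` and `center` columns (any extra
#'   columns, e.g. `label`, are kept).
#' @param genes,genome,scheme As in [build_category_ranges()]; a
#'   pre-built partition can be passed via `ranges` to avoid recomputing.
#' @param ranges Optional result of [build_category_ranges()].
#' @return `sites` with a `category` factor column (levels in scheme
#'   order).
#' @export
annotate_sites <- function(sites, genes, genome, scheme = category_scheme(),
                           ranges = NULL) {
  if (is.null(ranges)) ranges <- build_category_ranges(genes, genome, scheme)
  bad <- !sites$chrom %in% genome$chrom
  if (any(bad)) abort(paste0("unknown chromosome: ", sites$chrom[bad][1]))
  cat <- rep("intergenic", nrow(sites))
  if (nrow(sites)) {
    pos <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$center + 1,
                                                   sites$center + 1))
    for (nm in setdiff(scheme$categories, "intergenic")) {
      hit <- IRanges::overlapsAny(pos, ranges[[nm]])
      cat[hit & cat == "intergenic"] <- nm
    }
  }
  sites$category <- factor(cat, levels = scheme$categories)
  sites
}

#' Category of a single genomic position
#'
#' @param genes A gene-model tibble.
#' @param scheme A [category_scheme()].
#' @param chrom,position The query position (0-based).
#' @param genome A `genome_model`.
#' @return A single category name.
#' @examples
#' # a position 500 bp upstream of a + strand TSS annotates as "promoter"
#' @export
annotate_position <- function(genes, scheme = category_scheme(), chrom,
                              position, genome) {
  s <- annotate_sites(tibble(chrom = chrom, center = position),
                      genes, genome, scheme)
  as.character(s$category[[1]])
}

#' Per-category site counts and fractions
#'
#' Counts site centers per category. When the input carries a `label`
#' column (an [compare_conditions()] result), profiles are computed
#' separately per class label; an `"all"` profile over every site is always
#' included. Fractions within each label sum to 1.
#'
#' @param sites A tibble with `chrom`, `center`, and optionally `label`.
#' @inheritParams annotate_sites
#' @return A tibble with `label`, `category`, `n`, `fraction`, `n_total`.
#' @export
category_profile <- function(sites, genes, genome, scheme = category_scheme(),
                             ranges = NULL) {
  if (!nrow(sites)) abort("empty site list")
  ann <- annotate_sites(sites, genes, genome, scheme, ranges = ranges)
  if (!"label" %in% names(ann)) ann$label <- "all"
  groups <- if (all(ann$label == "all")) list(all = ann) else
    c(list(all = ann), split(ann, ann$label))
  purrr::map_dfr(names(groups), function(lb) {
    g <- groups[[lb]]
    tab <- table(g$category)
    tibble(label = lb, category = factor(names(tab), levels = scheme$categories),
           n = as.integer(tab), fraction = as.integer(tab) / nrow(g),
           n_total = nrow(g))
  })
}

#' Genomic background fraction of each category
#'
#' Base-wise category fractions over the whole genome, using the same
#' priority-resolved partition as site annotation; the seven fractions sum
#' to exactly 1 for any gene set.
#'
#' @inheritParams build_category_ranges
#' @param ranges Optional pre-built [build_category_ranges()] result.
#' @return A tibble with `category`, `bases`, `fraction`.
#' @export
genomic_background_fractions <- function(genes, genome,
                                         scheme = category_scheme(),
                                         ranges = NULL) {
  if (is.null(ranges)) ranges <- build_category_ranges(genes, genome, scheme)
  bases <- vapply(scheme$categories, function(nm)
    sum(as.double(GenomicRanges::width(ranges[[nm]]))), double(1))
  tibble(category = factor(scheme$categories, levels = scheme$categories),
         bases = unname(bases), fraction = unname(bases) / sum(genome$length))
}

#' Log-space binomial ("Bernoulli") enrichment test
#'
#' One-sided upper-tail probability that at least `k` of `n` sites fall in
#' a category whose genomic base fraction is `p0`, i.e.
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, returned as `log10(p)`. The
#' entire computation stays in log-space, so probabilities far below the
#' smallest positive double (about 1e-308) are returned exactly instead of
#' underflowing to zero — the published promoter enrichment is of this
#' kind (p < 1e-310).
#'
#' @param k Sites observed in the category (0 <= k <= n).
#' @param n Total sites.
#' @param p0 Background fraction in (0, 1).
#' @return `log10` of the upper-tail probability (0 when `k == 0`).
#'   Vectorized.
#' @examples
#' enrichment_test(10, 10, 0.5) # 10 * log10(0.5)
#' @export
enrichment_test <- function(k, n, p0) {
  if (any(p0 <= 0 | p0 >= 1)) abort("`p0` must be in (0, 1)")
  if (any(k < 0 | k > n)) abort("must have 0 <= k <= n")
  pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Fold enrichment of an observed fraction over a background fraction
#'
#' @param fraction_observed Observed fraction among sites.
#' @param fraction_background Background fraction (> 0).
#' @return The ratio. Vectorized.
#' @examples
#' fold_over_background(0.083, 0.01) # ~ 8-fold
#' @export
fold_over_background <- function(fraction_observed, fraction_background) {
  if (any(fraction_background <= 0)) abort("background fraction must be > 0")
  fraction_observed / fraction_background
}

#' Per-class category enrichment against the genomic background
#'
#' Combines [category_profile()], [genomic_background_fractions()],
#' [enrichment_test()] and [fold_over_background()] into the standard
#' enrichment table: for every class label and category, the observed
#' count `k` out of `n` sites, the background fraction `p0`, the log10
#' upper-tail p-value, and the fold over background.
#'
#' @inheritParams category_profile
#' @return A tibble with `label`, `category`, `k`, `n`, `p0`, `log10_p`,
#'   `fold`.
#' @export
category_enrichment <- function(sites, genes, genome,
                                scheme = category_scheme()) {
  ranges <- build_category_ranges(genes, genome, scheme)
  prof <- category_profile(sites, genes, genome, scheme, ranges = ranges)
  bg <- genomic_background_fractions(genes, genome, scheme, ranges = ranges)
  out <- dplyr::left_join(prof, bg[, c("category", "fraction")],
                          by = "category", suffix = c("", "_bg"))
  ## categories with zero genomic footprint are untestable, drop them
  out <- out[out$fraction_bg > 0, , drop = FALSE]
  tibble(label = out$label, category = out$category, k = out$n,
         n = out$n_total, p0 = out$fraction_bg,
         log10_p = enrichment_test(out$n, out$n_total, out$fraction_bg),
         fold = fold_over_background(out$fraction, out$fraction_bg))
}
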