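#' Parameters for the minimal sliding-window peak caller
#'
#' @param window Window width in bases (default 200).
#' @param step Step between window starts; must satisfy
#'   `window >= step > 0` (default 50).
#' @param fdr_alpha Benjamini-Hochberg threshold on window q-values
#'   (default 0.001).
#' @param min_fold_over_input Minimum ratio of ChIP window count to the
#'   depth-scaled control expectation (default 4).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(window = 200, step = 50, fdr_alpha = 0.001,
                          min_fold_over_input = 4) {
  if (step <= 0 || window < step) abort("must have window >= step > 0")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("`fdr_alpha` must be in (0, 1)")
  if (min_fold_over_input <= 0) abort("`min_fold_over_input` must be > 0")
  structure(list(window = window, step = step, fdr_alpha = fdr_alpha,
                 min_fold_over_input = min_fold_over_input),
            class = "caller_params")
}

#' Minimal sliding-window peak caller
#'
#' A deliberately simple plumbing caller so the pipeline can run end-to-end
#' when no external peak list is available: genome-tiling windows are
#' scored by the Poisson upper tail of the ChIP count against the
#' depth-scaled control expectation, q-values are Benjamini-Hochberg
#' adjusted across all windows, and overlapping windows that pass both the
#' q-value and fold filters are merged into peaks. It approximates, and
#' makes no attempt to reproduce, production callers; real analyses should
#' supply externally called peak BEDs.
#'
#' @param chip,control Read tibbles (control is typically sequenced input);
#'   both must be non-empty.
#' @param genome A `genome_model`.
#' @param params A [caller_params()] list.
#' @return A peaks tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) where `score` is the peak's best `-log10(q)`; merged peaks
#'   never overlap.
#' @export
call_peaks <- function(chip, control, genome, params = caller_params()) {
  check_nonempty_genome(genome)
  depth_chip <- read_depth(chip)
  depth_ctrl <- read_depth(control)
  if (depth_chip <= 0) abort("empty ChIP read set")
  if (depth_ctrl <= 0) abort("empty control read set")
  scale <- depth_chip / depth_ctrl
  res <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]; L <- genome$length[ci]
    starts <- seq(0, max(0, L - params$window), by = params$step)
    wins <- tibble(chrom = ch, center = starts + params$window / 2)
    cc <- window_counts_at(chip[chip$chrom == ch, ], wins, params$window)
    cb <- window_counts_at(control[control$chrom == ch, ], wins, params$window)
    ## genome-wide floor on the control expectation guards empty control bins
    lambda_floor <- depth_ctrl * params$window / sum(genome$length)
    lambda <- pmax(cb, lambda_floor) * scale
    p <- ppois(cc - 1, lambda, lower.tail = FALSE)
    fold <- cc / lambda
    res[[ci]] <- tibble(chrom = ch, start = starts,
                        end = pmin(starts + params$window, L),
                        p = p, fold = fold)
  }
  win <- dplyr::bind_rows(res)
  win$q <- p.adjust(win$p, method = "BH")
  sig <- win[win$q <= params$fdr_alpha &
               win$fold >= params$min_fold_over_input, , drop = FALSE]
  if (!nrow(sig)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character()))
  }
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start + 1, sig$end),
                               score = -log10(pmax(sig$q, .Machine$double.xmin)))
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  best <- vapply(S4Vectors::mcols(merged)$revmap,
                 function(ix) max(S4Vectors::mcols(gr)$score[ix]), double(1))
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(merged)),
                start = GenomicRanges::start(merged) - 1,
                end = as.double(GenomicRanges::end(merged)),
                score = best,
                strand = NA_character_)
  out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  dplyr::arrange(out[, c("chrom", "start", "end", "name", "score", "strand")],
                 .data$chrom, .data$start)
}

#' Center of a peak interval
#'
#' Defined as `floor((start + end) / 2)` — a deterministic tie-break for
#' even-length peaks.
#'
#' @param peaks A peaks tibble (or any tibble with `start` and `end`).
#' @return Numeric vector of center positions.
#' @examples
#' peak_center(tibble::tibble(start = c(100, 100, 0), end = c(300, 301, 1)))
#' @export
peak_center <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}
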