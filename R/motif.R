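#' Parameters for PWM motif scanning
#'
#' @param threshold_fraction A window is motif-positive when its best
#'   log-odds score reaches this fraction of the maximum achievable score
#'   (in `(0, 1]`, default 0.8). Production motif scanners do not publish a
#'   universal cutoff; a fraction of the maximum is portable across
#'   matrices and is reported in all outputs.
#' @param scan_window Even width in bases of the sequence window scanned
#'   around each site center (default 200, matching the comparison
#'   window).
#' @param background_samples Number of random genome windows used to
#'   estimate the background motif rate (default 10000).
#' @param seed Seed for background sampling (default 1).
#' @return A list of class `motif_scan_params`.
#' @export
motif_scan_params <- function(threshold_fraction = 0.8, scan_window = 200,
                              background_samples = 10000, seed = 1) {
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("`threshold_fraction` must be in (0, 1]")
  }
  if (scan_window <= 0 || scan_window %% 2 != 0) {
    abort("`scan_window` must be even and > 0")
  }
  structure(list(threshold_fraction = threshold_fraction,
                 scan_window = scan_window,
                 background_samples = background_samples, seed = seed),
            class = "motif_scan_params")
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L,
              a = 1L, c = 2L, g = 3L, t = 4L, n = 5L)
DNA_COMP <- c(4L, 3L, 2L, 1L, 5L)

encode_seq <- function(s) {
  idx <- DNA_CODE[strsplit(s, "", fixed = TRUE)[[1]]]
  if (anyNA(idx)) abort("sequence contains characters other than A/C/G/T/N")
  unname(idx)
}

## Best log2-odds over all offsets and both strands for a list of encoded
## sequences (integer vectors). S is the L x 5 score matrix.
best_scores_encoded <- function(idx_list, S) {
  L <- nrow(S)
  vapply(idx_list, function(idx) {
    W <- length(idx)
    if (W < L) abort("sequence shorter than the motif")
    n_off <- W - L + 1L
    pos <- rep(0:(n_off - 1L), each = L) + seq_len(L)
    fwd <- colSums(matrix(S[cbind(rep(seq_len(L), n_off), idx[pos])], nrow = L))
    rc <- rev(DNA_COMP[idx])
    rev_ <- colSums(matrix(S[cbind(rep(seq_len(L), n_off), rc[pos])], nrow = L))
    max(fwd, rev_)
  }, double(1))
}

#' Best log-odds score of a PWM anywhere in a sequence
#'
#' Scores every offset on both strands (the reverse strand is scored on
#' the reverse complement) and returns the maximum summed log2-odds.
#' `N` bases score as background and contribute 0.
#'
#' @param pwm A [pwm()] object.
#' @param sequence A nucleotide string at least as long as the motif.
#' @return The maximum score (a single number). A sequence equal to the
#'   consensus attains [pwm_max_score()]; for a uniform matrix every score
#'   is 0.
#' @export
best_log_odds <- function(pwm, sequence) {
  best_scores_encoded(list(encode_seq(sequence)), pwm_score_matrix(pwm))[[1]]
}

#' Does the window around a site contain a motif?
#'
#' Extracts `scan_window` bases centered on the site (truncated at
#' chromosome ends; an error only if fewer bases than the motif length
#' remain) and tests whether the best log-odds score reaches
#' `threshold_fraction` of the maximum achievable score.
#'
#' @param pwm A [pwm()] object.
#' @param genome A `genome_model` with sequences attached.
#' @param chrom,center Site position.
#' @param params A [motif_scan_params()] list.
#' @return `TRUE` or `FALSE`.
#' @export
site_has_motif <- function(pwm, genome, chrom, center,
                           params = motif_scan_params()) {
  half <- params$scan_window / 2
  s <- extract_window_seq(genome, chrom, center - half, center + half)
  if (nchar(s) < ncol(pwm$counts)) {
    abort("window truncated below the motif length at the chromosome end")
  }
  best_log_odds(pwm, s) >= params$threshold_fraction * pwm_max_score(pwm)
}

#' Motif-occurrence fraction per site class
#'
#' Scans the window around every site for the motif, reports the
#' motif-positive fraction per class label (plus an `"all"` row), and
#' compares each to the background rate estimated from seeded random
#' genome windows of the same width. A zero background yields an infinite
#' fold with a warning.
#'
#' @param sites A tibble with `chrom`, `center` and (optionally) `label`;
#'   typically a [compare_conditions()] result.
#' @param pwm A [pwm()] object.
#' @param genome A `genome_model` with sequences.
#' @param params A [motif_scan_params()] list.
#' @return A tibble with `label`, `n`, `n_motif`, `fraction`,
#'   `background_fraction`, `fold`, of class `motif_report`.
#' @export
motif_fraction_report <- function(sites, pwm, genome,
                                  params = motif_scan_params()) {
  if (!nrow(sites)) abort("empty site list")
  S <- pwm_score_matrix(pwm)
  maxs <- pwm_max_score(pwm)
  thr <- params$threshold_fraction * maxs
  half <- params$scan_window / 2
  seqs <- lapply(seq_len(nrow(sites)), function(i)
    encode_seq(extract_window_seq(genome, sites$chrom[i],
                                  sites$center[i] - half,
                                  sites$center[i] + half)))
  hit <- best_scores_encoded(seqs, S) >= thr
  lab <- if ("label" %in% names(sites)) sites$label else rep("all", nrow(sites))
  bg_frac <- motif_background_fraction(pwm, genome, params)
  groups <- if (all(lab == "all")) list(all = hit) else
    c(list(all = hit), split(hit, lab))
  out <- purrr::map_dfr(names(groups), function(lb) {
    h <- groups[[lb]]
    tibble(label = lb, n = length(h), n_motif = sum(h),
           fraction = mean(h), background_fraction = bg_frac)
  })
  if (bg_frac == 0 && any(out$fraction > 0)) {
    warn("background motif fraction is 0; fold over background is infinite")
  }
  out$fold <- ifelse(out$fraction == 0 & bg_frac == 0, NA_real_,
                     out$fraction / bg_frac)
  class(out) <- c("motif_report", class(out))
  out
}

#' Background motif rate from random genome windows
#'
#' Samples `background_samples` windows of `scan_window` bases uniformly
#' from the genome (chromosomes weighted by length) under the params seed
#' and returns the motif-positive fraction. Identical seeds give identical
#' samples.
#'
#' @inheritParams motif_fraction_report
#' @return A fraction in `[0, 1]`.
#' @export
motif_background_fraction <- function(pwm, genome,
                                      params = motif_scan_params()) {
  check_nonempty_genome(genome)
  n <- params$background_samples
  if (n <= 0) return(0)
  S <- pwm_score_matrix(pwm)
  thr <- params$threshold_fraction * pwm_max_score(pwm)
  w <- params$scan_window
  withr::with_seed(params$seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE,
                     prob = genome$length / sum(genome$length))
    starts <- floor(runif(n) * pmax(1, genome$length[ci] - w))
    seqs <- lapply(seq_len(n), function(i)
      encode_seq(extract_window_seq(genome, genome$chrom[ci[i]],
                                    starts[i], starts[i] + w)))
    mean(best_scores_encoded(seqs, S) >= thr)
  })
}
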