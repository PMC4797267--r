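#' Parameters for the two-condition occupancy comparison
#'
#' Defaults mirror the published classification rule: reads are counted in
#' a 200-bp window around each peak center, and a site is called induced
#' (or repressed) when the depth-normalized signal differs by 4-fold or
#' more *and* the exact-test p-value is at most 1e-4; both thresholds are
#' inclusive. Everything else is common.
#'
#' @param window Window width in bases centered on the peak center; must be
#'   even (default 200).
#' @param fold_cut Fold-change threshold, > 1 (default 4).
#' @param p_cut P-value threshold in (0, 1) (default 1e-4).
#' @param pseudocount Pseudocount added to each depth-normalized signal
#'   (reads per ten million) before forming the fold change (default 1).
#' @return A list of class `diff_params`.
#' @export
diff_params <- function(window = 200, fold_cut = 4, p_cut = 1e-4,
                        pseudocount = 1) {
  if (window <= 0 || window %% 2 != 0) abort("`window` must be even and > 0")
  if (fold_cut <= 1) abort("`fold_cut` must be > 1")
  if (p_cut <= 0 || p_cut >= 1) abort("`p_cut` must be in (0, 1)")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  structure(list(window = window, fold_cut = fold_cut, p_cut = p_cut,
                 pseudocount = pseudocount), class = "diff_params")
}

#' Count reads in a window around a position
#'
#' A read is in the window when its midpoint (floor of the interval
#' midpoint) lies in `[center - window/2, center + window/2)`; each read is
#' counted at most once per window.
#'
#' @param reads A reads tibble (`chrom`, `start`, `end`, ...).
#' @param chrom Chromosome name.
#' @param center Window center (0-based).
#' @param window Even window width in bases.
#' @param genome Optional `genome_model`; when given, `chrom` must be one
#'   of its chromosomes.
#' @return Integer count.
#' @examples
#' reads <- tibble::tibble(chrom = "chrT", start = c(100, 149, 150),
#'                         end = c(200, 249, 250))
#' window_count(reads, "chrT", 100, 200) # midpoints 150, 199, 200 -> 2
#' @export
window_count <- function(reads, chrom, center, window, genome = NULL) {
  if (window <= 0 || window %% 2 != 0) abort("`window` must be even and > 0")
  if (!is.null(genome)) chrom_length(genome, chrom)
  if (!nrow(reads)) return(0L)
  m <- read_midpoints(reads)[reads$chrom == chrom]
  sum(m >= center - window / 2 & m < center + window / 2)
}

## Vectorized window counts for many sites against one read set.
## sites: tibble with chrom, center. Returns integer vector.
window_counts_at <- function(reads, sites, window) {
  out <- integer(nrow(sites))
  if (!nrow(reads) || !nrow(sites)) return(out)
  mids <- split(read_midpoints(reads), reads$chrom)
  for (ch in unique(sites$chrom)) {
    m <- sort(mids[[ch]])
    idx <- which(sites$chrom == ch)
    if (!length(m)) next
    lo <- sites$center[idx] - window / 2
    hi <- sites$center[idx] + window / 2
    out[idx] <- findInterval(hi - 0.5, m) - findInterval(lo - 0.5, m)
  }
  out
}

#' Exact two-condition p-value for a pair of window counts
#'
#' The standard conditional test for comparing two Poisson-like counts with
#' known totals: given `n = count_a + count_b` reads in the window, under
#' the null of no occupancy difference `count_b` is binomial with success
#' probability `depth_b / (depth_a + depth_b)`. The two-sided p-value sums
#' all outcomes whose probability does not exceed that of the observed one
#' (minimum-likelihood rule, with the conventional `1 + 1e-7` relative tie
#' tolerance). Returns 1 when both counts are zero. The computation is
#' canonicalized over the ordering of the two conditions so that swapping
#' (a, b) gives bit-identical p-values.
#'
#' @param count_a,count_b Window counts in the two conditions
#'   (non-negative).
#' @param depth_a,depth_b Total mapped reads per condition (> 0).
#' @return P-value(s) in (0, 1]. Vectorized over counts.
#' @examples
#' differential_pvalue(0, 10, 1e6, 1e6) # 2 * 0.5^10
#' @export
differential_pvalue <- function(count_a, count_b, depth_a, depth_b) {
  if (any(depth_a <= 0) || any(depth_b <= 0)) abort("depths must be > 0")
  if (any(count_a < 0) || any(count_b < 0)) abort("counts must be non-negative")
  n <- length(count_a)
  stopifnot(length(count_b) == n)
  depth_a <- rep_len(depth_a, n); depth_b <- rep_len(depth_b, n)
  vapply(seq_len(n), function(i) {
    binom_twosided(count_a[i], count_b[i], depth_a[i], depth_b[i])
  }, double(1))
}

binom_twosided <- function(ca, cb, da, db) {
  ## canonical orientation: test the condition with the lexicographically
  ## larger (depth, count); exact symmetry under condition swap
  if (db > da || (db == da && cb > ca)) {
    x <- cb; p <- db / (da + db)
  } else {
    x <- ca; p <- da / (da + db)
  }
  n <- ca + cb
  if (n == 0) return(1)
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Depth-normalized fold change between conditions
#'
#' Signals are scaled to reads per ten million mapped reads and guarded
#' with a pseudocount, so the fold change is defined (and equals 1) even
#' when both counts are zero:
#' `((count_b * 1e7 / depth_b) + pc) / ((count_a * 1e7 / depth_a) + pc)`.
#' Condition B is the treated condition, so values above 1 mean induction.
#'
#' @inheritParams differential_pvalue
#' @param pseudocount Pseudocount in reads-per-ten-million units
#'   (default 1).
#' @return Fold change(s) > 0. Vectorized.
#' @examples
#' fold_change(10, 40, 1e7, 1e7) # 41/11
#' @export
fold_change <- function(count_a, count_b, depth_a, depth_b, pseudocount = 1) {
  if (any(depth_a <= 0) || any(depth_b <= 0)) abort("depths must be > 0")
  ((count_b * 1e7 / depth_b) + pseudocount) /
    ((count_a * 1e7 / depth_a) + pseudocount)
}

#' Classify a site from its fold change and p-value
#'
#' Thresholds are inclusive exactly as published: induced when
#' `fold_change >= fold_cut` and `p_value <= p_cut`; repressed when
#' `fold_change <= 1/fold_cut` and `p_value <= p_cut`; common otherwise.
#'
#' @param fold_change,p_value Numeric vectors.
#' @param params A [diff_params()] list.
#' @return A character vector in `c("induced", "repressed", "common")`.
#' @export
classify_site <- function(fold_change, p_value, params = diff_params()) {
  dplyr::case_when(
    fold_change >= params$fold_cut & p_value <= params$p_cut ~ "induced",
    fold_change <= 1 / params$fold_cut & p_value <= params$p_cut ~ "repressed",
    .default = "common"
  )
}

#' Compare occupancy between two conditions at the union of peak centers
#'
#' Evaluation sites are the union of peak centers from both conditions,
#' deduplicated by greedy merging: centers closer than `window/2` are
#' clustered and the cluster is represented by the center with the largest
#' summed window count (`count_a + count_b`). Each retained center gets
#' window counts, depth-normalized signals, fold change, exact p-value, a
#' class label, and the volcano-plot coordinates.
#'
#' @param peaks_a,peaks_b Peak tibbles for the untreated (A) and treated
#'   (B) conditions; either may be empty, but not both.
#' @param reads_a,reads_b Read tibbles per condition; depths are taken with
#'   [read_depth()].
#' @param params A [diff_params()] list.
#' @return A tibble of class `occupancy_diff`, sorted by `chrom`, `center`,
#'   with columns `chrom`, `center`, `count_a`, `count_b`, `norm_a`,
#'   `norm_b`, `fold_change`, `p_value`, `label`, `log2_fold`,
#'   `neglog10_p`. Depths and parameters ride along as attributes.
#' @export
compare_conditions <- function(peaks_a, peaks_b, reads_a, reads_b,
                               params = diff_params()) {
  if ((is.null(peaks_a) || !nrow(peaks_a)) && (is.null(peaks_b) || !nrow(peaks_b))) {
    abort("no peaks supplied in either condition")
  }
  depth_a <- read_depth(reads_a); depth_b <- read_depth(reads_b)
  if (depth_a <= 0 || depth_b <= 0) abort("both read sets must be non-empty")
  cand <- dplyr::bind_rows(
    if (!is.null(peaks_a) && nrow(peaks_a))
      tibble(chrom = peaks_a$chrom, center = peak_center(peaks_a)),
    if (!is.null(peaks_b) && nrow(peaks_b))
      tibble(chrom = peaks_b$chrom, center = peak_center(peaks_b))
  )
  cand <- dplyr::arrange(cand, .data$chrom, .data$center)
  cand$count_a <- window_counts_at(reads_a, cand, params$window)
  cand$count_b <- window_counts_at(reads_b, cand, params$window)
  cand$total <- cand$count_a + cand$count_b
  sites <- dedup_centers(cand, params$window / 2)
  out <- tibble(chrom = sites$chrom, center = sites$center,
                count_a = sites$count_a, count_b = sites$count_b)
  out$norm_a <- out$count_a * 1e7 / depth_a
  out$norm_b <- out$count_b * 1e7 / depth_b
  out$fold_change <- fold_change(out$count_a, out$count_b, depth_a, depth_b,
                                 params$pseudocount)
  out$p_value <- differential_pvalue(out$count_a, out$count_b, depth_a, depth_b)
  out$label <- classify_site(out$fold_change, out$p_value, params)
  out$log2_fold <- log2(out$fold_change)
  out$neglog10_p <- -log10(pmax(out$p_value, .Machine$double.xmin))
  out <- dplyr::arrange(out, .data$chrom, .data$center)
  attr(out, "depth_a") <- depth_a
  attr(out, "depth_b") <- depth_b
  attr(out, "params") <- params
  class(out) <- c("occupancy_diff", class(out))
  out
}

## Greedy dedup of candidate centers: walk sorted centers per chromosome;
## successive centers closer than `min_gap` join the open cluster; each
## cluster keeps the row with the largest summed window count (earliest
## such row on ties, which is symmetric in the two conditions).
dedup_centers <- function(cand, min_gap) {
  keep <- logical(nrow(cand))
  i <- 1L
  while (i <= nrow(cand)) {
    j <- i
    while (j < nrow(cand) && cand$chrom[j + 1L] == cand$chrom[i] &&
           cand$center[j + 1L] - cand$center[j] < min_gap) {
      j <- j + 1L
    }
    block <- i:j
    keep[block[which.max(cand$total[block])]] <- TRUE
    i <- j + 1L
  }
  cand[keep, , drop = FALSE]
}

#' @export
print.occupancy_diff <- function(x, ...) {
  s <- table(factor(x$label, c("induced", "repressed", "common")))
  cat("<occupancy_diff> ", nrow(x), " sites: ",
      s[["induced"]], " induced, ", s[["repressed"]], " repressed, ",
      s[["common"]], " common (window ", attr(x, "params")$window,
      " bp, fold >= ", attr(x, "params")$fold_cut,
      ", p <= ", attr(x, "params")$p_cut, ")\n", sep = "")
  NextMethod()
}

#' Write an occupancy comparison as TSV with a commented header
#'
#' @param x An `occupancy_diff` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_diff <- function(x, path) {
  p <- attr(x, "params")
  hdr <- c(paste0("# occudiff comparison: window=", p$window,
                  " fold_cut=", p$fold_cut, " p_cut=", p$p_cut,
                  " pseudocount=", p$pseudocount),
           paste0("# depth_a=", attr(x, "depth_a"),
                  " depth_b=", attr(x, "depth_b")),
           paste0("# classes: ", paste(sprintf("%s=%d",
                  c("induced", "repressed", "common"),
                  as.integer(table(factor(x$label, c("induced", "repressed", "common"))))),
                  collapse = " ")),
           paste(c("chrom", "center", "count_a", "count_b", "fold_change",
                   "p_value", "label"), collapse = "\t"))
  body <- sprintf("%s\t%d\t%d\t%d\t%.6g\t%.6g\t%s",
                  x$chrom, as.integer(x$center), as.integer(x$count_a),
                  as.integer(x$count_b), x$fold_change, x$p_value, x$label)
  writeLines(c(hdr, body), path)
  invisible(path)
}
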