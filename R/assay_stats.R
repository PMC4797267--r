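#' Percentage of protein co-fractionating with chromatin
#'
#' Band intensities are normalized to a loading control measured in the
#' same fraction, and the chromatin-bound percentage is
#' `100 * nC / (nC + nS * concentration_factor)` with `nC = csb_C/ctrl_C`,
#' `nS = csb_S/ctrl_S`. The concentration factor compensates for the
#' chromatin fraction being more concentrated than the soluble fraction
#' during sample preparation; the default 1.3 reflects the buffer volumes
#' of the fractionation protocol the formula comes from, and other
#' protocols should set their own.
#'
#' The result is invariant to rescaling all four intensities by a common
#' factor.
#'
#' @param csb_C,csb_S Target-protein band intensities in the
#'   chromatin-enriched (C) and soluble (S) fractions (non-negative).
#' @param ctrl_C,ctrl_S Loading-control intensities in the same fractions
#'   (strictly positive).
#' @param concentration_factor Relative concentration of the C fraction
#'   (default 1.3).
#' @return Percentage in `[0, 100]`. Vectorized.
#' @examples
#' chromatin_fraction_percent(1, 1, 1, 1) # 100 / 2.3
#' @export
chromatin_fraction_percent <- function(csb_C, csb_S, ctrl_C, ctrl_S,
                                       concentration_factor = 1.3) {
  if (any(ctrl_C <= 0) || any(ctrl_S <= 0)) {
    abort("loading-control intensities must be > 0")
  }
  if (any(csb_C < 0) || any(csb_S < 0)) abort("intensities must be non-negative")
  nC <- csb_C / ctrl_C
  nS <- csb_S / ctrl_S
  if (any(nC + nS == 0)) {
    abort("both normalized signals are zero; the fraction is undefined")
  }
  100 * nC / (nC + nS * concentration_factor)
}

#' Percent survival after treatment
#'
#' The ratio of viable treated cells to viable untreated cells, as a
#' percentage. Homogeneous of degree zero: doubling both counts changes
#' nothing.
#'
#' @param treated_viable,untreated_viable Viable-cell counts;
#'   `untreated_viable` must be > 0.
#' @return Percentage. Vectorized.
#' @examples
#' percent_survival(500, 1000) # 50
#' @export
percent_survival <- function(treated_viable, untreated_viable) {
  if (any(untreated_viable <= 0)) abort("untreated count must be > 0")
  if (any(treated_viable < 0)) abort("treated count must be non-negative")
  100 * treated_viable / untreated_viable
}

#' Paired t-test on replicate measurements
#'
#' Standard paired t statistic on the differences `y - x` with `n - 1`
#' degrees of freedom and a two-sided p-value. Degenerate inputs are
#' resolved explicitly rather than erroring: identical pairs give
#' `t = 0, p = 1`; zero-variance differences with a nonzero mean give an
#' infinite t and `p = 0`, flagged `degenerate`.
#'
#' @param x,y Paired replicate values (equal length, at least 2 pairs).
#' @return A one-row tibble with `t`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`, and `stars` (`*` p < 0.05, `**` p < 0.01, `***`
#'   p < 0.001).
#' @examples
#' paired_t_test(c(0, 1, 3), c(1, 3, 6)) # differences 1, 2, 3
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- y - x
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(t = 0, df = length(d) - 1, p_value = 1, mean_diff = 0,
                    degenerate = TRUE, stars = ""))
    }
    warn("zero-variance differences with nonzero mean; p-value degenerates to 0")
    return(tibble(t = sign(mean(d)) * Inf, df = length(d) - 1, p_value = 0,
                  mean_diff = mean(d), degenerate = TRUE, stars = "***"))
  }
  ht <- stats::t.test(y, x, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = unname(ht$estimate),
         degenerate = FALSE, stars = significance_stars(ht$p.value))
}

#' Significance stars for a p-value
#'
#' The usual convention: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' empty otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}
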