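#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an occupancy comparison
#'
#' Returns the site-level table as a plain tibble (one row per evaluation
#' site) with the volcano coordinates included.
#'
#' @param x An `occupancy_diff` from [compare_conditions()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.occupancy_diff <- function(x, ...) {
  out <- x
  attr(out, "params") <- NULL
  attr(out, "depth_a") <- NULL
  attr(out, "depth_b") <- NULL
  class(out) <- setdiff(class(out), "occupancy_diff")
  as_tibble(out)
}

#' One-row summary of an occupancy comparison
#'
#' @param x An `occupancy_diff` from [compare_conditions()].
#' @param ... Unused.
#' @return A one-row tibble with the class counts, total sites, depths,
#'   and thresholds.
#' @export
glance.occupancy_diff <- function(x, ...) {
  p <- attr(x, "params")
  s <- table(factor(x$label, c("induced", "repressed", "common")))
  tibble(n_sites = nrow(x),
         n_induced = as.integer(s[["induced"]]),
         n_repressed = as.integer(s[["repressed"]]),
         n_common = as.integer(s[["common"]]),
         depth_a = attr(x, "depth_a"), depth_b = attr(x, "depth_b"),
         window = p$window, fold_cut = p$fold_cut, p_cut = p$p_cut)
}
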