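#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-structure ratio fit
#'
#' @param x An [ratio_per_structure()] result.
#' @param ... Unused.
#' @return One row per model (`through_origin`, `with_intercept`) with
#'   `slope`, `intercept`, `r_squared` and the degeneracy flag.
#' @export
tidy.nf_ratio <- function(x, ...) {
  co0 <- stats::coef(x$through_origin)
  co1 <- stats::coef(x$with_intercept)
  tibble::tibble(
    model = c("through_origin", "with_intercept"),
    slope = c(co0[["a"]], co1[["a"]]),
    intercept = c(0, co1[["(Intercept)"]]),
    r_squared = c(summary(x$through_origin)$r.squared,
                  summary(x$with_intercept)$r.squared),
    degenerate = x$degenerate
  )
}

#' @rdname tidy.nf_ratio
#' @export
glance.nf_ratio <- function(x, ...) {
  tibble::tibble(slope = stats::coef(x$through_origin)[["a"]],
                 n = x$n, degenerate = x$degenerate)
}

#' Tidy a Monte-Carlo null simulation
#'
#' @param x A [simulate_null()] result.
#' @param ... Unused.
#' @return Per-iteration medians (`iteration`, `median_nm`).
#' @export
tidy.nf_null <- function(x, ...) x$medians

#' @rdname tidy.nf_null
#' @export
glance.nf_null <- function(x, ...) {
  tibble::tibble(
    n_iter = x$config$n_iter,
    n_query = x$config$n_query,
    n_target = x$config$n_target,
    sphere_radius_um = x$config$sphere_radius_um,
    pooled_median_nm = stats::median(x$distances$distance_nm),
    median_of_medians_nm = stats::median(x$medians$median_nm)
  )
}

#' Tidy a smoothing-factor match
#'
#' @param x A [match_smoothing()] result.
#' @param ... Unused.
#' @return The scan table (`w`, `n_domains`, `abs_diff`).
#' @export
tidy.nf_match <- function(x, ...) x$scan

#' @rdname tidy.nf_match
#' @export
glance.nf_match <- function(x, ...) {
  tibble::tibble(chosen_w = x$chosen_w, target = x$target,
                 n_domains = nrow(x$domains),
                 linear_coverage_bp = domain_coverage(x$domains))
}

#' Tidy a motif scan
#'
#' @param x A [scan_motif()] result.
#' @param ... Unused.
#' @return The site table.
#' @export
tidy.nf_motif <- function(x, ...) x$sites

#' @rdname tidy.nf_motif
#' @export
glance.nf_motif <- function(x, ...) {
  q <- if (nrow(x$distances) > 0L) {
    stats::quantile(x$distances$distance_bp, c(0.25, 0.5, 0.75), names = FALSE)
  } else rep(NA_real_, 3L)
  tibble::tibble(n_sites = nrow(x$sites),
                 median_distance_bp = q[2],
                 iqd_low_bp = q[1], iqd_high_bp = q[3])
}
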