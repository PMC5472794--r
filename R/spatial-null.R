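#' Nearest-neighbour distances between two centroid sets
#'
#' For every query point, the minimum Euclidean distance to any target
#' point. Inputs are tibbles with `centroid_{x,y,z}_nm` columns or plain
#' 3-column matrices (nm).
#'
#' @param query,target Point sets; `target` must be non-empty.
#' @return A tibble `query_id`, `distance_nm`.
#' @export
nearest_distances <- function(query, target) {
  q <- as_points(query)
  t <- as_points(target)
  if (nrow(t) == 0L) stop("`target` set is empty", call. = FALSE)
  if (nrow(q) == 0L) {
    return(tibble::tibble(query_id = integer(0), distance_nm = numeric(0)))
  }
  d2 <- outer(rowSums(q^2), rep(1, nrow(t))) +
    outer(rep(1, nrow(q)), rowSums(t^2)) - 2 * q %*% t(t)
  d2 <- pmax(d2, 0)
  j <- max.col(-d2, ties.method = "first")
  tibble::tibble(query_id = seq_len(nrow(q)),
                 distance_nm = sqrt(d2[cbind(seq_len(nrow(q)), j)]))
}

as_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(unname(x))
  }
  centroid_matrix(x)
}

#' Uniform random points in a ball
#'
#' Radius is drawn as `R * U^(1/3)` and the direction uniformly on the
#' sphere, giving a uniform density over the ball volume.
#'
#' @param n Number of points.
#' @param radius Ball radius.
#' @return An `n x 3` matrix centred at the origin.
#' @export
runif_ball <- function(n, radius) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  dir <- dir / nrm
  dir * (radius * stats::runif(n)^(1 / 3))
}

#' Configuration for the uniform-sphere Monte-Carlo null
#'
#' @param sphere_radius_um Sphere radius in um, typically the
#'   sphere-equivalent radius of the mean segmented nuclear volume.
#' @param n_query,n_target Object counts per simulation, matching the
#'   observed per-nucleus counts of the two channels.
#' @param n_iter Number of simulations (default 100).
#' @param seed Integer seed.
#' @return A list of class `null_config`.
#' @export
null_config <- function(sphere_radius_um, n_query, n_target,
                        n_iter = 100L, seed = 1L) {
  stopifnot(sphere_radius_um > 0, n_query >= 1L, n_target >= 1L, n_iter >= 1L)
  structure(list(sphere_radius_um = sphere_radius_um,
                 n_query = as.integer(n_query),
                 n_target = as.integer(n_target),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "null_config")
}

#' Monte-Carlo null of nearest-neighbour distances in a sphere
#'
#' Per iteration, `n_query` query and `n_target` target points are drawn
#' uniformly in a ball of the configured radius and the per-query
#' nearest distances are computed. Both the pooled distance distribution
#' and per-iteration medians are returned, since either may be compared
#' with the observed distances.
#'
#' @param cfg A [null_config()].
#' @return An object of class `nf_null`: `distances` tibble
#'   (`iteration`, `distance_nm`), `medians` tibble (`iteration`,
#'   `median_nm`), and the config.
#' @export
simulate_null <- function(cfg) {
  stopifnot(inherits(cfg, "null_config"))
  R_nm <- cfg$sphere_radius_um * 1000
  withr::with_seed(cfg$seed, {
    per_iter <- lapply(seq_len(cfg$n_iter), function(it) {
      q <- runif_ball(cfg$n_query, R_nm)
      t <- runif_ball(cfg$n_target, R_nm)
      tibble::tibble(iteration = it,
                     distance_nm = nearest_distances(q, t)$distance_nm)
    })
  })
  distances <- dplyr::bind_rows(per_iter)
  medians <- distances |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(median_nm = stats::median(.data$distance_nm),
                     .groups = "drop")
  structure(list(distances = distances, medians = medians, config = cfg),
            class = "nf_null")
}

#' @export
print.nf_null <- function(x, ...) {
  cat(sprintf(
    "<nf_null> %d iterations, %d query x %d target in R = %g um\n",
    x$config$n_iter, x$config$n_query, x$config$n_target,
    x$config$sphere_radius_um))
  cat(sprintf("pooled median nearest distance: %.1f nm\n",
              stats::median(x$distances$distance_nm)))
  invisible(x)
}

#' Compare observed nearest distances against a simulated null
#'
#' Reports quantiles of both distributions and the direction of the
#' effect (observed median below or above the null median); no p-value
#' is claimed.
#'
#' @param observed_nm Numeric vector of observed nearest distances (nm).
#' @param null A [simulate_null()] result.
#' @param probs Quantiles to report.
#' @return A tibble `quantile`, `observed_nm`, `null_nm` with an
#'   attribute `direction` (`"below"`, `"above"` or `"equal"`).
#' @export
compare_to_null <- function(observed_nm, null,
                            probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(null, "nf_null"))
  out <- tibble::tibble(
    quantile = probs,
    observed_nm = stats::quantile(observed_nm, probs, type = 7, names = FALSE),
    null_nm = stats::quantile(null$distances$distance_nm, probs, type = 7,
                              names = FALSE)
  )
  om <- stats::median(observed_nm)
  nm <- stats::median(null$distances$distance_nm)
  attr(out, "direction") <- if (om < nm) "below" else if (om > nm) "above" else "equal"
  out
}

#' Per-structure ratio via regression through the origin
#'
#' Given paired per-nucleus counts of two object classes, fits the
#' least-squares slope of `b` on `a` both through the origin and with an
#' intercept (both reported; the through-origin slope is the per-
#' structure ratio).
#'
#' @param counts Tibble with columns `a` and `b`, one row per nucleus.
#' @return An object of class `nf_ratio`; see [tidy.nf_ratio()].
#' @export
ratio_per_structure <- function(counts) {
  stopifnot(all(c("a", "b") %in% names(counts)))
  if (nrow(counts) < 2L) stop("at least two nuclei are required", call. = FALSE)
  fit0 <- stats::lm(b ~ 0 + a, data = counts)
  fit1 <- stats::lm(b ~ a, data = counts)
  degenerate <- stats::var(counts$a) == 0
  structure(list(through_origin = fit0, with_intercept = fit1,
                 degenerate = degenerate, n = nrow(counts)),
            class = "nf_ratio")
}

#' @export
print.nf_ratio <- function(x, ...) {
  cat(sprintf("<nf_ratio> slope through origin: %.3f (n = %d)%s\n",
              stats::coef(x$through_origin)[["a"]], x$n,
              if (x$degenerate) " [degenerate: constant predictor]" else ""))
  invisible(x)
}
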