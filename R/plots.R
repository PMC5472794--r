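#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed vs null nearest-distance distributions
#'
#' Empirical CDFs of the pooled null distances, optionally overlaid
#' with observed distances.
#'
#' @param object A [simulate_null()] result.
#' @param observed_nm Optional observed nearest distances (nm).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nf_null <- function(object, observed_nm = NULL, ...) {
  df <- dplyr::mutate(object$distances, set = "null")
  if (!is.null(observed_nm)) {
    df <- dplyr::bind_rows(df, tibble::tibble(iteration = NA_integer_,
                                              distance_nm = observed_nm,
                                              set = "observed"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_nm,
                                   colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "nearest-neighbour distance (nm)",
                  y = "empirical CDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Peak occupancy around domain boundaries
#'
#' @param object A [ctcf_boundary_analysis()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of summed peak score per offset bin
#'   (negative offsets outside the domain, positive inside).
#' @export
autoplot.nf_ctcf <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset_bin, y = .data$summed_score)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "offset from domain boundary (kb)",
                  y = "summed peak score") +
    ggplot2::theme_minimal()
}

#' Track signal with called domains
#'
#' @param track Binned-track tibble.
#' @param domains A [call_domains()] tibble.
#' @param chrom Optional chromosome to restrict the panel to.
#' @return A ggplot of the bin values with domain extents shaded.
#' @export
plot_track_domains <- function(track, domains, chrom = NULL) {
  if (!is.null(chrom)) {
    track <- dplyr::filter(track, .data$chrom == !!chrom)
    domains <- dplyr::filter(domains, .data$chrom == !!chrom)
  }
  p <- ggplot2::ggplot(track) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "signal") +
    ggplot2::theme_minimal()
  if (nrow(domains) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2
    )
  }
  p
}

#' Cluster metric distributions
#'
#' @param clusters A [cluster_metrics()] tibble.
#' @return A faceted ggplot of the per-cluster metric distributions.
#' @export
plot_cluster_metrics <- function(clusters) {
  long <- clusters |>
    dplyr::select("cluster", "n_foci", "integrated_volume_um3",
                  "interfocal_volume_um3", "shortest_path_nm",
                  "mean_intercentroid_nm") |>
    tidyr::pivot_longer(-"cluster", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal()
}

#' Cluster count as a function of the linkage cutoff
#'
#' @param scan A [cutoff_scan()] tibble.
#' @return A ggplot line chart.
#' @export
plot_cutoff_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$cutoff_nm,
                                     y = .data$n_clusters)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "linkage cutoff (nm)", y = "clusters") +
    ggplot2::theme_minimal()
}
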