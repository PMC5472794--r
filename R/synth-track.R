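#' Ground truth for a synthetic binned ChIP-Seq track
#'
#' Describes planted enriched domains on a single reference sequence:
#' bins falling inside a domain draw counts at `enrichment_rate`, all
#' other bins at `background_rate` (Poisson noise).
#'
#' @param domain_intervals Tibble/data frame with `chrom`, `start`, `end`
#'   (bp, 0-based half-open); intervals must be disjoint and sorted.
#' @param background_rate,enrichment_rate Expected reads per bin outside
#'   and inside domains; `enrichment_rate` must be >= `background_rate`.
#' @param boundary_peak_offsets Offsets (bp) of flanking peak features
#'   from domain boundaries, recycled over boundaries; positive values
#'   place peaks outside the domain.
#' @param seed Integer seed.
#' @return An object of class `track_truth`.
#' @export
track_truth <- function(domain_intervals,
                        background_rate = 5,
                        enrichment_rate = 50,
                        boundary_peak_offsets = 0,
                        seed = 1L) {
  di <- tibble::as_tibble(domain_intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(di)))
  di <- dplyr::arrange(di, .data$chrom, .data$start)
  if (any(di$end <= di$start)) stop("domain intervals must have end > start", call. = FALSE)
  overlap <- di |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (any(overlap$start < overlap$prev_end, na.rm = TRUE)) {
    stop("domain intervals must be non-overlapping", call. = FALSE)
  }
  if (enrichment_rate < background_rate) {
    stop("`enrichment_rate` must be >= `background_rate`", call. = FALSE)
  }
  structure(list(
    domain_intervals = di,
    background_rate = background_rate,
    enrichment_rate = enrichment_rate,
    boundary_peak_offsets = boundary_peak_offsets,
    seed = as.integer(seed)
  ), class = "track_truth")
}

#' Simulate a binned coverage track with planted domains
#'
#' Bin counts are Poisson with mean `enrichment_rate` for bins entirely
#' inside a planted domain and `background_rate` elsewhere. Domain
#' boundaries must align to the bin grid.
#'
#' @param genome_length Length of the (single) reference sequence in bp.
#' @param bin_size Bin width in bp (default 10 kb).
#' @param truth A [track_truth()].
#' @return A binned-track tibble with columns `chrom`, `start`, `end`,
#'   `value` and an additional logical column `in_domain` carrying the
#'   bin-level truth labels; `bin_size` is stored as an attribute.
#' @export
make_chipseq_track <- function(genome_length, bin_size = 10000L, truth) {
  stopifnot(inherits(truth, "track_truth"))
  di <- truth$domain_intervals
  if (length(unique(di$chrom)) > 1L) {
    stop("make_chipseq_track() simulates a single reference sequence", call. = FALSE)
  }
  chrom <- if (nrow(di)) di$chrom[1] else "chr1"
  if (nrow(di) && any(di$end > genome_length)) {
    stop("planted domains extend past `genome_length`", call. = FALSE)
  }
  if (nrow(di) && any(di$start %% bin_size != 0 | di$end %% bin_size != 0)) {
    stop("planted domain boundaries must align to the bin grid", call. = FALSE)
  }
  n_bins <- genome_length %/% bin_size
  start <- (seq_len(n_bins) - 1L) * bin_size
  in_domain <- rep(FALSE, n_bins)
  for (i in seq_len(nrow(di))) {
    in_domain[(di$start[i] %/% bin_size + 1L):(di$end[i] %/% bin_size)] <- TRUE
  }
  value <- withr::with_seed(truth$seed, {
    stats::rpois(n_bins, ifelse(in_domain, truth$enrichment_rate,
                                truth$background_rate))
  })
  out <- tibble::tibble(
    chrom = chrom, start = start, end = start + bin_size,
    value = as.numeric(value), in_domain = in_domain
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

#' Plant peak features flanking the truth domain boundaries
#'
#' Emits one BED6-style peak per domain boundary, centred at the boundary
#' displaced outward by `boundary_peak_offsets` plus uniform jitter. A
#' configurable fraction of peaks receives the maximum score, emulating
#' saturated-occupancy footprints.
#'
#' @param truth A [track_truth()].
#' @param jitter_bp Uniform jitter half-width (bp) added to each offset.
#' @param score_range `c(min, max)` score bounds.
#' @param max_score_fraction Fraction of peaks assigned exactly the
#'   maximum score.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed (defaults to the truth seed).
#' @return A tibble with BED6 columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, plus truth columns `boundary_pos`, `side` and
#'   `is_max`.
#' @export
make_ctcf_peaks <- function(truth, jitter_bp = 0,
                            score_range = c(100, 1000),
                            max_score_fraction = 0.3,
                            peak_width = 200L,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "track_truth"))
  di <- truth$domain_intervals
  if (nrow(di) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character(),
                          boundary_pos = integer(), side = character(),
                          is_max = logical()))
  }
  boundaries <- tibble::tibble(
    chrom = rep(di$chrom, 2L),
    pos = c(di$start, di$end),
    side = rep(c("left", "right"), each = nrow(di))
  )
  offs <- rep_len(truth$boundary_peak_offsets, nrow(boundaries))
  withr::with_seed(as.integer(seed), {
    jit <- if (jitter_bp > 0) {
      round(stats::runif(nrow(boundaries), -jitter_bp, jitter_bp))
    } else rep(0L, nrow(boundaries))
    # outward displacement: left boundary -> upstream, right -> downstream
    centre <- ifelse(boundaries$side == "left",
                     boundaries$pos - offs, boundaries$pos + offs) + jit
    score <- stats::runif(nrow(boundaries), score_range[1], score_range[2])
    is_max <- stats::runif(nrow(boundaries)) < max_score_fraction
    score[is_max] <- score_range[2]
    out <- tibble::tibble(
      chrom = boundaries$chrom,
      start = as.integer(centre - peak_width %/% 2L),
      end = as.integer(centre + peak_width %/% 2L),
      name = sprintf("peak_%d", seq_len(nrow(boundaries))),
      score = score,
      strand = ".",
      boundary_pos = as.integer(boundaries$pos),
      side = boundaries$side,
      is_max = is_max
    )
    dplyr::arrange(out, .data$chrom, .data$start)
  })
}
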