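#' Bin mapped reads into fixed-width RPKM bins
#'
#' Reads are assigned to non-overlapping bins by their midpoint and
#' converted to RPKM: `count / (bin_kb * total_reads / 1e6)`.
#'
#' @param reads Tibble with `chrom`, `start`, `end` (bp, 0-based
#'   half-open), one row per mapped read.
#' @param chrom_sizes Tibble with `chrom`, `size` (bp) or a named
#'   numeric vector.
#' @param bin_size Bin width in bp (default 10 kb).
#' @return A binned-track tibble `chrom`, `start`, `end`, `value`
#'   covering every chromosome completely; attribute `bin_size` and
#'   `normalization = "rpkm"`.
#' @export
bin_rpkm <- function(reads, chrom_sizes, bin_size = 10000L) {
  cs <- as_chrom_sizes(chrom_sizes)
  total <- nrow(reads)
  if (total == 0L) stop("zero mapped reads", call. = FALSE)
  bins <- cs |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = .data$chrom,
                   start = seq(0L, .data$size - 1L, by = bin_size)) |>
    dplyr::mutate(end = pmin(.data$start + bin_size, cs$size[match(.data$chrom, cs$chrom)]))
  mid <- (reads$start + reads$end) %/% 2L
  key <- paste(reads$chrom, mid %/% bin_size)
  cnt <- table(key)
  bins$count <- as.integer(cnt[paste(bins$chrom, bins$start %/% bin_size)])
  bins$count[is.na(bins$count)] <- 0L
  bins$value <- bins$count / (((bins$end - bins$start) / 1000) * (total / 1e6))
  out <- tibble::as_tibble(bins[, c("chrom", "start", "end", "value")])
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "normalization") <- "rpkm"
  out
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    return(tibble::tibble(chrom = names(chrom_sizes),
                          size = as.integer(chrom_sizes)))
  }
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  tibble::as_tibble(chrom_sizes)
}

#' Moving-average smoothing of a binned track
#'
#' Centred moving average of `w` bins within each chromosome; edge bins
#' use truncated windows. For even `w` the window is left-heavy
#' (`floor((w-1)/2)` bins before, the remainder after).
#'
#' @param track Binned-track tibble.
#' @param w Window width in bins, 1 (identity) to 25.
#' @return The smoothed track; attribute `normalization` gains a
#'   `"smoothed"` tag.
#' @export
smooth_track <- function(track, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w > 25 || w != round(w)) {
    stop("`w` must be a whole number in 1..25", call. = FALSE)
  }
  w <- as.integer(w)
  if (w == 1L) return(track)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  out <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(value = ma_truncated(.data$value, left, right)) |>
    dplyr::ungroup()
  attr(out, "bin_size") <- attr(track, "bin_size")
  attr(out, "normalization") <- c(attr(track, "normalization"),
                                  sprintf("smoothed_w%d", w))
  out
}

ma_truncated <- function(x, left, right) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalize a track to its genome-wide mean
#'
#' @param track Binned-track tibble.
#' @return The track divided by the mean of all bin values (genome-wide
#'   mean becomes 1).
#' @export
normalize_to_genome_mean <- function(track) {
  m <- mean(track$value)
  if (!is.finite(m) || m == 0) {
    stop("genome-wide mean is zero or undefined; cannot normalize", call. = FALSE)
  }
  out <- dplyr::mutate(track, value = .data$value / m)
  attr(out, "bin_size") <- attr(track, "bin_size")
  attr(out, "normalization") <- c(attr(track, "normalization"), "genome_mean")
  out
}

#' Spearman correlation of a signal track against feature tracks
#'
#' Bins are matched on `chrom`/`start`/`end`; per feature, Spearman's
#' rho with average ranks for ties, excluding bins with missing feature
#' values pairwise. With `drop_zero = TRUE` bins where the signal track
#' is zero are excluded first (for unmappable/zero-coverage bins).
#'
#' @param track The signal (e.g. gamma-H2AX) binned track.
#' @param features Named list of binned-track tibbles on the same grid.
#' @param drop_zero Exclude bins with zero signal value.
#' @return A tibble `feature`, `rho`, `n_bins`.
#' @export
correlate_features <- function(track, features, drop_zero = FALSE) {
  stopifnot(is.list(features), !is.null(names(features)))
  base <- track
  if (drop_zero) base <- dplyr::filter(base, .data$value != 0)
  rows <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    j <- dplyr::inner_join(
      dplyr::select(base, "chrom", "start", "end", gamma = "value"),
      dplyr::select(f, "chrom", "start", "end", feature = "value"),
      by = c("chrom", "start", "end")
    )
    j <- dplyr::filter(j, !is.na(.data$feature), !is.na(.data$gamma))
    if (nrow(j) < 3L) {
      stop(sprintf("fewer than 3 shared bins with feature '%s'", nm),
           call. = FALSE)
    }
    tibble::tibble(
      feature = nm,
      rho = stats::cor(j$gamma, j$feature, method = "spearman"),
      n_bins = nrow(j)
    )
  })
  dplyr::bind_rows(rows)
}

#' Retain the top bins matching an imaging volume fraction
#'
#' Keeps the bins whose value is at or above the `(100 -
#' volume_fraction_pct)`-th percentile of the track's value distribution
#' (linear-interpolation percentile). A volume fraction of 7.81% keeps
#' the top bins above the 92.19th percentile. Ties at the threshold are
#' all retained.
#'
#' @param track Binned-track tibble.
#' @param volume_fraction_pct Percent of the nuclear volume occupied by
#'   foci, in (0, 100).
#' @return The track with a logical `retained` column; attributes
#'   `threshold` and `percentile` record the cut.
#' @export
percentile_filter <- function(track, volume_fraction_pct) {
  if (!(volume_fraction_pct > 0 && volume_fraction_pct < 100)) {
    stop("`volume_fraction_pct` must be in (0, 100)", call. = FALSE)
  }
  pct <- 100 - volume_fraction_pct
  thr <- stats::quantile(track$value, pct / 100, type = 7, names = FALSE)
  out <- dplyr::mutate(track, retained = .data$value >= thr)
  attr(out, "bin_size") <- attr(track, "bin_size")
  attr(out, "threshold") <- thr
  attr(out, "percentile") <- pct
  out
}

#' Merge retained bins into 1D domains
#'
#' Maximal runs of consecutive retained bins (no gap tolerance) become
#' domains; consecutive means physically adjacent bins of the same
#' chromosome.
#'
#' @param track A [percentile_filter()] result (or any binned track with
#'   a logical `retained` column).
#' @return A tibble `chrom`, `start`, `end`, `n_bins`, `mean_signal`,
#'   sorted; attribute `linear_coverage_bp` holds the summed length.
#' @export
call_domains <- function(track) {
  stopifnot("retained" %in% names(track))
  kept <- track |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::filter(.data$retained)
  if (nrow(kept) == 0L) {
    out <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_bins = integer(0),
                          mean_signal = numeric(0))
    attr(out, "linear_coverage_bp") <- 0
    return(out)
  }
  kept <- kept |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(new_run = dplyr::row_number() == 1L |
                    .data$start != dplyr::lag(.data$end)) |>
    dplyr::ungroup() |>
    dplyr::mutate(run = cumsum(.data$new_run))
  out <- kept |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = .data$chrom[1],
                     start = min(.data$start),
                     end = max(.data$end),
                     n_bins = dplyr::n(),
                     mean_signal = mean(.data$value),
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
  attr(out, "linear_coverage_bp") <- sum(out$end - out$start)
  out
}

#' Linear coverage of a domain set
#'
#' @param domains A [call_domains()] tibble.
#' @return Total domain length in bp.
#' @export
domain_coverage <- function(domains) {
  sum(domains$end - domains$start)
}

#' Choose the smoothing factor matching the 3D nano-focus count
#'
#' The per-nucleus 3D nano-focus count is scaled to the haploid genome
#' (`target = n_nanofoci / ploidy_factor`); for every smoothing window
#' `w`, the track is smoothed, percentile-filtered at the imaging volume
#' fraction and segmented into domains, and the `w` whose domain count
#' is closest to the target is chosen (ties towards the smaller `w`).
#'
#' @param track Binned-track tibble (raw; smoothing is applied inside).
#' @param volume_fraction_pct Imaging volume fraction in percent.
#' @param n_nanofoci Observed 3D nano-focus count.
#' @param ploidy_factor Genome / haploid size ratio (default 3.12).
#' @param w_range Candidate windows (default 1..25).
#' @return An object of class `nf_match`: `chosen_w`, `target`,
#'   `scan` tibble (`w`, `n_domains`, `abs_diff`), and `domains` for the
#'   chosen `w`; see [glance.nf_match()].
#' @export
match_smoothing <- function(track, volume_fraction_pct, n_nanofoci,
                            ploidy_factor = 3.12, w_range = 1:25) {
  stopifnot(n_nanofoci > 0)
  target <- n_nanofoci / ploidy_factor
  scan <- lapply(w_range, function(w) {
    dom <- call_domains(percentile_filter(smooth_track(track, w),
                                          volume_fraction_pct))
    tibble::tibble(w = w, n_domains = nrow(dom),
                   abs_diff = abs(nrow(dom) - target))
  })
  scan <- dplyr::bind_rows(scan)
  chosen <- scan$w[which.min(scan$abs_diff)]  # which.min takes first = smaller w
  domains <- call_domains(percentile_filter(smooth_track(track, chosen),
                                            volume_fraction_pct))
  structure(list(chosen_w = chosen, target = target, scan = scan,
                 domains = domains),
            class = "nf_match")
}

#' @export
print.nf_match <- function(x, ...) {
  cat(sprintf("<nf_match> chosen w = %d (target %.1f domains, got %d)\n",
              x$chosen_w, x$target, nrow(x$domains)))
  invisible(x)
}

#' Distances and occupancy of peaks around domain boundaries
#'
#' For every domain boundary the distance to the nearest peak (peak
#' position = interval midpoint) is measured; in addition, peak scores
#' are summed in bins of `bin_bp` from `span_bp` outside the boundary to
#' `bin_bp` inside it (default: -300..-200, -200..-100, -100..0 kb
#' outside and 0..+100 kb inside). With `max_score_only = TRUE` only
#' peaks carrying the file's maximum score are considered.
#'
#' @param domains A [call_domains()] tibble.
#' @param peaks BED6-like tibble with `chrom`, `start`, `end`, `score`.
#' @param bin_bp Occupancy bin width (default 100 kb).
#' @param span_bp Outside span (default 300 kb).
#' @param max_score_only Restrict to maximum-score peaks.
#' @return An object of class `nf_ctcf`: `boundaries` tibble (`chrom`,
#'   `boundary_pos`, `side`, `distance_bp`, `missing`), `profile` tibble
#'   (`offset_bin`, `summed_score`), and the peak filter used.
#' @export
ctcf_boundary_analysis <- function(domains, peaks, bin_bp = 100000L,
                                   span_bp = 300000L,
                                   max_score_only = FALSE) {
  pk <- peaks
  if (max_score_only) pk <- dplyr::filter(pk, .data$score == max(.data$score))
  pk_pos <- (pk$start + pk$end) %/% 2L
  boundaries <- tibble::tibble(
    chrom = rep(domains$chrom, 2L),
    boundary_pos = c(domains$start, domains$end),
    side = rep(c("left", "right"), each = nrow(domains))
  )
  dist_missing <- mapply(function(ch, pos) {
    sel <- pk$chrom == ch
    if (!any(sel)) return(c(NA_real_, TRUE))
    c(min(abs(pk_pos[sel] - pos)), FALSE)
  }, boundaries$chrom, boundaries$boundary_pos)
  boundaries$distance_bp <- unname(dist_missing[1, ])
  boundaries$missing <- as.logical(unname(dist_missing[2, ]))

  # signed offset relative to the boundary: negative = outside the
  # domain, positive = inside (direction flips at right boundaries)
  breaks <- seq(-span_bp, bin_bp, by = bin_bp)
  labels <- sprintf("%d..%d", utils::head(breaks, -1L) %/% 1000L,
                    breaks[-1L] %/% 1000L)
  sums <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_len(nrow(boundaries))) {
    sel <- pk$chrom == boundaries$chrom[i]
    if (!any(sel)) next
    off <- pk_pos[sel] - boundaries$boundary_pos[i]
    if (boundaries$side[i] == "right") off <- -off
    bin <- cut(off, breaks = breaks, labels = labels, right = FALSE)
    add <- tapply(pk$score[sel], bin, sum)
    add[is.na(add)] <- 0
    sums <- sums + add[labels]
  }
  profile <- tibble::tibble(offset_bin = factor(labels, levels = labels),
                            summed_score = unname(sums))
  structure(list(boundaries = boundaries, profile = profile,
                 max_score_only = max_score_only,
                 bin_bp = bin_bp, span_bp = span_bp),
            class = "nf_ctcf")
}

#' @export
print.nf_ctcf <- function(x, ...) {
  ok <- !x$boundaries$missing
  cat(sprintf("<nf_ctcf> %d boundaries, median distance %.0f bp%s\n",
              nrow(x$boundaries),
              stats::median(x$boundaries$distance_bp[ok]),
              if (x$max_score_only) " (max-score peaks only)" else ""))
  invisible(x)
}

#' Expected DSB count from a per-Gy yield
#'
#' `bound = yield * dose * ploidy_factor / 2`, rounded to the nearest
#' 10: a diploid-genome yield is scaled to the ploidy-adjusted genome.
#' With the 30-55 DSB/Gy diploid yield, 10 Gy and ploidy factor 3.12
#' this gives 470-860 DSBs.
#'
#' @param yield_low,yield_high DSBs per Gy per diploid genome.
#' @param dose_gy Dose in Gy.
#' @param ploidy_factor Genome / haploid size ratio (3.12; use 2 for a
#'   diploid genome, i.e. no scaling).
#' @return A tibble with `low` and `high` expected DSB counts.
#' @export
expected_dsb_count <- function(yield_low = 30, yield_high = 55,
                               dose_gy = 10, ploidy_factor = 3.12) {
  stopifnot(yield_low > 0, yield_high >= yield_low, dose_gy > 0,
            ploidy_factor > 0)
  b <- c(yield_low, yield_high) * dose_gy * ploidy_factor / 2
  b <- round(b / 10) * 10
  tibble::tibble(low = b[1], high = b[2])
}
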