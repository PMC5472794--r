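#' Configuration for DAPI-based DNA content estimation
#'
#' @param genome_size_mbp Total genome size in Mbp (for HeLa this is the
#'   karyotype-derived value; no default is asserted).
#' @param ploidy_factor Genome / haploid-reference size ratio (3.12 for
#'   HeLa); carried for downstream per-cell vs genomic comparisons.
#' @param cell_cycle_factor Per-nucleus multiplier correcting for cell
#'   cycle stage, defined as nuclear integrated DAPI over a G1 reference
#'   DAPI value (1 = no correction).
#' @param trim_low,trim_high Percentile bounds (default 0.5 and 99.5);
#'   pooled content values outside these percentiles are flagged as
#'   discarded.
#' @return A list of class `dna_content_config`.
#' @export
dna_content_config <- function(genome_size_mbp, ploidy_factor = 3.12,
                               cell_cycle_factor = 1,
                               trim_low = 0.5, trim_high = 99.5) {
  stopifnot(genome_size_mbp > 0, ploidy_factor > 0, cell_cycle_factor > 0,
            trim_low < trim_high, trim_low >= 0, trim_high <= 100)
  structure(list(genome_size_mbp = genome_size_mbp,
                 ploidy_factor = ploidy_factor,
                 cell_cycle_factor = cell_cycle_factor,
                 trim_low = trim_low, trim_high = trim_high),
            class = "dna_content_config")
}

#' Estimate per-focus DNA content from DAPI intensity
#'
#' The DNA content of a focus is its share of the integrated nuclear
#' DAPI intensity scaled to the genome size:
#' `content_kb = (focus DAPI / nuclear DAPI) * genome_size_mbp * 1000 /
#' cell_cycle_factor`. Values outside the `[trim_low, trim_high]`
#' percentiles of the pooled distribution (linear-interpolation
#' percentiles, `stats::quantile()` type 7) are flagged as discarded in
#' the `dna_retained` column.
#'
#' @param foci A [foci_table()] tibble.
#' @param nucleus A [segment_nucleus()] result (its `integrated_dapi` is
#'   the denominator).
#' @param cfg A [dna_content_config()].
#' @param dapi_channel Name of the DAPI channel.
#' @return The input tibble with `dna_content_kb` and `dna_retained`
#'   columns appended.
#' @export
estimate_dna_content <- function(foci, nucleus, cfg, dapi_channel = "dapi") {
  stopifnot(inherits(cfg, "dna_content_config"),
            inherits(nucleus, "nucleus_mask"))
  col <- paste0("integrated_", dapi_channel)
  if (!col %in% names(foci)) {
    stop(sprintf("column '%s' missing from the focus table", col), call. = FALSE)
  }
  if (!is.finite(nucleus$integrated_dapi) || nucleus$integrated_dapi <= 0) {
    stop("nuclear integrated DAPI is zero; cannot normalize", call. = FALSE)
  }
  content <- foci[[col]] / nucleus$integrated_dapi *
    cfg$genome_size_mbp * 1000 / cfg$cell_cycle_factor
  out <- dplyr::mutate(foci, dna_content_kb = content)
  if (nrow(out) > 0L) {
    lo <- stats::quantile(content, cfg$trim_low / 100, type = 7, names = FALSE)
    hi <- stats::quantile(content, cfg$trim_high / 100, type = 7, names = FALSE)
    out$dna_retained <- content >= lo & content <= hi
  } else {
    out$dna_retained <- logical(0)
  }
  out
}

#' Percent of nuclear volume occupied by foci
#'
#' @param foci A [foci_table()] tibble (its `volume_um3` column is
#'   summed).
#' @param nucleus A [segment_nucleus()] result.
#' @return Percentage, `100 * sum(focus volumes) / nucleus volume`.
#' @export
volume_fraction <- function(foci, nucleus) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (nrow(foci) == 0L) return(0)
  100 * sum(foci$volume_um3) / nucleus$volume_um3
}

#' Build hollow shells around every focus
#'
#' Each focus is dilated by `dilation_voxels` along every axis (per-axis
#' Chebyshev box, so the default 3 voxels at 39/125 nm spans 117 nm
#' laterally and 375 nm axially), the focus voxels themselves are
#' subtracted, the result is clipped to the nucleus, and voxels claimed
#' by the shells of several foci are assigned to the focus with the
#' nearest centroid.
#'
#' @param labels A `focus_labels` array.
#' @param dilation_voxels Dilation in voxels along every axis (default 3).
#' @param nucleus Optional [segment_nucleus()] result used for clipping.
#' @return An integer shell label array (class `focus_labels`) aligned
#'   with `labels`.
#' @export
make_shells <- function(labels, dilation_voxels = 3L, nucleus = NULL) {
  stopifnot(inherits(labels, "focus_labels"))
  dm <- dim(labels)
  sz_nm <- attr(labels, "voxel_size_nm")
  sz <- c(sz_nm[1], sz_nm[1], sz_nm[2])
  d <- as.integer(dilation_voxels)
  n <- max(labels)
  shells <- array(0L, dm)
  if (n == 0L) {
    return(structure(shells, voxel_size_nm = sz_nm,
                     channel = attr(labels, "channel"),
                     dilation_voxels = d, class = "focus_labels"))
  }
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, dm)
  l <- labels[idx]
  pos <- vx_centre_nm(coords, sz_nm)
  cen <- rowsum(pos, l) / tabulate(l, nbins = n)

  offs <- as.matrix(expand.grid(dx = -d:d, dy = -d:d, dz = -d:d))
  cand_vox <- coords[rep(seq_len(nrow(coords)), each = nrow(offs)), , drop = FALSE] +
    offs[rep(seq_len(nrow(offs)), times = nrow(coords)), , drop = FALSE]
  cand_lab <- rep(l, each = nrow(offs))
  ok <- cand_vox[, 1] >= 1L & cand_vox[, 1] <= dm[1] &
    cand_vox[, 2] >= 1L & cand_vox[, 2] <= dm[2] &
    cand_vox[, 3] >= 1L & cand_vox[, 3] <= dm[3]
  cand_vox <- cand_vox[ok, , drop = FALSE]
  cand_lab <- cand_lab[ok]
  lin <- cand_vox[, 1] + dm[1] * (cand_vox[, 2] - 1L) +
    dm[1] * dm[2] * (cand_vox[, 3] - 1L)
  pair <- !duplicated(lin * (n + 1) + cand_lab)
  lin <- lin[pair]; cand_vox <- cand_vox[pair, , drop = FALSE]
  cand_lab <- cand_lab[pair]
  drop <- labels[lin] > 0L
  if (!is.null(nucleus)) drop <- drop | !nucleus$mask[lin]
  lin <- lin[!drop]; cand_vox <- cand_vox[!drop, , drop = FALSE]
  cand_lab <- cand_lab[!drop]
  if (length(lin) > 0L) {
    cpos <- vx_centre_nm(cand_vox, sz_nm)
    dist <- sqrt(rowSums((cpos - cen[cand_lab, , drop = FALSE])^2))
    ord <- order(lin, dist)
    first <- !duplicated(lin[ord])
    shells[lin[ord][first]] <- cand_lab[ord][first]
  }
  structure(shells, voxel_size_nm = sz_nm, channel = attr(labels, "channel"),
            dilation_voxels = d, class = "focus_labels")
}

#' Focus vs shell intensity statistics
#'
#' For every focus, the maximum and mean intensity of the requested
#' channels inside the focus voxels and inside its shell. Foci whose
#' shell was fully clipped away get `NA` statistics and are flagged via
#' `shell_missing`. With `normalize = "nucleus_max"` all statistics are
#' divided by the maximum intensity of the channel inside the nucleus.
#'
#' @param stack An [image_stack()].
#' @param channels Channels to measure (default: all).
#' @param labels Focus label array.
#' @param shells Matching [make_shells()] array.
#' @param normalize `"none"` or `"nucleus_max"`.
#' @param nucleus Required for `normalize = "nucleus_max"`.
#' @return A tibble with one row per focus: `focus_id`, `shell_missing`,
#'   then `focus_max_*`, `focus_mean_*`, `shell_max_*`, `shell_mean_*`
#'   per channel.
#' @export
shell_stats <- function(stack, channels = NULL, labels, shells,
                        normalize = c("none", "nucleus_max"),
                        nucleus = NULL) {
  normalize <- match.arg(normalize)
  if (is.null(channels)) channels <- channel_names(stack)
  n <- max(labels)
  out <- tibble::tibble(focus_id = seq_len(n))
  f_idx <- which(labels > 0L)
  s_idx <- which(shells > 0L)
  f_l <- labels[f_idx]
  s_l <- shells[s_idx]
  out$shell_missing <- !(out$focus_id %in% s_l)
  grp_stat <- function(v, g, n, fun) {
    res <- rep(NA_real_, n)
    if (length(v)) {
      agg <- vapply(split(v, g), fun, numeric(1))
      res[as.integer(names(agg))] <- agg
    }
    res
  }
  for (ch in channels) {
    a <- get_channel(stack, ch)
    scale <- 1
    if (normalize == "nucleus_max") {
      if (is.null(nucleus)) {
        stop("`nucleus` is required for normalize = 'nucleus_max'", call. = FALSE)
      }
      scale <- max(a[nucleus$mask])
    }
    fv <- a[f_idx]; sv <- a[s_idx]
    out[[paste0("focus_max_", ch)]] <- grp_stat(fv, f_l, n, max) / scale
    out[[paste0("focus_mean_", ch)]] <- grp_stat(fv, f_l, n, mean) / scale
    out[[paste0("shell_max_", ch)]] <- grp_stat(sv, s_l, n, max) / scale
    out[[paste0("shell_mean_", ch)]] <- grp_stat(sv, s_l, n, mean) / scale
  }
  out
}
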