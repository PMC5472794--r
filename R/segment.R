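#' Segment the nucleus from the DAPI channel
#'
#' Thresholds the DAPI channel, keeps 26-connected components of at
#' least `min_volume_um3`, fills internal cavities, then applies
#' `morph_iterations` rounds of dilation followed by closing with a
#' 3x3x3 box element to absorb DAPI-weak volumes, and returns the
#' largest surviving component.
#'
#' @param stack An [image_stack()].
#' @param dapi_channel Name of the DAPI channel.
#' @param threshold Intensity threshold (counts, 16-bit scale).
#' @param min_volume_um3 Minimum nucleus volume (default 200 um^3).
#' @param morph_iterations Rounds of dilate + close (default 2).
#' @return An object of class `nucleus_mask`: logical `mask` array,
#'   `volume_um3`, `integrated_dapi` and the voxel sizes.
#' @export
segment_nucleus <- function(stack, dapi_channel = "dapi", threshold,
                            min_volume_um3 = 200, morph_iterations = 2L) {
  a <- get_channel(stack, dapi_channel)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("`threshold` must be a single finite number", call. = FALSE)
  }
  vox <- vx_volume_um3(stack$voxel_size_nm)
  lab <- vx_label(a >= threshold, 26L)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * vox >= min_volume_um3)
  if (length(keep) == 0L) {
    stop(sprintf("no nucleus: no connected component reaches %g um^3",
                 min_volume_um3), call. = FALSE)
  }
  mask <- array(lab %in% keep, dim(lab))
  mask <- vx_fill_holes(mask)
  for (i in seq_len(morph_iterations)) {
    mask <- vx_dilate_box(mask, c(1L, 1L, 1L))
    mask <- vx_close_box(mask, c(1L, 1L, 1L))
  }
  lab2 <- vx_label(mask, 26L)
  counts2 <- tabulate(lab2[lab2 > 0L])
  mask <- array(lab2 == which.max(counts2), dim(lab2))
  structure(list(
    mask = mask,
    volume_um3 = sum(mask) * vox,
    integrated_dapi = sum(a[mask]),
    voxel_size_nm = stack$voxel_size_nm
  ), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %.1f um^3, integrated DAPI %.4g\n",
              x$volume_um3, x$integrated_dapi))
  invisible(x)
}

#' Detect nano-foci in one channel
#'
#' Voxels at or above `intensity_threshold` are grouped into 26-connected
#' components; components smaller than `min_volume_um3` or whose
#' intensity-weighted centroid falls outside the nucleus mask are
#' discarded. Labels are renumbered consecutively.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to segment.
#' @param nucleus A [segment_nucleus()] result from the same stack.
#' @param intensity_threshold Lower intensity threshold (default 1000).
#' @param min_volume_um3 Minimum object volume (default 0.001 um^3).
#' @return An integer label array (class `focus_labels`) with attributes
#'   `voxel_size_nm` and `channel`.
#' @export
detect_foci <- function(stack, channel, nucleus,
                        intensity_threshold = 1000,
                        min_volume_um3 = 0.001) {
  a <- get_channel(stack, channel)
  stopifnot(inherits(nucleus, "nucleus_mask"))
  vox <- vx_volume_um3(stack$voxel_size_nm)
  lab <- vx_label(a >= intensity_threshold, 26L)
  n <- max(lab)
  if (n > 0L) {
    counts <- tabulate(lab[lab > 0L], nbins = n)
    keep <- counts * vox >= min_volume_um3
    if (any(keep)) {
      # centroid-inside-nucleus filter
      idx <- which(lab > 0L & array(keep[pmax(lab, 1L)], dim(lab)))
      coords <- arrayInd(idx, dim(lab))
      l <- lab[idx]
      w <- a[idx]
      for (k in which(keep)) {
        sel <- l == k
        cen <- colSums(coords[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
        cv <- pmin(pmax(round(cen), 1L), dim(lab))
        if (!nucleus$mask[cv[1], cv[2], cv[3]]) keep[k] <- FALSE
      }
    }
    remap <- integer(n)
    remap[keep] <- seq_len(sum(keep))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(lab, voxel_size_nm = stack$voxel_size_nm, channel = channel,
            class = "focus_labels")
}

#' Split merged foci with a marker-controlled watershed
#'
#' Components whose volume exceeds `2 * nominal_volume_um3` are split:
#' markers are intensity maxima within the component separated by at
#' least the equivalent-sphere diameter of `nominal_volume_um3`, and the
#' component's voxels are partitioned by an intensity-ordered seeded
#' watershed (ties resolved towards the nearest marker). Splitting is
#' best-effort: fragments below `min_volume_um3` are merged back into
#' the adjacent piece with the nearest marker.
#'
#' @param labels A [detect_foci()] label grid.
#' @param stack The originating [image_stack()] (intensity source).
#' @param nominal_volume_um3 Nominal single-object volume (default 0.05).
#' @param min_volume_um3 Minimum surviving object volume.
#' @return A relabelled `focus_labels` array.
#' @export
separate_touching <- function(labels, stack, nominal_volume_um3 = 0.05,
                              min_volume_um3 = 0.001) {
  stopifnot(inherits(labels, "focus_labels"))
  a <- get_channel(stack, attr(labels, "channel"))
  sz_nm <- attr(labels, "voxel_size_nm")
  sz <- c(sz_nm[1], sz_nm[1], sz_nm[2])
  vox <- vx_volume_um3(sz_nm)
  dm <- dim(labels)
  n <- max(labels)
  if (n == 0L) return(labels)
  counts <- tabulate(labels[labels > 0L], nbins = n)
  # equivalent-sphere diameter of the nominal volume, in nm
  sep_nm <- 2 * (3 * nominal_volume_um3 * 1e9 / (4 * pi))^(1 / 3)

  out <- array(as.integer(labels), dm)
  next_label <- n
  is_max <- array(a == vx_max_box(a, c(1L, 1L, 1L)), dm)
  for (k in seq_len(n)) {
    if (counts[k] * vox <= 2 * nominal_volume_um3) next
    idx <- which(out == k)
    coords <- arrayInd(idx, dm)
    vals <- a[idx]
    cand <- which(is_max[idx])
    if (length(cand) < 2L) next
    # greedy marker selection by decreasing intensity, min separation
    ord <- cand[order(-vals[cand], cand)]
    pos_nm <- sweep(coords - 0.5, 2, sz, "*")
    markers <- integer(0)
    for (m in ord) {
      if (length(markers) == 0L ||
          all(sqrt(rowSums(sweep(pos_nm[markers, , drop = FALSE], 2,
                                 pos_nm[m, ])^2)) >= sep_nm)) {
        markers <- c(markers, m)
      }
    }
    if (length(markers) < 2L) next
    piece <- vx_watershed_rows(coords, vals, markers, pos_nm)
    # merge undersized fragments into the piece with the nearest marker
    piece_counts <- tabulate(piece, nbins = length(markers))
    small <- which(piece_counts * vox < min_volume_um3)
    if (length(small) > 0L && length(small) < length(markers)) {
      ok <- setdiff(seq_along(markers), small)
      for (s in small) {
        d <- sqrt(rowSums(sweep(pos_nm[markers[ok], , drop = FALSE], 2,
                                pos_nm[markers[s], ])^2))
        piece[piece == s] <- ok[which.min(d)]
      }
      keep_pieces <- sort(unique(piece))
      piece <- match(piece, keep_pieces)
      markers <- markers[keep_pieces]
    }
    if (length(unique(piece)) < 2L) next
    new_ids <- c(k, next_label + seq_len(length(unique(piece)) - 1L))
    next_label <- next_label + length(unique(piece)) - 1L
    out[idx] <- new_ids[piece]
  }
  # renumber consecutively in first-voxel order
  fg <- out > 0L
  seen <- out[fg][!duplicated(out[fg])]
  remap <- integer(max(out))
  remap[seen] <- seq_along(seen)
  out[fg] <- remap[out[fg]]
  structure(out, voxel_size_nm = sz_nm, channel = attr(labels, "channel"),
            class = "focus_labels")
}

# Seeded watershed over one component's voxels: rows are processed in
# decreasing intensity; an unassigned row adjacent (26-neighbourhood) to
# an assigned one takes the label of the nearest marker among its
# assigned neighbours. Multiple passes handle plateaus.
vx_watershed_rows <- function(coords, vals, markers, pos_nm) {
  nr <- nrow(coords)
  key <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3])
  row_of <- seq_len(nr)
  names(row_of) <- key(coords)
  assign <- integer(nr)
  assign[markers] <- seq_along(markers)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  ord <- order(-vals, seq_len(nr))
  repeat {
    changed <- FALSE
    for (r in ord) {
      if (assign[r] > 0L) next
      nb <- sweep(offs, 2, as.numeric(coords[r, ]), "+")
      nbr <- row_of[paste(nb[, 1], nb[, 2], nb[, 3])]
      nbr <- nbr[!is.na(nbr)]
      lab_nb <- unique(assign[nbr])
      lab_nb <- lab_nb[lab_nb > 0L]
      if (length(lab_nb) == 1L) {
        assign[r] <- lab_nb
        changed <- TRUE
      } else if (length(lab_nb) > 1L) {
        d <- sqrt(rowSums(sweep(pos_nm[markers[lab_nb], , drop = FALSE], 2,
                                pos_nm[r, ])^2))
        assign[r] <- lab_nb[which.min(d)]
        changed <- TRUE
      }
    }
    if (!changed || all(assign > 0L)) break
  }
  # isolated plateau rows (no path to a marker): nearest marker
  left <- which(assign == 0L)
  for (r in left) {
    d <- sqrt(rowSums(sweep(pos_nm[markers, , drop = FALSE], 2, pos_nm[r, ])^2))
    assign[r] <- which.min(d)
  }
  assign
}

#' Measure all channels over a focus label grid
#'
#' One row per focus with voxel count, physical volume, the
#' intensity-weighted centroid in nm (weights from the segmentation
#' channel, honouring the anisotropic voxel sizes), and integrated,
#' maximum and mean intensity of every channel inside the focus voxels.
#'
#' @param labels A `focus_labels` array.
#' @param stack The originating [image_stack()].
#' @param nucleus Optional [segment_nucleus()] result (recorded columns
#'   are unaffected; kept for interface symmetry).
#' @return A tibble with columns `focus_id`, `channel`, `voxel_count`,
#'   `volume_um3`, `centroid_x_nm`, `centroid_y_nm`, `centroid_z_nm`,
#'   and `integrated_*`, `max_*`, `mean_*` per channel. Empty label
#'   grids give an empty tibble.
#' @export
foci_table <- function(labels, stack, nucleus = NULL) {
  stopifnot(inherits(labels, "focus_labels"))
  sz_nm <- attr(labels, "voxel_size_nm")
  seg_channel <- attr(labels, "channel")
  vox <- vx_volume_um3(sz_nm)
  n <- max(labels)
  chans <- channel_names(stack)
  base_cols <- tibble::tibble(
    focus_id = integer(0), channel = character(0), voxel_count = integer(0),
    volume_um3 = numeric(0), centroid_x_nm = numeric(0),
    centroid_y_nm = numeric(0), centroid_z_nm = numeric(0)
  )
  if (n == 0L) {
    for (ch in chans) {
      base_cols[[paste0("integrated_", ch)]] <- numeric(0)
      base_cols[[paste0("max_", ch)]] <- numeric(0)
      base_cols[[paste0("mean_", ch)]] <- numeric(0)
    }
    return(base_cols)
  }
  idx <- which(labels > 0L)
  l <- labels[idx]
  coords <- arrayInd(idx, dim(labels))
  w <- get_channel(stack, seg_channel)[idx]
  pos <- vx_centre_nm(coords, sz_nm)
  wsum <- unname(rowsum(w, l)[, 1])
  cen <- unname(rowsum(pos * w, l) / wsum)
  counts <- tabulate(l, nbins = n)
  out <- tibble::tibble(
    focus_id = seq_len(n),
    channel = seg_channel,
    voxel_count = counts,
    volume_um3 = counts * vox,
    centroid_x_nm = cen[, 1],
    centroid_y_nm = cen[, 2],
    centroid_z_nm = cen[, 3]
  )
  for (ch in chans) {
    v <- get_channel(stack, ch)[idx]
    out[[paste0("integrated_", ch)]] <- unname(rowsum(v, l)[, 1])
    out[[paste0("max_", ch)]] <- unname(vapply(split(v, l), max, numeric(1)))
    out[[paste0("mean_", ch)]] <- unname(rowsum(v, l)[, 1] / counts)
  }
  out
}
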