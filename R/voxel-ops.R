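# Internal 3D voxel-grid primitives. Arrays are indexed [x, y, z].
# All operations treat voxels outside the grid as background.

vx_shift <- function(a, d, fill = if (is.logical(a)) FALSE else 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- tgt <- vector("list", 3L)
  for (k in 1:3) {
    if (abs(d[k]) >= dm[k]) return(out)
    if (d[k] >= 0) {
      tgt[[k]] <- (1 + d[k]):dm[k]
      src[[k]] <- 1:(dm[k] - d[k])
    } else {
      tgt[[k]] <- 1:(dm[k] + d[k])
      src[[k]] <- (1 - d[k]):dm[k]
    }
  }
  out[tgt[[1]], tgt[[2]], tgt[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Chebyshev (box) dilation by r = c(rx, ry, rz) voxels.
vx_dilate_box <- function(mask, r = c(1L, 1L, 1L)) {
  out <- mask
  for (axis in 1:3) {
    if (r[axis] < 1L) next
    acc <- out
    for (s in seq_len(r[axis])) {
      d <- c(0L, 0L, 0L)
      d[axis] <- s
      acc <- acc | vx_shift(out, d) | vx_shift(out, -d)
    }
    out <- acc
  }
  out
}

vx_erode_box <- function(mask, r = c(1L, 1L, 1L)) {
  out <- mask
  for (axis in 1:3) {
    if (r[axis] < 1L) next
    acc <- out
    for (s in seq_len(r[axis])) {
      d <- c(0L, 0L, 0L)
      d[axis] <- s
      acc <- acc & vx_shift(out, d) & vx_shift(out, -d)
    }
    out <- acc
  }
  out
}

# Morphological closing with a box element (dilate then erode).
vx_close_box <- function(mask, r = c(1L, 1L, 1L)) {
  vx_erode_box(vx_dilate_box(mask, r), r)
}

# Separable box maximum filter (for local-maximum detection).
vx_max_box <- function(a, r = c(1L, 1L, 1L)) {
  out <- a
  for (axis in 1:3) {
    if (r[axis] < 1L) next
    acc <- out
    for (s in seq_len(r[axis])) {
      d <- c(0L, 0L, 0L)
      d[axis] <- s
      acc <- pmax(acc, vx_shift(out, d, fill = -Inf), vx_shift(out, -d, fill = -Inf))
    }
    out <- acc
  }
  out
}

# Connected-component labelling of a logical array.
# Run-based: maximal runs along x are the union-find units; runs in
# neighbouring (y, z) columns are linked when their x-extents are adjacent
# under the requested connectivity, and components of the run-adjacency
# graph become labels. Labels are renumbered in first-voxel order so the
# result is deterministic.
vx_label <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  dm <- dim(mask)
  nx <- dm[1]
  v <- as.vector(mask)
  n <- length(v)
  if (!any(v)) return(array(0L, dm))

  first_in_col <- (seq_len(n) - 1L) %% nx == 0L
  prev <- c(FALSE, v[-n])
  is_start <- v & (first_in_col | !prev)
  run_vec <- cumsum(is_start)
  run_vec[!v] <- 0L
  n_run <- max(run_vec)
  run_arr <- array(as.integer(run_vec), dm)

  offsets <- if (connectivity == 6L) {
    list(c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    # half-space offsets excluding pure x (runs absorb x-adjacency)
    c(
      lapply(-1:1, function(dx) c(dx, 1L, 0L)),
      unlist(lapply(-1:1, function(dx) {
        lapply(-1:1, function(dy) c(dx, dy, 1L))
      }), recursive = FALSE)
    )
  }

  codes <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    sh <- vx_shift(run_arr, offsets[[i]], fill = 0L)
    sel <- which(run_arr > 0L & sh > 0L)
    if (length(sel)) {
      a <- run_arr[sel]; b <- sh[sel]
      ne <- a != b
      # encode each run pair as one double for fast dedup
      codes[[i]] <- unique((a[ne] - 1) * as.double(n_run) + b[ne])
    }
  }
  codes <- unique(unlist(codes))
  pairs <- if (length(codes)) {
    cbind((codes - 1) %/% n_run + 1, (codes - 1) %% n_run + 1)
  } else NULL

  if (is.null(pairs) || nrow(pairs) == 0L) {
    comp <- seq_len(n_run)
  } else {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_run - igraph::vcount(g)))
    comp <- as.integer(igraph::components(g)$membership)
  }

  # renumber components by order of first appearance along the array
  lab_vec <- integer(n)
  fg <- run_vec > 0L
  lab_vec[fg] <- comp[run_vec[fg]]
  first_seen <- lab_vec[fg][!duplicated(lab_vec[fg])]
  remap <- integer(max(comp))
  remap[first_seen] <- seq_along(first_seen)
  lab_vec[fg] <- remap[lab_vec[fg]]
  array(lab_vec, dm)
}

# Fill internal cavities: background components (6-connected) that do not
# touch the grid border are added to the mask.
vx_fill_holes <- function(mask) {
  dm <- dim(mask)
  bg <- vx_label(!mask, 6L)
  border <- unique(c(
    bg[1, , ], bg[dm[1], , ],
    bg[, 1, ], bg[, dm[2], ],
    bg[, , 1], bg[, , dm[3]]
  ))
  border <- setdiff(border, 0L)
  mask | (bg > 0L & !(bg %in% border))
}

# Physical voxel volume in um^3 from c(lateral, axial) sizes in nm.
vx_volume_um3 <- function(voxel_size_nm) {
  unname(voxel_size_nm[1]^2 * voxel_size_nm[2] * 1e-9)
}

# Voxel-centre physical coordinates (nm) for 1-based indices.
vx_centre_nm <- function(idx, voxel_size_nm) {
  sz <- c(voxel_size_nm[1], voxel_size_nm[1], voxel_size_nm[2])
  sweep(idx - 0.5, 2, sz, "*")
}
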