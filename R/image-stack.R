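#' Multi-channel anisotropic voxel stack
#'
#' Container for a 3D fluorescence image: one numeric array per channel,
#' all of identical dimensions, indexed `[x, y, z]`, plus the physical
#' voxel sizes. Super-resolution stacks are anisotropic: the default
#' lateral (x, y) pixel size is 39 nm and the axial (z) spacing 125 nm.
#'
#' @param channels Named list of 3D numeric arrays with identical
#'   dimensions; values are non-negative intensity counts (16-bit scale).
#' @param voxel_size_nm Numeric of length 2, `c(lateral, axial)` in nm.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_nm = c(39, 125)) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of 3D arrays", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3L)) {
    stop("every channel must be a 3D array", call. = FALSE)
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  voxel_size_nm <- as.numeric(voxel_size_nm)
  if (length(voxel_size_nm) != 2L || any(!is.finite(voxel_size_nm)) ||
      any(voxel_size_nm <= 0)) {
    stop("`voxel_size_nm` must be two positive numbers (lateral, axial)",
         call. = FALSE)
  }
  structure(
    list(channels = channels, voxel_size_nm = voxel_size_nm),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels, %d channel(s): %s\n",
    d[1], d[2], d[3], length(x$channels),
    paste(names(x$channels), collapse = ", ")
  ))
  cat(sprintf("voxel size: %g nm lateral, %g nm axial (%.3g um^3/voxel)\n",
              x$voxel_size_nm[1], x$voxel_size_nm[2],
              vx_volume_um3(x$voxel_size_nm)))
  invisible(x)
}

channel_names <- function(stack) names(stack$channels)

get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")), call. = FALSE)
  }
  stack$channels[[channel]]
}

#' Write an image stack as one multi-page TIFF per channel
#'
#' Each channel is written as a 16-bit multi-page TIFF (one page per
#' z-slice); voxel sizes are recorded in a sidecar JSON file so that
#' [read_image_stack()] can restore the object.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_image_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    a <- pmin(pmax(stack$channels[[ch]], 0), 65535) / 65535
    pages <- lapply(seq_len(d[3]), function(z) t(a[, , z]))  # tiff wants [y, x]
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(
    list(channels = names(stack$channels), dim = d,
         voxel_size_nm = stack$voxel_size_nm),
    meta, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, meta))
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir Directory holding the TIFFs and metadata file.
#' @param prefix Filename prefix used at write time.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(dir, prefix = "stack") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                            all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    a <- array(0, meta$dim)
    for (z in seq_along(pages)) a[, , z] <- t(pages[[z]]) * 65535
    channels[[ch]] <- round(a)
  }
  image_stack(channels, meta$voxel_size_nm)
}
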