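#' Simulate a nucleus image with planted, clustered nano-foci
#'
#' Builds a multi-channel 3D stack emulating a DAPI-stained nucleus with
#' gamma-H2AX-like nano-foci arranged in spatial clusters, with full
#' ground truth. The nucleus is a sphere of uniform DAPI signal; each
#' nano-focus is an isotropic (in nm) Gaussian intensity blob added to
#' its channel. Cluster centres are drawn uniformly in the nucleus with a
#' minimum mutual separation; member foci scatter around their centre
#' with an isotropic Gaussian spread. Optionally the DAPI signal is
#' dimmed inside foci (and boosted in a surrounding shell), and a marker
#' channel (e.g. CTCF-like) receives one blob offset from each focus
#' centroid by a fixed physical distance in a random direction.
#'
#' Default blob parameters (`focus_sigma_nm = 60`, `focus_amplitude =
#' 5000` against a detection threshold of 1000) give a thresholded
#' lateral diameter of about 215 nm, matching the ~200 nm nano-focus
#' scale; the default geometry (4 foci per cluster, 100 nm intra-cluster
#' spread, 2000 nm minimum cluster separation) mirrors the observed
#' median cluster size and makes clusters unambiguous at a 500 nm
#' linkage cutoff.
#'
#' @param shape Integer vector `c(nx, ny, nz)`, voxel grid dimensions.
#' @param voxel_size_nm `c(lateral, axial)` voxel sizes in nm.
#' @param n_clusters Number of planted clusters (0 gives pure noise).
#' @param foci_per_cluster Foci per cluster.
#' @param intra_cluster_sigma_nm Gaussian spread of foci around their
#'   cluster centre (nm).
#' @param min_intra_focus_nm Minimum mutual separation of foci within a
#'   cluster (nm); keeps planted blobs individually resolvable by the
#'   thresholded segmentation (default 350 nm, above the separation at
#'   which two default blobs' summed intensity saddles below the
#'   detection threshold).
#' @param min_inter_cluster_nm Minimum distance between cluster centres
#'   (must exceed `2 * intra_cluster_sigma_nm`).
#' @param nucleus_radius_um Nucleus sphere radius; default fills 90% of
#'   the smallest physical half-extent of the stack.
#' @param channels Channels to synthesize; `"dapi"` and `"gh2ax"` are
#'   always meaningful, any further name (e.g. `"ctcf"`) becomes a
#'   marker channel with blobs offset by `marker_offset_nm`.
#' @param focus_sigma_nm Gaussian sigma of focus blobs (nm).
#' @param focus_amplitude Peak blob intensity (counts).
#' @param dapi_level Uniform DAPI intensity inside the nucleus.
#' @param dapi_focus_mode `"dim"` (DAPI reduced inside focus support),
#'   `"shell"` (additionally boosted in the surrounding shell) or
#'   `"flat"` (unmodified).
#' @param dapi_focus_factor Multiplier applied to DAPI inside the focus
#'   support when dimming.
#' @param dapi_shell_factor Multiplier applied in the shell region for
#'   `dapi_focus_mode = "shell"`.
#' @param marker_offset_nm Physical offset of marker-channel blobs from
#'   focus centroids.
#' @param noise_sd Gaussian read-noise standard deviation (counts).
#' @param support_threshold Intensity defining the nominal focus support
#'   on the noiseless blob channel; planted DNA fractions are integrals
#'   of noiseless DAPI over this support.
#' @param seed Integer seed; identical seeds give identical stacks.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `image_truth`: tibble of planted foci with centroids, cluster
#'   ids and DNA fractions, cluster centres, nucleus geometry, all
#'   generator parameters).
#' @export
make_nucleus_image <- function(shape = c(160L, 160L, 48L),
                               voxel_size_nm = c(39, 125),
                               n_clusters = 5L,
                               foci_per_cluster = 4L,
                               intra_cluster_sigma_nm = 150,
                               min_intra_focus_nm = 350,
                               min_inter_cluster_nm = 2000,
                               nucleus_radius_um = NULL,
                               channels = c("dapi", "gh2ax"),
                               focus_sigma_nm = 60,
                               focus_amplitude = 5000,
                               dapi_level = 500,
                               dapi_focus_mode = c("dim", "shell", "flat"),
                               dapi_focus_factor = 0.7,
                               dapi_shell_factor = 1.3,
                               marker_offset_nm = 150,
                               noise_sd = 20,
                               support_threshold = 1000,
                               seed = 1L) {
  dapi_focus_mode <- match.arg(dapi_focus_mode)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  if (n_clusters > 0L && min_inter_cluster_nm <= 2 * intra_cluster_sigma_nm) {
    stop("`min_inter_cluster_nm` must exceed 2 * `intra_cluster_sigma_nm`",
         call. = FALSE)
  }
  sz <- c(voxel_size_nm[1], voxel_size_nm[1], voxel_size_nm[2])
  extent_nm <- shape * sz
  centre_nm <- extent_nm / 2
  if (is.null(nucleus_radius_um)) {
    nucleus_radius_um <- 0.9 * min(extent_nm) / 2 / 1000
  }
  radius_nm <- nucleus_radius_um * 1000
  if (radius_nm > min(extent_nm) / 2) {
    stop("nucleus sphere does not fit inside the requested stack", call. = FALSE)
  }
  margin_nm <- 3 * intra_cluster_sigma_nm + 4 * focus_sigma_nm
  if (n_clusters > 0L && radius_nm <= margin_nm) {
    stop("nucleus too small to contain foci with the requested blob geometry",
         call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    # cluster centres: uniform in the shrunken ball, minimum separation
    cl_centres <- matrix(numeric(0), 0L, 3L)
    if (n_clusters > 0L) {
      attempts <- 0L
      while (nrow(cl_centres) < n_clusters) {
        attempts <- attempts + 1L
        if (attempts > 5000L) {
          stop(sprintf(
            "could not place %d cluster centres at >= %g nm separation inside the nucleus",
            n_clusters, min_inter_cluster_nm), call. = FALSE)
        }
        p <- runif_ball(1L, radius_nm - margin_nm)
        if (nrow(cl_centres) == 0L ||
            all(sqrt(rowSums(sweep(cl_centres, 2, p[1, ])^2)) >=
                min_inter_cluster_nm)) {
          cl_centres <- rbind(cl_centres, p)
        }
      }
      cl_centres <- sweep(cl_centres, 2, centre_nm, "+")
    }

    # member foci around the centres: mutually separated (so planted
    # blobs are individually resolvable), truncated to the cluster
    # neighbourhood, and accepted only when single-linkage connected at
    # max_intra_link_nm so a planted cluster is a cluster under the
    # downstream linkage definition
    max_intra_link_nm <- 450
    trunc_nm <- max(2.5 * intra_cluster_sigma_nm, min_intra_focus_nm)
    foci <- matrix(numeric(0), 0L, 3L)
    cluster_of <- integer(0)
    for (k in seq_len(n_clusters)) {
      members <- NULL
      for (set_try in seq_len(500L)) {
        cand <- matrix(numeric(0), 0L, 3L)
        ok_set <- TRUE
        for (j in seq_len(foci_per_cluster)) {
          placed <- FALSE
          for (tr in seq_len(500L)) {
            p <- cl_centres[k, ] + stats::rnorm(3L, 0, intra_cluster_sigma_nm)
            if (sqrt(sum((p - cl_centres[k, ])^2)) > trunc_nm) next
            if (sqrt(sum((p - centre_nm)^2)) > radius_nm - 4 * focus_sigma_nm) next
            if (nrow(cand) > 0L &&
                any(sqrt(rowSums(sweep(cand, 2, p)^2)) < min_intra_focus_nm)) next
            placed <- TRUE
            break
          }
          if (!placed) { ok_set <- FALSE; break }
          cand <- rbind(cand, p)
        }
        if (ok_set && linked_at(cand, max_intra_link_nm)) {
          members <- cand
          break
        }
      }
      if (is.null(members)) {
        stop(sprintf(
          "could not place %d mutually separated, linkage-connected foci in a cluster",
          foci_per_cluster), call. = FALSE)
      }
      foci <- rbind(foci, members)
      cluster_of <- c(cluster_of, rep(k, foci_per_cluster))
    }
    n_foci <- nrow(foci)

    # voxel-centre coordinate grids (nm)
    xc <- (seq_len(shape[1]) - 0.5) * sz[1]
    yc <- (seq_len(shape[2]) - 0.5) * sz[2]
    zc <- (seq_len(shape[3]) - 0.5) * sz[3]
    in_nucleus <- outer(outer((xc - centre_nm[1])^2, (yc - centre_nm[2])^2, "+"),
                        (zc - centre_nm[3])^2, "+") <= radius_nm^2

    add_blobs <- function(a, centres, amplitude, sigma) {
      half <- ceiling(4 * sigma / sz)
      for (i in seq_len(nrow(centres))) {
        ctr <- centres[i, ]
        iv <- lapply(1:3, function(k) {
          c0 <- round(ctr[k] / sz[k] + 0.5)
          max(1L, c0 - half[k]):min(shape[k], c0 + half[k])
        })
        dx2 <- (xc[iv[[1]]] - ctr[1])^2
        dy2 <- (yc[iv[[2]]] - ctr[2])^2
        dz2 <- (zc[iv[[3]]] - ctr[3])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        a[iv[[1]], iv[[2]], iv[[3]]] <-
          a[iv[[1]], iv[[2]], iv[[3]]] + amplitude * exp(-d2 / (2 * sigma^2))
      }
      a
    }

    clean <- list()
    zero <- array(0, shape)
    if ("gh2ax" %in% channels) {
      clean$gh2ax <- add_blobs(zero, foci, focus_amplitude, focus_sigma_nm)
    }
    support <- if (!is.null(clean$gh2ax)) {
      clean$gh2ax >= support_threshold
    } else {
      add_blobs(zero, foci, focus_amplitude, focus_sigma_nm) >= support_threshold
    }
    if ("dapi" %in% channels) {
      dapi <- ifelse(in_nucleus, dapi_level, 0)
      if (dapi_focus_mode %in% c("dim", "shell") && n_foci > 0L) {
        dapi[support] <- dapi[support] * dapi_focus_factor
        if (dapi_focus_mode == "shell") {
          shell <- vx_dilate_box(support, c(3L, 3L, 3L)) & !support
          dapi[shell] <- dapi[shell] * dapi_shell_factor
        }
      }
      clean$dapi <- dapi
    }
    marker_names <- setdiff(channels, c("dapi", "gh2ax"))
    for (mk in marker_names) {
      if (n_foci > 0L) {
        dir <- matrix(stats::rnorm(3L * n_foci), ncol = 3L)
        dir <- dir / sqrt(rowSums(dir^2))
        mk_centres <- foci + dir * marker_offset_nm
        clean[[mk]] <- add_blobs(zero, mk_centres, focus_amplitude, focus_sigma_nm)
      } else {
        clean[[mk]] <- zero
      }
    }
    clean <- clean[channels]

    # planted DNA fractions: noiseless DAPI mass over each focus support
    dna_fraction <- rep(NA_real_, n_foci)
    if ("dapi" %in% channels && n_foci > 0L) {
      total_dapi <- sum(clean$dapi)
      sup_lab <- vx_label(support, 26L)
      cen_idx <- cbind(
        pmin(pmax(round(foci[, 1] / sz[1] + 0.5), 1L), shape[1]),
        pmin(pmax(round(foci[, 2] / sz[2] + 0.5), 1L), shape[2]),
        pmin(pmax(round(foci[, 3] / sz[3] + 0.5), 1L), shape[3])
      )
      own <- sup_lab[cen_idx]
      masses <- rowsum(clean$dapi[sup_lab > 0L],
                       group = sup_lab[sup_lab > 0L])
      for (i in seq_len(n_foci)) {
        if (own[i] > 0L) dna_fraction[i] <- masses[as.character(own[i]), 1] / total_dapi
      }
    }

    noisy <- lapply(clean, function(a) {
      pmax(a + array(stats::rnorm(length(a), 0, noise_sd), dim(a)), 0)
    })

    truth <- structure(list(
      foci = tibble::tibble(
        focus_id = seq_len(n_foci),
        cluster = cluster_of,
        x_nm = foci[, 1], y_nm = foci[, 2], z_nm = foci[, 3],
        dna_fraction = dna_fraction
      ),
      cluster_centres = cl_centres,
      nucleus_centre_nm = centre_nm,
      nucleus_radius_um = nucleus_radius_um,
      focus_sigma_nm = focus_sigma_nm,
      support_threshold = support_threshold,
      params = list(
        shape = shape, voxel_size_nm = voxel_size_nm,
        n_clusters = n_clusters, foci_per_cluster = foci_per_cluster,
        intra_cluster_sigma_nm = intra_cluster_sigma_nm,
        min_inter_cluster_nm = min_inter_cluster_nm,
        focus_amplitude = focus_amplitude, dapi_level = dapi_level,
        dapi_focus_mode = dapi_focus_mode, noise_sd = noise_sd,
        marker_offset_nm = marker_offset_nm
      ),
      seed = as.integer(seed)
    ), class = "image_truth")

    list(stack = image_stack(noisy, voxel_size_nm), truth = truth)
  })
}

# single-linkage connectivity of a small point set at a distance cutoff
linked_at <- function(pts, cutoff_nm) {
  n <- nrow(pts)
  if (n <= 1L) return(TRUE)
  g <- as.matrix(stats::dist(pts)) < cutoff_nm
  reach <- g[1, ] | seq_len(n) == 1L
  repeat {
    new <- reach | colSums(g[reach, , drop = FALSE]) > 0L
    if (all(new == reach)) break
    reach <- new
  }
  all(reach)
}

#' Write image ground truth as TSV + JSON
#'
#' @param truth An `image_truth` object from [make_nucleus_image()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_image_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, sprintf("%s_foci.tsv", prefix))
  readr::write_tsv(truth$foci, tsv)
  js <- file.path(dir, sprintf("%s_params.json", prefix))
  jsonlite::write_json(
    c(truth$params,
      list(nucleus_radius_um = truth$nucleus_radius_um, seed = truth$seed)),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, js))
}
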