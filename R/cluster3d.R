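#' Group nano-foci into clusters by a centroid-distance cutoff
#'
#' Two foci belong to the same cluster when a chain of pairwise centroid
#' distances strictly below `cutoff_nm` connects them (single-linkage
#' connected components; pairs at exactly the cutoff are not linked).
#'
#' @param foci Tibble with centroid columns `centroid_x_nm`,
#'   `centroid_y_nm`, `centroid_z_nm` (as produced by [foci_table()]).
#' @param cutoff_nm Linkage cutoff in nm (default 500).
#' @return The input tibble with a `cluster` integer column appended;
#'   cluster ids are numbered by first focus appearance.
#' @export
cluster_foci <- function(foci, cutoff_nm = 500) {
  if (!is.numeric(cutoff_nm) || length(cutoff_nm) != 1L || cutoff_nm <= 0) {
    stop("`cutoff_nm` must be a single positive number", call. = FALSE)
  }
  pts <- centroid_matrix(foci)
  n <- nrow(pts)
  if (n == 0L) return(dplyr::mutate(foci, cluster = integer(0)))
  d <- as.matrix(stats::dist(pts))
  adj <- d < cutoff_nm
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  first <- memb[!duplicated(memb)]
  remap <- integer(max(memb))
  remap[first] <- seq_along(first)
  dplyr::mutate(foci, cluster = remap[memb])
}

centroid_matrix <- function(foci) {
  cols <- c("centroid_x_nm", "centroid_y_nm", "centroid_z_nm")
  if (!all(cols %in% names(foci))) {
    stop("centroid columns centroid_{x,y,z}_nm are required", call. = FALSE)
  }
  as.matrix(foci[, cols])
}

#' Per-cluster structural metrics
#'
#' For every cluster: member count; integrated volume (sum of member
#' focus volumes); inter-focal volume (convex hull volume of the member
#' centroids, 0 with a degeneracy flag for fewer than 4 non-coplanar
#' points); the shortest path connecting all centroids (shortest open
#' Hamiltonian path, exact via dynamic programming up to
#' `exact_path_max` members, nearest-neighbour + 2-opt above, flagged in
#' `path_exact`); the mean pairwise inter-centroid distance; and the
#' summed member DNA content when a `dna_content_kb` column is present.
#'
#' @param foci A [cluster_foci()] result (must carry a `cluster` column).
#' @param exact_path_max Largest member count solved exactly (default 10).
#' @return A tibble with one row per cluster: `cluster`, `n_foci`,
#'   `integrated_volume_um3`, `interfocal_volume_um3`,
#'   `hull_degenerate`, `shortest_path_nm`, `path_exact`,
#'   `mean_intercentroid_nm`, `dna_content_kb`.
#' @export
cluster_metrics <- function(foci, exact_path_max = 10L) {
  if (!"cluster" %in% names(foci)) {
    stop("`foci` must carry a `cluster` column; run cluster_foci() first",
         call. = FALSE)
  }
  pts <- centroid_matrix(foci)
  has_vol <- "volume_um3" %in% names(foci)
  has_dna <- "dna_content_kb" %in% names(foci)
  ids <- sort(unique(foci$cluster))
  rows <- lapply(ids, function(k) {
    sel <- foci$cluster == k
    p <- pts[sel, , drop = FALSE]
    m <- nrow(p)
    if (m == 1L) {
      path <- 0; exact <- TRUE; meanic <- 0
      hull <- list(volume = 0, degenerate = TRUE)
    } else {
      d <- as.matrix(stats::dist(p))
      meanic <- mean(d[upper.tri(d)])
      if (m <= exact_path_max) {
        path <- hk_shortest_path(d); exact <- TRUE
      } else {
        path <- heuristic_shortest_path(d); exact <- FALSE
      }
      hull <- hull_volume_nm3(p)
    }
    tibble::tibble(
      cluster = k, n_foci = m,
      integrated_volume_um3 = if (has_vol) sum(foci$volume_um3[sel]) else NA_real_,
      interfocal_volume_um3 = hull$volume * 1e-9,
      hull_degenerate = hull$degenerate,
      shortest_path_nm = path,
      path_exact = exact,
      mean_intercentroid_nm = meanic,
      dna_content_kb = if (has_dna) sum(foci$dna_content_kb[sel]) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Cluster counts over a range of cutoffs
#'
#' @param foci Tibble with centroid columns.
#' @param cutoffs_nm Sorted cutoff values in nm (default 300..700 by 50).
#' @return A tibble `cutoff_nm`, `n_clusters`; the count is
#'   non-increasing in the cutoff.
#' @export
cutoff_scan <- function(foci, cutoffs_nm = seq(300, 700, by = 50)) {
  tibble::tibble(
    cutoff_nm = cutoffs_nm,
    n_clusters = vapply(cutoffs_nm, function(ct) {
      if (nrow(foci) == 0L) return(0L)
      max(cluster_foci(foci, ct)$cluster)
    }, integer(1))
  )
}

# Exact shortest open Hamiltonian path by Held-Karp dynamic programming.
hk_shortest_path <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  if (n == 2L) return(d[1, 2])
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, nrow = full, ncol = n)
  for (j in seq_len(n)) dp[bitwShiftL(1L, j - 1L), j] <- 0
  for (S in seq_len(full)) {
    for (j in seq_len(n)) {
      bj <- bitwShiftL(1L, j - 1L)
      if (!bitwAnd(S, bj) || is.infinite(dp[S, j])) next
      rest <- bitwAnd(full, bitwNot(S))
      for (i in seq_len(n)) {
        bi <- bitwShiftL(1L, i - 1L)
        if (!bitwAnd(rest, bi)) next
        S2 <- bitwOr(S, bi)
        v <- dp[S, j] + d[j, i]
        if (v < dp[S2, i]) dp[S2, i] <- v
      }
    }
  }
  min(dp[full, ])
}

# Nearest-neighbour construction from every start + 2-opt refinement.
heuristic_shortest_path <- function(d) {
  n <- nrow(d)
  best <- Inf
  best_tour <- NULL
  for (s in seq_len(n)) {
    tour <- s
    left <- setdiff(seq_len(n), s)
    while (length(left)) {
      nxt <- left[which.min(d[tour[length(tour)], left])]
      tour <- c(tour, nxt)
      left <- setdiff(left, nxt)
    }
    len <- path_length(d, tour)
    if (len < best) { best <- len; best_tour <- tour }
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        cand <- best_tour
        cand[i:j] <- rev(cand[i:j])
        len <- path_length(d, cand)
        if (len < best - 1e-12) {
          best <- len; best_tour <- cand; improved <- TRUE
        }
      }
    }
  }
  best
}

path_length <- function(d, tour) {
  sum(d[cbind(tour[-length(tour)], tour[-1L])])
}

# Exact convex hull volume (nm^3) of a small 3D point set by brute-force
# facet detection: a triple spans a supporting plane when all points lie
# on one side; coplanar facet groups are fan-triangulated and signed
# tetrahedron volumes against an interior point are accumulated.
hull_volume_nm3 <- function(p, tol = 1e-9) {
  p <- unique(round(p, 9))
  n <- nrow(p)
  if (n < 4L) return(list(volume = 0, degenerate = TRUE))
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  if (qr(q)$rank < 3L) return(list(volume = 0, degenerate = TRUE))
  scale <- max(abs(q))
  planes <- list()
  combs <- utils::combn(n, 3L)
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]; k <- combs[3, c_i]
    nrm <- cross3(p[j, ] - p[i, ], p[k, ] - p[i, ])
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale^2) next
    nrm <- nrm / nn
    s <- as.vector((sweep(p, 2, p[i, ])) %*% nrm)
    if (all(s <= tol * scale)) {
      planes[[length(planes) + 1L]] <- list(nrm = -nrm, pt = p[i, ],
                                            on = which(abs(s) <= tol * scale))
    } else if (all(s >= -tol * scale)) {
      planes[[length(planes) + 1L]] <- list(nrm = nrm, pt = p[i, ],
                                            on = which(abs(s) <= tol * scale))
    }
  }
  if (!length(planes)) return(list(volume = 0, degenerate = TRUE))
  key <- vapply(planes, function(pl) paste(sort(pl$on), collapse = ","),
                character(1))
  planes <- planes[!duplicated(key)]
  vol <- 0
  for (pl in planes) {
    verts <- p[pl$on, , drop = FALSE]
    # order facet vertices around their 2D projection
    e1 <- verts[2, ] - verts[1, ]
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(pl$nrm, e1)
    vc <- colMeans(verts)
    ang <- atan2((sweep(verts, 2, vc)) %*% e2, (sweep(verts, 2, vc)) %*% e1)
    verts <- verts[order(ang), , drop = FALSE]
    for (t in 2:(nrow(verts) - 1L)) {
      a <- verts[1, ] - ctr; b <- verts[t, ] - ctr; cc <- verts[t + 1L, ] - ctr
      vol <- vol + abs(sum(a * cross3(b, cc))) / 6
    }
  }
  list(volume = vol, degenerate = FALSE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
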