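# Shared fixtures and independent oracles. Fixtures are built in code at
# test time; the expensive default simulation is cached per session.

toy_stack <- function(channels, voxel_size_nm = c(39, 125)) {
  image_stack(channels, voxel_size_nm)
}

# solid DAPI ball of a given volume, coarse voxels for speed
ball_stack <- function(volume_um3, voxel_size_nm = c(200, 400),
                       level = 1000, pad = 4L, cavity_um = 0) {
  r_nm <- (3 * volume_um3 / (4 * pi))^(1 / 3) * 1000
  sz <- c(voxel_size_nm[1], voxel_size_nm[1], voxel_size_nm[2])
  shape <- ceiling(2 * r_nm / sz) + 2L * pad
  ctr <- shape * sz / 2
  xc <- (seq_len(shape[1]) - 0.5) * sz[1]
  yc <- (seq_len(shape[2]) - 0.5) * sz[2]
  zc <- (seq_len(shape[3]) - 0.5) * sz[3]
  d2 <- outer(outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
  a <- ifelse(d2 <= r_nm^2, level, 0)
  if (cavity_um > 0) a[d2 <= (cavity_um * 1000)^2] <- 0
  image_stack(list(dapi = a), voxel_size_nm)
}

# wrap a plain integer array as a focus label grid
as_labels <- function(arr, voxel_size_nm = c(39, 125), channel = "gh2ax") {
  structure(array(as.integer(arr), dim(arr)),
            voxel_size_nm = voxel_size_nm, channel = channel,
            class = "focus_labels")
}

# default study-conditions simulation, segmented end to end; cached
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- make_nucleus_image(seed = 1)
      nucleus <- segment_nucleus(sim$stack, "dapi", threshold = 150,
                                 min_volume_um3 = 5)
      labels <- separate_touching(
        detect_foci(sim$stack, "gh2ax", nucleus), sim$stack)
      foci <- foci_table(labels, sim$stack, nucleus)
      cache <<- list(sim = sim, nucleus = nucleus, labels = labels,
                     foci = foci)
    }
    cache
  }
})

# ---- independent oracles -------------------------------------------------

# transitive closure of the strict-cutoff adjacency by boolean powers
oracle_cluster <- function(pts, cutoff) {
  n <- nrow(pts)
  g <- as.matrix(stats::dist(pts)) < cutoff
  diag(g) <- TRUE
  repeat {
    g2 <- (g %*% g) > 0
    if (all(g2 == g)) break
    g <- g2
  }
  memb <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      nxt <- nxt + 1L
      memb[g[i, ]] <- nxt
    }
  }
  memb
}

# exhaustive-permutation shortest open Hamiltonian path
oracle_shortest_path <- function(d) {
  n <- nrow(d)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    len <- sum(d[cbind(p[-n], p[-1L])])
    if (len < best) best <- len
  }
  best
}

# naive IUPAC motif scan, one strand
oracle_motif_scan <- function(seq, consensus) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(s) - length(m) + 1L)) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (!(s[i + j - 1L] %in% iupac[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)  # 0-based
  }
  hits
}

revcomp_chr <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(i) length(unique(b[i])) == 1L)) &&
    length(unique(a)) == length(unique(b))
}

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}
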