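test_that("nucleus volume of a synthetic ball matches the analytic value", {
  st <- ball_stack(300)
  nuc <- segment_nucleus(st, "dapi", threshold = 500, morph_iterations = 0L)
  expect_lt(abs(nuc$volume_um3 - 300) / 300, 0.02)
  # the morphology rounds (dilate + close) can only grow the mask
  nuc2 <- segment_nucleus(st, "dapi", threshold = 500, morph_iterations = 2L)
  expect_gte(nuc2$volume_um3, nuc$volume_um3)
})

test_that("balls below the volume floor raise a 'no nucleus' error", {
  st <- ball_stack(100)
  expect_error(segment_nucleus(st, "dapi", threshold = 500), "no nucleus")
})

test_that("internal cavities are filled into the nucleus mask", {
  solid <- ball_stack(300)
  holed <- ball_stack(300, cavity_um = 1)
  nuc_solid <- segment_nucleus(solid, "dapi", threshold = 500,
                               morph_iterations = 0L)
  nuc_holed <- segment_nucleus(holed, "dapi", threshold = 500,
                               morph_iterations = 0L)
  expect_equal(nuc_holed$volume_um3, nuc_solid$volume_um3)
})

test_that("detect_foci finds nothing below threshold and all isolated blobs", {
  dm <- c(60L, 60L, 24L)
  flat <- array(500, dm)
  nucleus <- structure(list(mask = array(TRUE, dm), volume_um3 = 1,
                            integrated_dapi = 1, voxel_size_nm = c(39, 125)),
                       class = "nucleus_mask")
  st <- toy_stack(list(gh2ax = flat))
  expect_equal(max(detect_foci(st, "gh2ax", nucleus)), 0L)

  # five well-separated blobs
  centres <- rbind(c(10, 10, 6), c(40, 10, 6), c(10, 40, 18),
                   c(40, 40, 18), c(25, 25, 12))
  a <- array(0, dm)
  for (i in seq_len(nrow(centres))) {
    v <- centres[i, ]
    a[v[1] + (-2:2), v[2] + (-2:2), v[3] + (-1:1)] <- 3000
  }
  st <- toy_stack(list(gh2ax = a))
  lab <- detect_foci(st, "gh2ax", nucleus)
  expect_equal(max(lab), 5L)
  ft <- foci_table(lab, st)
  got <- as.matrix(ft[, c("centroid_x_nm", "centroid_y_nm", "centroid_z_nm")])
  want <- nanofoci:::vx_centre_nm(centres, c(39, 125))
  # every planted centre is recovered within one voxel
  for (i in seq_len(nrow(want))) {
    d <- sqrt(colSums((t(got) - want[i, ])^2))
    expect_lt(min(d), 125)
  }
})

test_that("objects below the minimum volume are removed", {
  # 3 voxels at 39/39/125 nm: 3 x 1.90e-4 um^3 = 5.7e-4 um^3 < 0.001
  dm <- c(30L, 30L, 12L)
  nucleus <- structure(list(mask = array(TRUE, dm), volume_um3 = 1,
                            integrated_dapi = 1, voxel_size_nm = c(39, 125)),
                       class = "nucleus_mask")
  a <- array(0, dm)
  a[10:12, 10, 5] <- 2000                       # 3 voxels, removed
  a[20:22, 20:21, 8] <- 2000                    # 6 voxels, kept
  st <- toy_stack(list(gh2ax = a))
  lab <- detect_foci(st, "gh2ax", nucleus)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 6L)
  expect_equal(3 * nanofoci:::vx_volume_um3(c(39, 125)) < 0.001, TRUE)
})

test_that("foci outside the nucleus are discarded", {
  dm <- c(30L, 30L, 12L)
  mask <- array(FALSE, dm)
  mask[1:15, , ] <- TRUE
  nucleus <- structure(list(mask = mask, volume_um3 = 1, integrated_dapi = 1,
                            voxel_size_nm = c(39, 125)),
                       class = "nucleus_mask")
  a <- array(0, dm)
  a[5:7, 10:12, 5:6] <- 2000     # inside
  a[22:24, 10:12, 5:6] <- 2000   # outside
  lab <- detect_foci(toy_stack(list(gh2ax = a)), "gh2ax", nucleus)
  expect_equal(max(lab), 1L)
  expect_true(all(which(lab > 0) %in% which(a > 0 & mask)))
})

test_that("a fused dumbbell is split into two balanced objects", {
  dm <- c(64L, 40L, 20L)
  sz <- c(39, 39, 125)
  xc <- (seq_len(dm[1]) - 0.5) * sz[1]
  yc <- (seq_len(dm[2]) - 0.5) * sz[2]
  zc <- (seq_len(dm[3]) - 0.5) * sz[3]
  blob <- function(a, ctr, amp, sig) {
    d2 <- outer(outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
    a + amp * exp(-d2 / (2 * sig^2))
  }
  mid <- c(dm[1] * 39 / 2, dm[2] * 39 / 2, dm[3] * 125 / 2) + c(11, 7, 13)
  a <- blob(array(0, dm), mid + c(-300, 0, 0), 5000, 160)
  a <- blob(a, mid + c(300, 0, 0), 5000, 160)
  st <- toy_stack(list(gh2ax = a))
  nucleus <- structure(list(mask = array(TRUE, dm), volume_um3 = 1,
                            integrated_dapi = 1, voxel_size_nm = c(39, 125)),
                       class = "nucleus_mask")
  lab <- detect_foci(st, "gh2ax", nucleus)
  expect_equal(max(lab), 1L)
  vol <- sum(lab > 0) * nanofoci:::vx_volume_um3(c(39, 125))
  expect_gt(vol, 0.1)  # above the 2 x 0.05 um^3 split trigger
  split <- separate_touching(lab, st)
  expect_equal(max(split), 2L)
  masses <- tabulate(split[split > 0])
  expect_lt(abs(masses[1] - masses[2]) / mean(masses), 0.2)
})

test_that("an isolated small blob is left untouched by the splitter", {
  dm <- c(30L, 30L, 14L)
  a <- array(0, dm)
  a[12:17, 12:17, 5:9] <- 3000   # ~0.034 um^3 < 2 x 0.05
  st <- toy_stack(list(gh2ax = a))
  lab <- as_labels(ifelse(a > 0, 1L, 0L))
  out <- separate_touching(lab, st)
  expect_identical(as.integer(out), as.integer(lab))
})

test_that("three collinear fused blobs split into three ordered objects", {
  dm <- c(96L, 40L, 20L)
  sz <- c(39, 39, 125)
  xc <- (seq_len(dm[1]) - 0.5) * sz[1]
  yc <- (seq_len(dm[2]) - 0.5) * sz[2]
  zc <- (seq_len(dm[3]) - 0.5) * sz[3]
  blob <- function(a, ctr, amp, sig) {
    d2 <- outer(outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
    a + amp * exp(-d2 / (2 * sig^2))
  }
  mid <- c(dm[1] * 39 / 2, dm[2] * 39 / 2, dm[3] * 125 / 2) + c(11, 7, 13)
  planted_x <- mid[1] + c(-600, 0, 600)
  a <- array(0, dm)
  for (x in planted_x) a <- blob(a, c(x, mid[2], mid[3]), 5000, 160)
  st <- toy_stack(list(gh2ax = a))
  nucleus <- structure(list(mask = array(TRUE, dm), volume_um3 = 1,
                            integrated_dapi = 1, voxel_size_nm = c(39, 125)),
                       class = "nucleus_mask")
  lab <- detect_foci(st, "gh2ax", nucleus)
  expect_equal(max(lab), 1L)
  split <- separate_touching(lab, st)
  expect_equal(max(split), 3L)
  ft <- foci_table(split, st)
  expect_equal(order(ft$centroid_x_nm), order(planted_x))
  expect_equal(sort(ft$centroid_x_nm), planted_x, tolerance = 0.02)
})

test_that("foci_table measures volumes, intensities and anisotropy exactly", {
  dm <- c(20L, 20L, 10L)
  a <- array(0, dm)
  a[3:4, 3:4, 3:4] <- 1500   # 8-voxel cube
  st <- toy_stack(list(gh2ax = a))
  ft <- foci_table(as_labels(ifelse(a > 0, 1L, 0L)), st)
  expect_equal(ft$voxel_count, 8L)
  expect_equal(ft$volume_um3, 8 * 39 * 39 * 125 * 1e-9)
  expect_equal(ft$integrated_gh2ax, 8 * 1500)  # conservation on zero background

  # two single-voxel foci one z-step apart: physical distance 125 nm
  b <- array(0, dm)
  b[10, 10, 4] <- 2000
  b[10, 10, 6] <- 2000
  lab2 <- array(0L, dm); lab2[10, 10, 4] <- 1L; lab2[10, 10, 6] <- 2L
  ft2 <- foci_table(as_labels(lab2), toy_stack(list(gh2ax = b)))
  d <- sqrt(sum((as.matrix(ft2[1, 5:7]) - as.matrix(ft2[2, 5:7]))^2))
  expect_equal(d, 2 * 125)
})

test_that("empty label grids give an empty focus table, not an error", {
  dm <- c(10L, 10L, 5L)
  st <- toy_stack(list(gh2ax = array(0, dm)))
  ft <- foci_table(as_labels(array(0L, dm)), st)
  expect_equal(nrow(ft), 0L)
  expect_true(all(c("focus_id", "volume_um3", "integrated_gh2ax") %in% names(ft)))
})

test_that("segmented nano-foci have ~200 nm median lateral diameter", {
  fx <- default_sim()
  lab <- fx$labels
  diams <- vapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    (max(w[, 1]) - min(w[, 1]) + 1) * 39
  }, numeric(1))
  expect_lt(abs(stats::median(diams) - 200) / 200, 0.2)
})

test_that("raising the intensity threshold never increases the focus count", {
  fx <- default_sim()
  counts <- vapply(c(800, 1000, 1500, 2500, 4000), function(thr) {
    max(detect_foci(fx$sim$stack, "gh2ax", fx$nucleus,
                    intensity_threshold = thr))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("every above-threshold voxel in the nucleus is labelled or size-filtered", {
  fx <- default_sim()
  a <- fx$sim$stack$channels$gh2ax
  all_lab <- detect_foci(fx$sim$stack, "gh2ax", fx$nucleus,
                         min_volume_um3 = 0)
  kept <- detect_foci(fx$sim$stack, "gh2ax", fx$nucleus)
  # the size filter removes whole components, never individual voxels
  expect_true(all(all_lab[kept > 0] > 0))
  pairs <- unique(cbind(as.integer(all_lab[all_lab > 0]),
                        as.integer(kept[all_lab > 0])))
  # each unfiltered component maps to exactly one kept label (or to 0)
  expect_equal(anyDuplicated(pairs[pairs[, 2] > 0, 1]), 0L)
  # kept components all reach the minimum volume
  vox <- nanofoci:::vx_volume_um3(c(39, 125))
  expect_true(all(tabulate(kept[kept > 0]) * vox >= 0.001))
})
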