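flat_track <- function(values, bin_size = 10000L, chrom = "chr1") {
  n <- length(values)
  out <- tibble::tibble(chrom = chrom, start = (0:(n - 1)) * bin_size,
                        end = (1:n) * bin_size, value = as.numeric(values))
  attr(out, "bin_size") <- bin_size
  out
}

test_that("RPKM binning follows the formula and conserves reads", {
  # 100 reads in one 10-kb bin out of 1e4 total:
  # RPKM = 100 / (10 * 1e4/1e6) = 1000
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(seq(0, by = 36, length.out = 100) + 20000,
              withr::with_seed(1, sample.int(940000, 9900) + 39999))
  ) |> dplyr::mutate(end = start + 36)
  tr <- bin_rpkm(reads, c(chr1 = 1000000L), 10000L)
  expect_equal(tr$value[tr$start == 20000], 100 / (10 * 1e4 / 1e6))
  # empty bin
  expect_equal(tr$value[tr$start == 0], 0)
  # read conservation under the midpoint rule
  counts <- tr$value * ((tr$end - tr$start) / 1000) * (nrow(reads) / 1e6)
  expect_equal(sum(counts), nrow(reads))
  expect_error(bin_rpkm(reads[0, ], c(chr1 = 1000L)), "zero")
})

test_that("smoothing is the identity at w = 1 and spreads impulses", {
  tr <- flat_track(c(rep(0, 10), 100, rep(0, 10)))
  expect_identical(smooth_track(tr, 1)$value, tr$value)
  s5 <- smooth_track(tr, 5)$value
  expect_equal(s5[9:13], rep(20, 5))
  expect_equal(sum(s5), 100)  # interior impulse mass is conserved
  # constant tracks are unchanged; normalization maps them to ones
  const <- flat_track(rep(7, 50))
  expect_equal(smooth_track(const, 5)$value, rep(7, 50))
  expect_equal(normalize_to_genome_mean(const)$value, rep(1, 50))
  expect_error(smooth_track(tr, 0), "1..25")
  # truncated edge windows: first bin of w=5 averages bins 1..3
  ramp <- flat_track(1:10)
  expect_equal(smooth_track(ramp, 5)$value[1], mean(1:3))
})

test_that("Spearman correlations hit the exact and planted values", {
  x <- withr::with_seed(2, stats::runif(500))
  g <- flat_track(x)
  feats <- list(mono = flat_track(exp(3 * x)),
                anti = flat_track(-x))
  out <- correlate_features(g, feats)
  expect_equal(out$rho[out$feature == "mono"], 1)
  expect_equal(out$rho[out$feature == "anti"], -1)

  # Gaussian copula with Spearman rho 0.8 over 10,000 bins
  rho_s <- 0.8
  rho_p <- 2 * sin(pi * rho_s / 6)
  xy <- withr::with_seed(3, {
    z1 <- stats::rnorm(10000)
    z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * stats::rnorm(10000)
    list(x = z1, y = z2)
  })
  out2 <- correlate_features(flat_track(xy$x), list(f = flat_track(xy$y)))
  expect_lt(abs(out2$rho - 0.8), 0.02)

  # equivalence with the rank-then-Pearson oracle on tied integer data
  a <- withr::with_seed(4, stats::rpois(200, 3))
  b <- withr::with_seed(5, stats::rpois(200, 3))
  got <- correlate_features(flat_track(a), list(f = flat_track(b)))$rho
  expect_equal(got, stats::cor(rank(a), rank(b)))
  expect_error(correlate_features(flat_track(1:2), list(f = flat_track(1:2))),
               "fewer than 3")
})

test_that("volume fractions map to the documented percentiles", {
  tr <- flat_track(withr::with_seed(6, stats::runif(10000)))
  f1 <- percentile_filter(tr, 0.21)
  expect_equal(attr(f1, "percentile"), 99.79)
  f2 <- percentile_filter(tr, 7.81)
  expect_equal(attr(f2, "percentile"), 92.19)
  # retained fraction within one bin of the request on continuous values
  expect_lt(abs(sum(f2$retained) - 0.0781 * 10000), 1 + 1e-9)
  # degenerate constant track: all bins tie and all are retained
  expect_true(all(percentile_filter(flat_track(rep(1, 100)), 7.81)$retained))
  expect_error(percentile_filter(tr, 0), "0, 100")
})

test_that("domains are maximal runs with conserved linear coverage", {
  tr <- flat_track(c(5, 6, 1, 7))
  tr$retained <- c(TRUE, TRUE, FALSE, TRUE)
  dom <- call_domains(tr)
  expect_equal(nrow(dom), 2L)
  expect_equal(dom$end - dom$start, c(20000, 10000))
  expect_equal(dom$n_bins, c(2L, 1L))
  expect_equal(dom$mean_signal, c(5.5, 7))

  all_tr <- flat_track(rep(1, 10))
  all_tr$retained <- TRUE
  expect_equal(nrow(call_domains(all_tr)), 1L)

  # chromosome boundaries break runs
  two <- dplyr::bind_rows(flat_track(c(1, 1)), flat_track(c(1, 1), chrom = "chr2"))
  two$retained <- TRUE
  expect_equal(nrow(call_domains(two)), 2L)

  # conservation: coverage equals retained bins x bin size
  rnd <- flat_track(withr::with_seed(7, stats::runif(500)))
  flt <- percentile_filter(rnd, 12.5)
  expect_equal(domain_coverage(call_domains(flt)), sum(flt$retained) * 10000)

  # noiseless planted domains are recovered with exact boundaries
  tt <- track_truth(tibble::tibble(chrom = "chr1",
                                   start = c(20, 50) * 1e4, end = c(25, 60) * 1e4),
                    background_rate = 0, enrichment_rate = 40, seed = 8)
  tr2 <- make_chipseq_track(1e7, 10000, tt)
  dom2 <- call_domains(percentile_filter(tr2, 100 * mean(tr2$in_domain)))
  expect_equal(dom2$start, c(200000, 500000))
  expect_equal(dom2$end, c(250000, 600000))
})

test_that("smoothing-factor matching minimises over the exhaustive scan", {
  # target arithmetic: 3120 nano-foci at ploidy factor 3.12 -> 1000
  tr <- flat_track(withr::with_seed(9, stats::rpois(2000, 5)))
  m <- match_smoothing(tr, 10, n_nanofoci = 3120)
  expect_equal(m$target, 1000)
  expect_equal(nrow(m$scan), 25L)
  expect_equal(m$scan$abs_diff[m$scan$w == m$chosen_w], min(m$scan$abs_diff))

  # a w whose domain count uniquely equals the target must be chosen
  counts <- m$scan$n_domains
  uniq <- which(!(counts %in% counts[duplicated(counts)]))
  if (length(uniq) > 0L) {
    w_star <- m$scan$w[uniq[length(uniq)]]
    n_star <- counts[uniq[length(uniq)]]
    m2 <- match_smoothing(tr, 10, n_nanofoci = n_star * 3.12)
    expect_equal(m2$chosen_w, w_star)
    expect_equal(nrow(m2$domains), n_star)
  }

  # ties resolve to the smaller w (constant track: 1 domain for every w)
  const <- flat_track(rep(3, 200))
  m3 <- match_smoothing(const, 5, n_nanofoci = 3.12)
  expect_equal(m3$chosen_w, 1L)
})

test_that("boundary distances and occupancy profiles follow the plants", {
  domains <- tibble::tibble(chrom = "chr1", start = c(2e6, 8e6),
                            end = c(3e6, 9e6), n_bins = 100L, mean_signal = 1)
  # peaks exactly at the boundaries
  at <- tibble::tibble(chrom = "chr1",
                       start = c(2e6, 3e6, 8e6, 9e6) - 100,
                       end = c(2e6, 3e6, 8e6, 9e6) + 100,
                       score = 10)
  res <- ctcf_boundary_analysis(domains, at)
  expect_equal(res$boundaries$distance_bp, rep(0, 4))

  # peaks planted 50 kb outside every border
  out50 <- tibble::tibble(chrom = "chr1",
                          start = c(2e6 - 5e4, 3e6 + 5e4, 8e6 - 5e4, 9e6 + 5e4) - 100,
                          end = c(2e6 - 5e4, 3e6 + 5e4, 8e6 - 5e4, 9e6 + 5e4) + 100,
                          score = 7)
  res2 <- ctcf_boundary_analysis(domains, out50)
  expect_equal(res2$boundaries$distance_bp, rep(5e4, 4))
  prof <- res2$profile
  expect_equal(prof$summed_score[prof$offset_bin == "-100..0"], 4 * 7)
  expect_equal(prof$summed_score[prof$offset_bin == "0..100"], 0)

  # max-score pre-filter keeps exactly the maximum-score subset
  mix <- dplyr::bind_rows(at, dplyr::mutate(out50, score = 3))
  res3 <- ctcf_boundary_analysis(domains, mix, max_score_only = TRUE)
  expect_equal(res3$boundaries$distance_bp, rep(0, 4))

  # chromosome without peaks: flagged missing
  far <- tibble::tibble(chrom = "chr2", start = 0, end = 200, score = 1)
  res4 <- ctcf_boundary_analysis(domains, far)
  expect_true(all(res4$boundaries$missing))
})

test_that("motif scanning matches the naive oracle and expectations", {
  # direct match, 0-based offset
  ms <- scan_motif(c(chrA = "TTACGTTT"), "ACGT")
  fwd <- ms$sites[ms$sites$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 2L)
  # palindromic consensus: forward and reverse sites coincide
  expect_equal(ms$sites$start[ms$sites$strand == "-"], 2L)

  expect_error(scan_motif(c(a = "ACGT"), "ACGX"), "invalid IUPAC")

  # degenerate consensus vs naive scan on both strands
  s <- random_seq(2000, seed = 10)
  cons <- "RYSW"
  got <- scan_motif(stats::setNames(s, "z"), cons)
  want_f <- oracle_motif_scan(s, cons)
  want_r <- oracle_motif_scan(s, revcomp_chr(cons))
  # reduce() merges overlapping matches, so compare covered positions
  cover <- function(starts, len, merged) {
    pos <- sort(unique(unlist(lapply(starts, function(x) x + 0:(len - 1)))))
    got_pos <- sort(unique(unlist(mapply(
      function(a, b) a:(b - 1), merged$start, merged$end, SIMPLIFY = FALSE))))
    identical(pos, as.integer(got_pos))
  }
  expect_true(cover(want_f, 4L, got$sites[got$sites$strand == "+", ]))
  expect_true(cover(want_r, 4L, got$sites[got$sites$strand == "-", ]))

  # 8-mer site count on a random megabase within 3 sigma of expectation
  big <- random_seq(1e6, seed = 11)
  cons8 <- "ACGGTCAT"
  n_sites <- nrow(scan_motif(stats::setNames(big, "c"), cons8)$sites)
  expected <- 2 * (1e6 - 7) * 0.25^8
  expect_lt(abs(n_sites - expected), 3 * sqrt(expected))

  # inter-site distances: successive starts; sites at 2, 9, 15 per strand
  ms2 <- scan_motif(c(c1 = "AAACGTAAAACGTAAACGTA"), "ACGT")
  expect_equal(nrow(ms2$distances), nrow(ms2$sites) - 1L)
  by_strand <- ms2$distances_by_strand
  expect_equal(sort(by_strand$distance_bp[by_strand$strand == "+"]), c(6, 7))
  expect_equal(sort(by_strand$distance_bp[by_strand$strand == "-"]), c(6, 7))
})

test_that("expected DSB counts reproduce the published arithmetic", {
  d <- expected_dsb_count()
  expect_equal(d$low, 470)
  expect_equal(d$high, 860)
  # diploid genome: no ploidy scaling
  d2 <- expected_dsb_count(ploidy_factor = 2)
  expect_equal(d2$low, 300)
  expect_equal(d2$high, 550)
})

test_that("bedGraph and BED round-trips preserve tracks and peaks", {
  tr <- flat_track(withr::with_seed(12, stats::rpois(50, 5)))
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, bin_size = 10000L)
  expect_equal(back$value, tr$value)
  expect_equal(back$start, tr$start)

  pk <- tibble::tibble(chrom = "chr1", start = c(10L, 50L), end = c(20L, 60L),
                       name = c("a", "b"), score = c(1, 2), strand = c("+", "-"))
  pb <- withr::local_tempfile(fileext = ".bed")
  write_bed6(pk, pb)
  expect_equal(read_bed6(pb), pk)
})
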