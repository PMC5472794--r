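#' Build and validate an end-to-end run configuration
#'
#' Collects the parameters of every pipeline stage with their standard
#' defaults (39/125 nm voxels, focus threshold 1000, 0.001 um^3 minimum
#' object, 0.05 um^3 nominal split volume, 3-voxel shells, 500 nm
#' linkage cutoff, 10 kb bins, smoothing windows 1..25, ploidy factor
#' 3.12). Conditions are free labels, each simulating one nucleus and
#' one matched coverage track.
#'
#' @param out_dir Output directory for the run.
#' @param conditions Character vector of condition labels.
#' @param seed Integer master seed; per-condition seeds derive from it.
#' @param image Named list overriding [make_nucleus_image()] arguments.
#' @param segmentation Named list: `dapi_threshold`,
#'   `nucleus_min_volume_um3`, `focus_threshold`, `focus_min_volume_um3`,
#'   `nominal_volume_um3`, `shell_dilation_voxels`.
#' @param clustering Named list: `cutoff_nm`.
#' @param dna Named list passed to [dna_content_config()] (requires
#'   `genome_size_mbp`).
#' @param null_model Named list: `n_iter`.
#' @param genomics Named list: `genome_length`, `bin_size`, `n_domains`,
#'   `domain_bins`, `background_rate`, `enrichment_rate`,
#'   `ploidy_factor`, `w_range`.
#' @return A validated list of class `nf_config`.
#' @export
run_config <- function(out_dir,
                       conditions = c("unir", "0.5h", "3h", "24h"),
                       seed = 1L,
                       image = list(),
                       segmentation = list(),
                       clustering = list(),
                       dna = list(),
                       null_model = list(),
                       genomics = list()) {
  cfg <- list(
    out_dir = out_dir,
    conditions = conditions,
    seed = as.integer(seed),
    image = utils::modifyList(list(
      shape = c(160L, 160L, 48L), voxel_size_nm = c(39, 125),
      n_clusters = 5L, foci_per_cluster = 4L,
      intra_cluster_sigma_nm = 150, min_inter_cluster_nm = 2000,
      channels = c("dapi", "gh2ax", "ctcf")
    ), image),
    # the demo stack is a scaled-down nucleus (~20 um^3), so the volume
    # floor is scaled accordingly; for full-size stacks raise it to 200
    segmentation = utils::modifyList(list(
      dapi_threshold = 150, nucleus_min_volume_um3 = 5,
      focus_threshold = 1000, focus_min_volume_um3 = 0.001,
      nominal_volume_um3 = 0.05, shell_dilation_voxels = 3L
    ), segmentation),
    clustering = utils::modifyList(list(cutoff_nm = 500), clustering),
    dna = utils::modifyList(list(
      genome_size_mbp = 3.12 * 3095, ploidy_factor = 3.12, cell_cycle_factor = 1
    ), dna),
    null_model = utils::modifyList(list(n_iter = 100L), null_model),
    genomics = utils::modifyList(list(
      genome_length = 20000000L, bin_size = 10000L,
      n_domains = 20L, domain_bins = 5L,
      background_rate = 5, enrichment_rate = 50,
      ploidy_factor = 3.12, w_range = 1:25
    ), genomics)
  )
  validate_config(cfg)
  structure(cfg, class = "nf_config")
}

validate_config <- function(cfg) {
  if (cfg$clustering$cutoff_nm <= 0) {
    stop("invalid config: clustering$cutoff_nm must be > 0", call. = FALSE)
  }
  if (cfg$segmentation$focus_threshold <= 0) {
    stop("invalid config: segmentation$focus_threshold must be > 0", call. = FALSE)
  }
  if (cfg$dna$genome_size_mbp <= 0) {
    stop("invalid config: dna$genome_size_mbp must be > 0", call. = FALSE)
  }
  if (cfg$genomics$bin_size <= 0 || cfg$genomics$genome_length <= 0) {
    stop("invalid config: genomics sizes must be > 0", call. = FALSE)
  }
  if (length(cfg$conditions) == 0L) {
    stop("invalid config: at least one condition is required", call. = FALSE)
  }
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Executes, per condition: image simulation, nucleus segmentation,
#' focus detection and splitting, focus measurement, DNA content and
#' volume fraction, shells, clustering and cluster metrics, the
#' sphere Monte-Carlo null, track simulation, smoothing-factor matching
#' and domain calling, and boundary analysis of planted peaks. Every
#' output table is written to the run directory stamped with the config
#' hash; a provenance record lists per-stage counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run directory; side effect: stage outputs and
#'   `provenance.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nf_config"))
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  provenance <- list(config_hash = hash, conditions = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    cseed <- (config$seed * 1009L + ci * 9973L) %% .Machine$integer.max
    cond_dir <- file.path(config$out_dir, gsub("[^A-Za-z0-9._-]", "_", cond))
    dir.create(cond_dir, showWarnings = FALSE)

    sim <- stage("simulate", do.call(make_nucleus_image,
                                     c(config$image, list(seed = cseed))))
    seg <- config$segmentation
    nucleus <- stage("segment_nucleus", segment_nucleus(
      sim$stack, "dapi", threshold = seg$dapi_threshold,
      min_volume_um3 = seg$nucleus_min_volume_um3))
    labels <- stage("detect_foci", detect_foci(
      sim$stack, "gh2ax", nucleus,
      intensity_threshold = seg$focus_threshold,
      min_volume_um3 = seg$focus_min_volume_um3))
    labels <- stage("separate_touching", separate_touching(
      labels, sim$stack, nominal_volume_um3 = seg$nominal_volume_um3,
      min_volume_um3 = seg$focus_min_volume_um3))
    foci <- stage("foci_table", foci_table(labels, sim$stack, nucleus))
    dna_cfg <- do.call(dna_content_config, config$dna)
    foci <- stage("estimate_dna_content",
                  estimate_dna_content(foci, nucleus, dna_cfg))
    vf <- stage("volume_fraction", volume_fraction(foci, nucleus))
    shells <- stage("make_shells", make_shells(
      labels, seg$shell_dilation_voxels, nucleus))
    sstats <- stage("shell_stats", shell_stats(
      sim$stack, labels = labels, shells = shells))
    foci_cl <- stage("cluster_foci",
                     cluster_foci(foci, config$clustering$cutoff_nm))
    clusters <- stage("cluster_metrics", cluster_metrics(foci_cl))

    r_um <- (3 * nucleus$volume_um3 / (4 * pi))^(1 / 3)
    n_ctcf <- max(1L, nrow(foci))
    null <- stage("simulate_null", simulate_null(null_config(
      sphere_radius_um = r_um, n_query = max(1L, nrow(foci)),
      n_target = n_ctcf, n_iter = config$null_model$n_iter,
      seed = cseed)))

    gen <- config$genomics
    n_bins <- gen$genome_length %/% gen$bin_size
    gap <- n_bins %/% (gen$n_domains + 1L)
    dom_start <- (seq_len(gen$n_domains) * gap) * gen$bin_size
    truth <- stage("track_truth", track_truth(
      tibble::tibble(chrom = "chr1", start = dom_start,
                     end = dom_start + gen$domain_bins * gen$bin_size),
      background_rate = gen$background_rate,
      enrichment_rate = gen$enrichment_rate,
      seed = cseed))
    track <- stage("make_chipseq_track",
                   make_chipseq_track(gen$genome_length, gen$bin_size, truth))
    match <- stage("match_smoothing", match_smoothing(
      track, vf, n_nanofoci = max(1L, nrow(foci)),
      ploidy_factor = gen$ploidy_factor, w_range = gen$w_range))
    peaks <- stage("make_ctcf_peaks", make_ctcf_peaks(truth, seed = cseed))
    ctcf <- stage("ctcf_boundary_analysis",
                  ctcf_boundary_analysis(match$domains, peaks))

    write_table_tsv(foci_cl, file.path(cond_dir, "foci.tsv"), hash)
    write_table_tsv(clusters, file.path(cond_dir, "clusters.tsv"), hash)
    write_table_tsv(sstats, file.path(cond_dir, "shell_stats.tsv"), hash)
    write_table_tsv(match$domains, file.path(cond_dir, "domains.tsv"), hash)
    write_table_tsv(tidy(null), file.path(cond_dir, "null_medians.tsv"), hash)
    write_table_tsv(ctcf$boundaries, file.path(cond_dir, "ctcf_boundaries.tsv"),
                    hash)
    summary_row <- tibble::tibble(
      condition = cond,
      n_foci = nrow(foci),
      n_clusters = max(0L, if (nrow(foci_cl)) max(foci_cl$cluster) else 0L),
      median_foci_per_cluster = if (nrow(clusters)) {
        stats::median(clusters$n_foci)
      } else NA_real_,
      volume_fraction_pct = vf,
      chosen_w = match$chosen_w,
      n_domains = nrow(match$domains),
      nucleus_volume_um3 = nucleus$volume_um3
    )
    write_table_tsv(summary_row, file.path(cond_dir, "summary.tsv"), hash)
    provenance$conditions[[cond]] <- list(
      seed = cseed, n_foci = nrow(foci),
      n_clusters = summary_row$n_clusters,
      n_domains = nrow(match$domains)
    )
  }
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Summarise a completed pipeline run
#'
#' Reads the per-condition summary tables from a run directory; rows
#' for incomplete conditions carry `NA` fields.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return One summary row per condition (possibly empty).
#' @export
report_summary <- function(run_dir) {
  dirs <- list.dirs(run_dir, recursive = FALSE)
  rows <- lapply(dirs, function(d) {
    f <- file.path(d, "summary.tsv")
    if (file.exists(f)) {
      read_table_tsv(f)
    } else {
      tibble::tibble(condition = basename(d), n_foci = NA_integer_,
                     n_clusters = NA_integer_,
                     median_foci_per_cluster = NA_real_,
                     volume_fraction_pct = NA_real_, chosen_w = NA_integer_,
                     n_domains = NA_integer_,
                     nucleus_volume_um3 = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}
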