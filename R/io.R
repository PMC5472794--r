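#' Read and write binned tracks as bedGraph
#'
#' bedGraph is 0-based half-open `chrom start end value`, matching the
#' binned-track tibble directly.
#'
#' @param track Binned-track tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param bin_size Optional expected bin size; checked if given.
#' @export
read_bedgraph <- function(path, bin_size = NULL) {
  out <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "ciid", progress = FALSE)
  widths <- unique(out$end - out$start)
  if (!is.null(bin_size) && any(widths > bin_size)) {
    stop("bin widths exceed the declared `bin_size`", call. = FALSE)
  }
  attr(out, "bin_size") <- if (is.null(bin_size)) max(widths) else as.integer(bin_size)
  out
}

#' Read and write BED6 peak files
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing BED columns are filled with placeholders).
#' @param path File path.
#' @return Invisibly `path` (write) or a tibble (read).
#' @export
write_bed6 <- function(peaks, path) {
  out <- tibble::tibble(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
}

#' Write a table as TSV with a provenance comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config_hash Optional hash string recorded as a `# config:`
#'   comment line.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(x, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config: %s", config_hash), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}
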