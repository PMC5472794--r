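#' Scan a genome for an IUPAC consensus motif
#'
#' Matches the consensus on both strands (degenerate IUPAC codes
#' allowed), merges overlapping same-strand matches, and derives the
#' inter-site distance distribution (successive site starts per
#' chromosome), overall and stratified by orientation.
#'
#' @param genome A named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param iupac_consensus Consensus motif as an IUPAC string (supplied
#'   via configuration; not hard-coded).
#' @return An object of class `nf_motif`: `sites` tibble (`chrom`,
#'   `start` 0-based, `end`, `strand`), `distances` tibble (`chrom`,
#'   `distance_bp`, pooled strands) and `distances_by_strand`.
#' @export
scan_motif <- function(genome, iupac_consensus) {
  if (!is.character(iupac_consensus) || length(iupac_consensus) != 1L ||
      nchar(iupac_consensus) == 0L) {
    stop("`iupac_consensus` must be a single non-empty string", call. = FALSE)
  }
  bad <- setdiff(strsplit(toupper(iupac_consensus), "")[[1]],
                 strsplit("ACGTRYSWKMBDHVN", "")[[1]])
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  seqs <- if (inherits(genome, "DNAStringSet")) {
    genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    Biostrings::readDNAStringSet(genome)
  } else {
    Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  fwd_pat <- Biostrings::DNAString(toupper(iupac_consensus))
  rev_pat <- Biostrings::reverseComplement(fwd_pat)

  one_strand <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, seqs, fixed = FALSE)
    rows <- lapply(seq_along(hits), function(i) {
      r <- IRanges::reduce(hits[[i]])  # merge overlapping same-strand sites
      if (length(r) == 0L) return(NULL)
      df <- as.data.frame(r)
      tibble::tibble(chrom = names(seqs)[i],
                     start = df$start - 1L,
                     end = df$end,
                     strand = strand)
    })
    dplyr::bind_rows(rows)
  }
  sites <- dplyr::bind_rows(one_strand(fwd_pat, "+"),
                            one_strand(rev_pat, "-")) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)

  gap_tbl <- function(s) {
    s |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(distance_bp = .data$start - dplyr::lag(.data$start)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$distance_bp)) |>
      dplyr::select("chrom", "distance_bp")
  }
  distances <- gap_tbl(sites)
  by_strand <- sites |>
    dplyr::group_by(.data$strand) |>
    dplyr::group_modify(~ gap_tbl(.x)) |>
    dplyr::ungroup()

  structure(list(sites = sites, distances = distances,
                 distances_by_strand = by_strand,
                 consensus = toupper(iupac_consensus)),
            class = "nf_motif")
}

#' @export
print.nf_motif <- function(x, ...) {
  cat(sprintf("<nf_motif> '%s': %d sites", x$consensus, nrow(x$sites)))
  if (nrow(x$distances) > 0L) {
    q <- stats::quantile(x$distances$distance_bp, c(0.25, 0.5, 0.75),
                         names = FALSE)
    cat(sprintf(", inter-site median %.0f bp (IQD %.0f-%.0f)", q[2], q[1], q[3]))
  }
  cat("\n")
  invisible(x)
}
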