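#' Extract gap-flanking sequences
#'
#' For each gap the up-to-`flank` bases immediately left and right of the
#' N-run are extracted verbatim (case preserved). Flanks are truncated at
#' sequence bounds and at the edge of an adjacent gap in `gaps`, so a
#' flank never reaches into a neighbouring annotated N-run; a side of
#' length zero is flagged unevaluable (`left_ok`/`right_ok` = FALSE).
#'
#' @param assembly an assembly tibble.
#' @param gaps a gap tibble from [find_gaps()] or [load_gaps_bed()].
#' @param flank maximum flank length F in bp (default 10000).
#' @return a flank tibble with the gap coordinates, per-side intervals
#'   (`left_start`..`right_end`), sequences, lengths and evaluability
#'   flags.
#' @export
extract_flanks <- function(assembly, gaps, flank = 10000) {
  stopifnot(flank >= 1)
  lens <- seq_lengths(assembly)
  gaps <- gaps %>%
    dplyr::arrange(.data$seq_id, .data$start) %>%
    dplyr::left_join(lens, by = "seq_id") %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::mutate(prev_end = dplyr::lag(.data$end, default = 0L),
                  next_start = dplyr::lead(.data$start),
                  next_start = dplyr::coalesce(.data$next_start, .data$length)) %>%
    dplyr::ungroup()
  out <- gaps %>%
    dplyr::mutate(
      left_start = pmax(.data$start - flank, .data$prev_end),
      left_end = .data$start,
      right_start = .data$end,
      right_end = pmin(.data$end + flank, .data$next_start),
      left_len = .data$left_end - .data$left_start,
      right_len = .data$right_end - .data$right_start,
      left_truncated = .data$left_len < flank,
      right_truncated = .data$right_len < flank,
      left_ok = .data$left_len > 0L,
      right_ok = .data$right_len > 0L
    )
  out$left_seq <- purrr::map_chr(seq_len(nrow(out)), function(i)
    seq_slice(assembly, out$seq_id[i], out$left_start[i], out$left_end[i]))
  out$right_seq <- purrr::map_chr(seq_len(nrow(out)), function(i)
    seq_slice(assembly, out$seq_id[i], out$right_start[i], out$right_end[i]))
  out %>%
    dplyr::transmute(
      gap_id = .data$gap_id, seq_id = .data$seq_id,
      gap_start = .data$start, gap_end = .data$end,
      n_length = .data$n_length,
      left_start = .data$left_start, left_end = .data$left_end,
      left_len = .data$left_len, left_seq = .data$left_seq,
      left_truncated = .data$left_truncated, left_ok = .data$left_ok,
      right_start = .data$right_start, right_end = .data$right_end,
      right_len = .data$right_len, right_seq = .data$right_seq,
      right_truncated = .data$right_truncated, right_ok = .data$right_ok,
      flank = flank
    )
}

#' Write flank sequences to FASTA for an external aligner
#'
#' Headers follow the `<gap_id>|L` / `<gap_id>|R` naming scheme that
#' [read_coords()] parses back.
#'
#' @param flanks a flank tibble from [extract_flanks()].
#' @param path output FASTA.
#' @param line_width bases per line.
#' @return `path`, invisibly.
#' @export
write_flank_fasta <- function(flanks, path, line_width = 60) {
  ids <- character(0); seqs <- character(0)
  for (i in seq_len(nrow(flanks))) {
    if (flanks$left_ok[i]) {
      ids <- c(ids, paste0(flanks$gap_id[i], "|L"))
      seqs <- c(seqs, flanks$left_seq[i])
    }
    if (flanks$right_ok[i]) {
      ids <- c(ids, paste0(flanks$gap_id[i], "|R"))
      seqs <- c(seqs, flanks$right_seq[i])
    }
  }
  write_fasta(tibble::tibble(seq_id = ids, header = ids, sequence = seqs),
              path, line_width = line_width)
}
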