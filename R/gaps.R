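#' Find assembly gaps as maximal N-runs
#'
#' Scans each sequence for maximal runs of `N`/`n` of at least `min_len`
#' bases. Runs touching a sequence end are kept but flagged `terminal`
#' (their missing flank makes them unevaluable for closure). The scan is
#' run-length based, case-insensitive, and idempotent.
#'
#' @param assembly an assembly tibble.
#' @param min_len minimum run length to report (default 10; single stray
#'   Ns are usually ambiguity calls, not assembly gaps).
#' @return a gap tibble with columns `gap_id` (`seqid:start-end`),
#'   `seq_id`, `start`, `end`, `n_length`, `terminal`, sorted by
#'   (`seq_id`, `start`).
#' @examples
#' find_gaps(assembly(c(a = "ACGTNNNNNACGT")), min_len = 1)
#' @export
find_gaps <- function(assembly, min_len = 10) {
  stopifnot(min_len >= 1)
  out <- purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    s <- assembly$sequence[i]
    n <- nchar(s)
    if (n == 0) return(NULL)
    r <- charToRaw(s)
    is_n <- r == as.raw(78L) | r == as.raw(110L)
    runs <- rle(as.vector(is_n))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    keep <- runs$values & runs$lengths >= min_len
    if (!any(keep)) return(NULL)
    tibble::tibble(seq_id = assembly$seq_id[i],
                   start = starts[keep], end = ends[keep],
                   terminal = starts[keep] == 0L | ends[keep] == n)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(gap_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          n_length = integer(), terminal = logical()))
  }
  out %>%
    dplyr::arrange(.data$seq_id, .data$start) %>%
    dplyr::mutate(gap_id = sprintf("%s:%d-%d", .data$seq_id, .data$start, .data$end),
                  n_length = .data$end - .data$start) %>%
    dplyr::select("gap_id", "seq_id", "start", "end", "n_length", "terminal")
}

#' Load gap intervals from a BED3 file
#'
#' Each interval is validated (unless `verify = FALSE`) to contain only
#' N/n bases in the assembly, so externally annotated gap sets cannot
#' silently disagree with the sequence.
#'
#' @param path BED3 file of gap intervals (0-based half-open).
#' @param assembly the assembly the gaps belong to.
#' @param verify check that every interval is all-N (default TRUE).
#' @return a gap tibble as from [find_gaps()].
#' @export
load_gaps_bed <- function(path, assembly, verify = TRUE) {
  bed <- read_bed(path)
  lens <- seq_lengths(assembly)
  bed <- dplyr::left_join(bed, lens, by = "seq_id")
  if (any(is.na(bed$length))) {
    abort(paste0("gap BED names unknown sequence(s): ",
                 paste(unique(bed$seq_id[is.na(bed$length)]), collapse = ", ")))
  }
  if (any(bed$start < 0 | bed$end > bed$length | bed$start >= bed$end)) {
    abort("gap BED contains out-of-bounds or empty intervals")
  }
  if (verify) {
    bad <- purrr::map_lgl(seq_len(nrow(bed)), function(i) {
      grepl("[^Nn]", seq_slice(assembly, bed$seq_id[i], bed$start[i], bed$end[i]))
    })
    if (any(bad)) {
      offenders <- sprintf("%s:%d-%d", bed$seq_id[bad], bed$start[bad], bed$end[bad])
      abort(paste0("gap interval(s) contain non-N bases: ",
                   paste(offenders, collapse = ", ")))
    }
  }
  bed %>%
    dplyr::arrange(.data$seq_id, .data$start) %>%
    dplyr::mutate(gap_id = sprintf("%s:%d-%d", .data$seq_id, .data$start, .data$end),
                  n_length = .data$end - .data$start,
                  terminal = .data$start == 0L | .data$end == .data$length) %>%
    dplyr::select("gap_id", "seq_id", "start", "end", "n_length", "terminal")
}

#' Write gaps to BED3
#'
#' @param gaps a gap tibble.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_gaps_bed <- function(gaps, path) {
  write_bed(dplyr::select(gaps, "seq_id", "start", "end"), path)
}

#' Summarize gaps per sequence and assembly-wide
#'
#' @param gaps a gap tibble.
#' @param assembly the assembly the gaps were found in (supplies the full
#'   sequence universe so gap-free sequences report zeros).
#' @return a tibble with one row per sequence (`seq_id`, `n_gaps`,
#'   `gap_bp`); assembly-wide totals are available via [glance()].
#' @export
gap_summary <- function(gaps, assembly) {
  per <- gaps %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::summarise(n_gaps = dplyr::n(), gap_bp = sum(.data$n_length),
                     .groups = "drop")
  out <- tibble::tibble(seq_id = assembly$seq_id) %>%
    dplyr::left_join(per, by = "seq_id") %>%
    dplyr::mutate(n_gaps = dplyr::coalesce(.data$n_gaps, 0L),
                  gap_bp = dplyr::coalesce(.data$gap_bp, 0L))
  class(out) <- c("gap_report", class(out))
  out
}

#' @exportS3Method generics::glance
glance.gap_report <- function(x, ...) {
  tibble::tibble(n_sequences = nrow(x),
                 n_gaps = sum(x$n_gaps),
                 gap_bp = sum(x$gap_bp))
}

#' Write a gap report TSV (1-based human-readable totals row included)
#'
#' @param report a gap report from [gap_summary()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path) {
  tot <- glance(report)
  out <- dplyr::bind_rows(
    tibble::as_tibble(report),
    tibble::tibble(seq_id = "Total", n_gaps = tot$n_gaps, gap_bp = tot$gap_bp)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
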