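#' Merge genomic intervals
#'
#' Collapses a set of 0-based half-open intervals into their sorted,
#' pairwise-disjoint, union-preserving form. If a `seq_id` column is
#' present intervals are merged per sequence; abutting intervals
#' (`end == next start`) are merged.
#'
#' @param intervals tibble with columns `start`, `end` and optionally
#'   `seq_id`.
#' @return tibble with the same columns, merged.
#' @examples
#' merge_intervals(tibble::tibble(start = c(0, 40), end = c(60, 100)))
#' @export
merge_intervals <- function(intervals) {
  has_seq <- "seq_id" %in% names(intervals)
  if (nrow(intervals) == 0) {
    out <- tibble::tibble(start = integer(), end = integer())
    if (has_seq) out <- tibble::add_column(out, seq_id = character(), .before = 1)
    return(out)
  }
  stopifnot(all(intervals$start < intervals$end))
  key <- if (has_seq) intervals$seq_id else rep("all", nrow(intervals))
  parts <- split(intervals, key)
  out <- purrr::map2_dfr(parts, names(parts), function(p, k) {
    r <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    res <- tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    if (has_seq) res <- tibble::add_column(res, seq_id = k, .before = 1)
    res
  })
  if (has_seq) dplyr::arrange(out, .data$seq_id, .data$start) else
    dplyr::arrange(out, .data$start)
}

# total bp in the union of intervals (merged internally)
union_length <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' Columns beyond the sixth are ignored.
#'
#' @param path BED3/BED6 file.
#' @return tibble with `seq_id`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  g <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g)
  )
  if (!is.null(g$name) && !all(is.na(g$name))) out$name <- g$name
  if (!is.null(g$score) && !all(is.na(g$score))) out$score <- g$score
  st <- as.character(GenomicRanges::strand(g))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to BED
#'
#' @param intervals tibble with `seq_id`, `start`, `end`, optionally
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  g <- GenomicRanges::GRanges(
    seqnames = intervals$seq_id,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*"
  )
  if ("name" %in% names(intervals)) g$name <- intervals$name
  if ("score" %in% names(intervals)) g$score <- intervals$score
  rtracklayer::export(g, path, format = "bed")
  invisible(path)
}
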