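#' Lengths of contigs connected during scaffolding
#'
#' A contig counts as "connected" iff its scaffold contains at least two
#' contig components. Lengths are contig-coordinate spans
#' (`component_end - component_start`).
#'
#' @param layout a scaffold-layout tibble from [read_agp()].
#' @return tibble `scaffold`, `component_id`, `length`.
#' @export
connected_contig_lengths <- function(layout) {
  contigs <- layout[layout$type == "contig", ]
  multi <- contigs %>%
    dplyr::count(.data$scaffold) %>%
    dplyr::filter(.data$n >= 2) %>%
    dplyr::pull("scaffold")
  contigs %>%
    dplyr::filter(.data$scaffold %in% multi) %>%
    dplyr::transmute(scaffold = .data$scaffold,
                     component_id = .data$component_id,
                     length = .data$component_end - .data$component_start)
}

#' Load mate-pair records and filter to plausible pairs
#'
#' Accepts a pair-table tibble or TSV path with columns `seq1`, `start1`,
#' `end1`, `strand1`, `seq2`, `start2`, `end2`, `strand2` (0-based
#' half-open mate intervals). Pairs are kept when both mates map to one
#' sequence, the outer span length lies within `[insert_min, insert_max]`,
#' and (if `require_orientation`) the mates point at each other from
#' opposite strands. Discards are tallied per reason in the `discarded`
#' attribute.
#'
#' @param pairs tibble or TSV path.
#' @param insert_min,insert_max outer-span bounds in bp; the defaults
#'   (5000, 25000) bracket a 10-15 kb mate-pair library.
#' @param require_orientation demand opposite-strand, inward/outward
#'   consistent mates (default FALSE for pair tables, which are usually
#'   pre-filtered).
#' @return tibble `seq_id`, `outer_start`, `outer_end`, `span_len`,
#'   `orientation_ok`; attribute `discarded` is a reason/count tibble.
#' @export
load_pairs <- function(pairs, insert_min = 5000, insert_max = 25000,
                       require_orientation = FALSE) {
  if (is.character(pairs)) {
    pairs <- readr::read_tsv(pairs, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("seq1", "start1", "end1", "strand1",
            "seq2", "start2", "end2", "strand2")
  if (!all(need %in% names(pairs))) {
    abort(paste0("pair table must have columns: ", paste(need, collapse = ", ")))
  }
  outer_start <- pmin(pairs$start1, pairs$start2)
  outer_end <- pmax(pairs$end1, pairs$end2)
  span <- outer_end - outer_start
  orientation_ok <- pairs$strand1 != pairs$strand2
  reason <- dplyr::case_when(
    pairs$seq1 != pairs$seq2 ~ "cross-sequence",
    span < insert_min ~ "span-too-short",
    span > insert_max ~ "span-too-long",
    require_orientation & !orientation_ok ~ "bad-orientation",
    TRUE ~ "kept"
  )
  kept <- tibble::tibble(seq_id = pairs$seq1,
                         outer_start = outer_start,
                         outer_end = outer_end,
                         span_len = span,
                         orientation_ok = orientation_ok)[reason == "kept", ]
  tab <- table(reason[reason != "kept"])
  disc <- tibble::tibble(reason = names(tab), n = as.integer(tab))
  attr(kept, "discarded") <- disc
  kept
}

#' Load mate pairs from a SAM/BAM file
#'
#' Mates are joined by read name; the outer span is the smallest interval
#' containing both mates. Unpaired records are counted and skipped.
#' Orientation filtering defaults to on for SAM/BAM input.
#'
#' @param path SAM or BAM file.
#' @inheritParams load_pairs
#' @return as [load_pairs()].
#' @export
load_pairs_sam <- function(path, insert_min = 5000, insert_max = 25000,
                           require_orientation = TRUE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required for SAM/BAM input")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand")))[[1]]
  reads <- tibble::tibble(qname = b$qname, seq = as.character(b$rname),
                          start = b$pos - 1L, end = b$pos - 1L + b$qwidth,
                          strand = as.character(b$strand)) %>%
    dplyr::filter(!is.na(.data$start))
  paired <- reads %>%
    dplyr::group_by(.data$qname) %>%
    dplyr::filter(dplyr::n() == 2) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::summarise(seq1 = dplyr::first(.data$seq), seq2 = dplyr::last(.data$seq),
                     start1 = dplyr::first(.data$start), end1 = dplyr::first(.data$end),
                     start2 = dplyr::last(.data$start), end2 = dplyr::last(.data$end),
                     strand1 = dplyr::first(.data$strand),
                     strand2 = dplyr::last(.data$strand), .groups = "drop")
  n_unpaired <- length(unique(reads$qname)) - nrow(paired)
  out <- load_pairs(paired, insert_min = insert_min, insert_max = insert_max,
                    require_orientation = require_orientation)
  attr(out, "discarded") <- dplyr::bind_rows(
    attr(out, "discarded"),
    tibble::tibble(reason = "unpaired", n = n_unpaired))
  out
}

#' Physical (fragment) coverage at assembly gaps
#'
#' Physical depth at a position is the number of mate-pair outer spans
#' containing it (computed with a difference array and prefix sums). The
#' per-gap statistic is the mean depth over the gap interval (or the
#' depth at the gap midpoint with `stat = "midpoint"`); with
#' `span_whole_gap = TRUE` it is instead the count of pairs whose span
#' contains the whole gap.
#'
#' @param pairs a pair tibble from [load_pairs()].
#' @param gaps gap intervals (`seq_id`, `start`, `end`), e.g. AGP gap
#'   components or a gap BED.
#' @param seq_lengths tibble (`seq_id`, `length`) for the sequence
#'   universe.
#' @param stat `"mean"` (default) or `"midpoint"`.
#' @param span_whole_gap require spans to contain the entire gap.
#' @return the gap tibble with a `coverage` column; gaps on sequences
#'   with no pairs get coverage 0 with a warning.
#' @export
physical_coverage_at_gaps <- function(pairs, gaps, seq_lengths,
                                      stat = c("mean", "midpoint"),
                                      span_whole_gap = FALSE) {
  stat <- match.arg(stat)
  missing_seq <- setdiff(unique(gaps$seq_id), unique(pairs$seq_id))
  if (length(missing_seq) > 0) {
    warn(paste0("no pairs on sequence(s): ",
                paste(missing_seq, collapse = ", "), "; coverage 0"))
  }
  gaps$coverage <- 0
  for (sid in unique(gaps$seq_id)) {
    gi <- which(gaps$seq_id == sid)
    p <- pairs[pairs$seq_id == sid, ]
    if (nrow(p) == 0) next
    if (span_whole_gap) {
      gaps$coverage[gi] <- purrr::map_dbl(gi, function(i) {
        sum(p$outer_start <= gaps$start[i] & p$outer_end >= gaps$end[i])
      })
      next
    }
    len <- seq_lengths$length[seq_lengths$seq_id == sid]
    if (length(len) == 0) abort(paste0("no length for sequence ", sid))
    d <- numeric(len + 1L)
    adds <- table(p$outer_start + 1L)
    subs <- table(pmin(p$outer_end, len) + 1L)
    d[as.integer(names(adds))] <- d[as.integer(names(adds))] + as.numeric(adds)
    d[as.integer(names(subs))] <- d[as.integer(names(subs))] - as.numeric(subs)
    depth_prefix <- c(0, cumsum(cumsum(d[seq_len(len)])))
    for (i in gi) {
      if (stat == "mean") {
        gaps$coverage[i] <- (depth_prefix[gaps$end[i] + 1L] -
                               depth_prefix[gaps$start[i] + 1L]) /
          (gaps$end[i] - gaps$start[i])
      } else {
        mid <- floor((gaps$start[i] + gaps$end[i]) / 2)
        gaps$coverage[i] <- depth_prefix[mid + 2L] - depth_prefix[mid + 1L]
      }
    }
  }
  gaps
}

#' Genome-wide mean physical coverage
#'
#' Conservation identity: total outer-span length divided by total
#' sequence length.
#'
#' @param pairs a pair tibble from [load_pairs()].
#' @param seq_lengths tibble (`seq_id`, `length`).
#' @return a single number.
#' @export
physical_coverage_mean <- function(pairs, seq_lengths) {
  sum(pairs$span_len) / sum(seq_lengths$length)
}
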