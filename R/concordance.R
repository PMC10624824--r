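#' Count matched and mismatched bases in pairwise alignment blocks
#'
#' Walks every alignment column of every block. Columns with a gap in
#' either row are skipped entirely (the "Total" of a match/mismatch table
#' is match + mismatch, so indel columns are never in the denominator);
#' bases match case-insensitively; a column involving N counts as a
#' mismatch unless `skip_n = TRUE`, in which case it is skipped.
#'
#' Blocks are counted as given. Overlapping blocks on the grouping side
#' raise a warning; `dedup = TRUE` first greedily keeps a non-overlapping
#' subset by A-side coordinates.
#'
#' @param blocks a block tibble from [read_maf_blocks()].
#' @param group_by which side's sequence names to aggregate by
#'   (`"a"` or `"b"`).
#' @param skip_n skip N-containing columns instead of counting them as
#'   mismatches.
#' @param dedup greedily drop blocks overlapping an earlier block on the
#'   A side before counting.
#' @return a `match_stats` tibble: `seq_id`, `match`, `mismatch`,
#'   `ratio` (= match / (match + mismatch)); assembly-wide totals via
#'   [glance()].
#' @export
count_match_mismatch <- function(blocks, group_by = c("a", "b"),
                                 skip_n = FALSE, dedup = FALSE) {
  group_by <- match.arg(group_by)
  if (nrow(blocks) > 0) {
    iv <- tibble::tibble(seq_id = blocks$a_seq, start = blocks$a_start,
                         end = blocks$a_end)
    if (dedup) {
      keep <- logical(nrow(iv))
      last_end <- list()
      ord <- order(iv$seq_id, iv$start)
      for (i in ord) {
        prev <- last_end[[iv$seq_id[i]]]
        if (is.null(prev) || iv$start[i] >= prev) {
          keep[i] <- TRUE
          last_end[[iv$seq_id[i]]] <- iv$end[i]
        }
      }
      blocks <- blocks[keep, ]
    } else if (union_length(iv) < sum(iv$end - iv$start)) {
      warn("alignment blocks overlap on the A side; columns are counted as given (see dedup)")
    }
  }
  counts <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    a <- charToRaw(toupper(blocks$a_text[i]))
    b <- charToRaw(toupper(blocks$b_text[i]))
    gap <- as.raw(45L)  # '-'
    nn <- as.raw(78L)   # 'N'
    use <- a != gap & b != gap
    if (skip_n) use <- use & a != nn & b != nn
    m <- sum(use & a == b & a != nn & b != nn)
    tibble::tibble(
      seq_id = if (group_by == "a") blocks$a_seq[i] else blocks$b_seq[i],
      match = m,
      mismatch = sum(use) - m
    )
  })
  if (nrow(counts) == 0) {
    counts <- tibble::tibble(seq_id = character(), match = numeric(),
                             mismatch = numeric())
  }
  out <- counts %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::summarise(match = sum(.data$match), mismatch = sum(.data$mismatch),
                     .groups = "drop") %>%
    dplyr::mutate(ratio = .data$match / (.data$match + .data$mismatch))
  class(out) <- c("match_stats", class(out))
  out
}

#' @exportS3Method generics::glance
glance.match_stats <- function(x, ...) {
  m <- sum(x$match); mm <- sum(x$mismatch)
  tibble::tibble(match = m, mismatch = mm,
                 ratio = if (m + mm > 0) m / (m + mm) else NA_real_)
}

#' Synteny coverage of a genome
#'
#' Fraction of the genome covered by the union of synteny-block
#' intervals: merged-union length divided by the genome size.
#'
#' @param x a block tibble from [read_maf_blocks()] or a plain interval
#'   tibble with `start`/`end` (and optionally `seq_id`).
#' @param genome_size total genome size in bp (> 0).
#' @param side which side of a block tibble to use (`"a"` or `"b"`).
#' @return the covered fraction, in `[0, 1]`.
#' @export
synteny_coverage <- function(x, genome_size, side = c("a", "b")) {
  stopifnot(genome_size > 0)
  side <- match.arg(side)
  iv <- if (all(c("start", "end") %in% names(x))) {
    x
  } else {
    tibble::tibble(seq_id = x[[paste0(side, "_seq")]],
                   start = x[[paste0(side, "_start")]],
                   end = x[[paste0(side, "_end")]])
  }
  if (nrow(iv) > 0 && any(iv$end > genome_size)) {
    abort("interval end exceeds genome size")
  }
  union_length(iv) / genome_size
}

#' Write a per-chromosome concordance table
#'
#' One row per sequence plus a `Total` row, columns `Chromosome`,
#' `Match`, `Mismatch`, `Match/Total`, with ratios formatted to a fixed
#' number of decimals.
#'
#' @param stats a `match_stats` tibble (or any tibble with `seq_id`,
#'   `match`, `mismatch`).
#' @param path output TSV.
#' @param digits decimals for the ratio column (default 3).
#' @return the formatted tibble that was written, invisibly.
#' @export
write_concordance_table <- function(stats, path, digits = 3) {
  fmt <- function(m, mm) {
    as.character(ifelse(m + mm > 0,
                        sprintf(paste0("%.", digits, "f"), m / (m + mm)), ""))
  }
  body <- tibble::tibble(
    Chromosome = as.character(stats$seq_id),
    Match = stats$match, Mismatch = stats$mismatch,
    `Match/Total` = fmt(stats$match, stats$mismatch)
  )
  total <- tibble::tibble(
    Chromosome = "Total",
    Match = sum(stats$match), Mismatch = sum(stats$mismatch),
    `Match/Total` = fmt(sum(stats$match), sum(stats$mismatch))
  )
  out <- dplyr::bind_rows(body, total)
  readr::write_tsv(out, path)
  invisible(out)
}
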