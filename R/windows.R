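#' Windowed repeat ratios
#'
#' Tiles every sequence with non-overlapping windows of length `window`
#' starting at 0 and computes the repeat ratio of each window: repeat
#' bases (soft-masked lowercase, or bases covered by a repeat-annotation
#' BED) divided by non-N bases. Terminal partial windows shorter than
#' `window / 2` are dropped, as are windows with no non-N bases.
#'
#' @param assembly an assembly tibble (case preserved; lowercase =
#'   soft-masked repeat).
#' @param window window length W in bp (default 50000).
#' @param repeat_bed optional repeat-annotation interval tibble
#'   (`seq_id`, `start`, `end`); when given it replaces the soft-mask as
#'   the repeat source.
#' @return tibble `seq_id`, `start`, `end`, `repeat_bases`,
#'   `non_n_bases`, `ratio`.
#' @export
window_repeat_ratios <- function(assembly, window = 50000, repeat_bed = NULL) {
  stopifnot(window >= 1)
  if (!is.null(repeat_bed)) repeat_bed <- merge_intervals(repeat_bed)
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    s <- assembly$sequence[i]
    n <- nchar(s)
    if (n == 0) return(NULL)
    r <- charToRaw(s)
    is_n <- r == as.raw(78L) | r == as.raw(110L)
    if (is.null(repeat_bed)) {
      is_rep <- r >= as.raw(97L) & r <= as.raw(122L) & !is_n
    } else {
      is_rep <- rep(FALSE, n)
      rb <- repeat_bed[repeat_bed$seq_id == assembly$seq_id[i], , drop = FALSE]
      for (j in seq_len(nrow(rb))) {
        is_rep[(rb$start[j] + 1L):rb$end[j]] <- TRUE
      }
      is_rep <- is_rep & !is_n
    }
    starts <- seq(0L, n - 1L, by = window)
    ends <- pmin(starts + window, n)
    keep <- (ends - starts) >= window / 2
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) return(NULL)
    cs_n <- c(0, cumsum(!is_n))
    cs_rep <- c(0, cumsum(is_rep))
    non_n <- cs_n[ends + 1L] - cs_n[starts + 1L]
    reps <- cs_rep[ends + 1L] - cs_rep[starts + 1L]
    out <- tibble::tibble(seq_id = assembly$seq_id[i],
                          start = starts, end = ends,
                          repeat_bases = reps, non_n_bases = non_n,
                          ratio = ifelse(non_n > 0, reps / non_n, NA_real_))
    out[out$non_n_bases > 0, ]
  })
}

#' Compare repeat ratios between closed-gap windows and the rest
#'
#' Windows are assigned to the closed-gap group when they overlap any
#' closed-gap interval by at least 1 bp; the two groups' repeat ratios
#' are compared with the two-sided Mann-Whitney U test ([mwu_test()]).
#'
#' @param windows a window tibble from [window_repeat_ratios()].
#' @param closed_gaps interval tibble of closed-gap regions (`seq_id`,
#'   `start`, `end`), in the same coordinates as the windows.
#' @return an `mwu_test` with the closed-gap group as `x`, plus a
#'   `windows` attribute carrying the group assignment.
#' @export
compare_window_groups <- function(windows, closed_gaps) {
  in_gap <- rep(FALSE, nrow(windows))
  for (sid in unique(closed_gaps$seq_id)) {
    g <- closed_gaps[closed_gaps$seq_id == sid, ]
    w <- which(windows$seq_id == sid)
    if (length(w) == 0) next
    ir_w <- IRanges::IRanges(start = windows$start[w] + 1L, end = windows$end[w])
    ir_g <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    in_gap[w] <- IRanges::overlapsAny(ir_w, ir_g)
  }
  if (!any(in_gap) || all(in_gap)) {
    abort("both window groups (closed-gap / other) must be non-empty")
  }
  res <- mwu_test(windows$ratio[in_gap], windows$ratio[!in_gap])
  attr(res, "windows") <- dplyr::mutate(
    windows, group = ifelse(in_gap, "closed-gap", "other"))
  res
}
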