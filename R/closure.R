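#' Closure thresholds
#'
#' The four closure criteria a gap must pass:
#' \describe{
#'   \item{c1}{each flank's chosen alignment covers strictly more than
#'     `min_aln_len` bp of the flank;}
#'   \item{c2}{the mean of the two chosen alignments' percent identities
#'     is strictly greater than `min_mean_identity`;}
#'   \item{c3}{both flanks place on the same donor sequence, same strand,
#'     in the donor order consistent with their target order;}
#'   \item{c4}{the donor bases under both chosen alignments contain no N.}
#' }
#' Both inequalities are strict: an alignment of exactly `min_aln_len`
#' bp, or a mean identity exactly at the threshold, fails.
#'
#' @param min_aln_len minimum per-flank alignment length, bp (default 5000).
#' @param min_mean_identity minimum mean percent identity (default 90).
#' @param require_fill_n_free also reject closures whose fill sequence
#'   contains N (default FALSE: c4 checks only the aligned donor bases).
#' @param max_overlap largest tolerated negative fill in bp when the two
#'   flank placements overlap in the donor (default 0: any positive
#'   overlap rejects).
#' @return a `closure_thresholds` list.
#' @export
closure_thresholds <- function(min_aln_len = 5000, min_mean_identity = 90,
                               require_fill_n_free = FALSE, max_overlap = 0) {
  stopifnot(min_aln_len >= 0, min_mean_identity >= 0, min_mean_identity <= 100,
            max_overlap >= 0)
  structure(list(min_aln_len = min_aln_len,
                 min_mean_identity = min_mean_identity,
                 require_fill_n_free = require_fill_n_free,
                 max_overlap = max_overlap),
            class = "closure_thresholds")
}

chosen_cols <- c("donor_seq_id", "donor_start", "donor_end", "strand",
                 "query_start", "query_end", "pct_identity", "align_len_query")

#' Evaluate the four closure criteria for every gap
#'
#' For each gap the best alignment per flank is chosen with
#' [best_alignment()], the four criteria are evaluated, and a decision row
#' is emitted. A gap is `unevaluable` when either flank was flagged at
#' extraction or has no alignment at all; otherwise it is `closed` iff
#' c1--c4 all hold, else `rejected`.
#'
#' @param flanks a flank tibble from [extract_flanks()].
#' @param alignments an alignment tibble from [align_flanks()] or
#'   [read_coords()].
#' @param donor the donor assembly (needed by c4, which inspects the
#'   donor bases under the chosen alignments).
#' @param thresholds a [closure_thresholds()] object.
#' @return a decision tibble: gap coordinates, `status`, criteria
#'   `c1`..`c4`, `reason`, and the chosen left/right alignment fields
#'   (`left_*`, `right_*`).
#' @export
evaluate_gaps <- function(flanks, alignments, donor,
                          thresholds = closure_thresholds()) {
  best <- best_alignment(alignments)
  donor_lookup <- setNames(donor$sequence, donor$seq_id)
  purrr::map_dfr(seq_len(nrow(flanks)), function(i) {
    fl <- flanks[i, ]
    la <- best[best$gap_id == fl$gap_id & best$flank_role == "left", ]
    ra <- best[best$gap_id == fl$gap_id & best$flank_role == "right", ]
    base <- tibble::tibble(gap_id = fl$gap_id, seq_id = fl$seq_id,
                           gap_start = fl$gap_start, gap_end = fl$gap_end,
                           n_length = fl$n_length)
    empty_side <- function(prefix) {
      v <- tibble::tibble(donor_seq_id = NA_character_, donor_start = NA_integer_,
                          donor_end = NA_integer_, strand = NA_character_,
                          query_start = NA_integer_, query_end = NA_integer_,
                          pct_identity = NA_real_, align_len_query = NA_integer_)
      setNames(v, paste0(prefix, names(v)))
    }
    side <- function(a, prefix) {
      if (nrow(a) == 0) return(empty_side(prefix))
      setNames(a[, chosen_cols], paste0(prefix, chosen_cols))
    }
    if (!fl$left_ok || !fl$right_ok || nrow(la) == 0 || nrow(ra) == 0) {
      return(dplyr::bind_cols(
        base,
        tibble::tibble(status = "unevaluable",
                       c1 = NA, c2 = NA, c3 = NA, c4 = NA,
                       reason = if (!fl$left_ok || !fl$right_ok)
                         "missing-flank" else "no-alignment"),
        side(la, "left_"), side(ra, "right_")))
    }
    c1 <- la$align_len_query > thresholds$min_aln_len &&
      ra$align_len_query > thresholds$min_aln_len
    c2 <- mean(c(la$pct_identity, ra$pct_identity)) > thresholds$min_mean_identity
    same_seq <- la$donor_seq_id == ra$donor_seq_id
    same_strand <- la$strand == ra$strand
    ordered_ok <- same_seq && same_strand &&
      ((la$strand == "+" && la$donor_end <= ra$donor_start) ||
         (la$strand == "-" && ra$donor_end <= la$donor_start))
    c3 <- same_seq && same_strand && ordered_ok
    dseq_l <- donor_lookup[[la$donor_seq_id]]
    dseq_r <- donor_lookup[[ra$donor_seq_id]]
    has_n <- function(s, from, to) {
      grepl("[Nn]", substr(s, from + 1L, to))
    }
    c4 <- !has_n(dseq_l, la$donor_start, la$donor_end) &&
      !has_n(dseq_r, ra$donor_start, ra$donor_end)
    closed <- c1 && c2 && c3 && c4
    reason <- if (closed) NA_character_ else
      paste0("criteria:", paste0(c("c1", "c2", "c3", "c4")[!c(c1, c2, c3, c4)],
                                 collapse = ","))
    dplyr::bind_cols(
      base,
      tibble::tibble(status = ifelse(closed, "closed", "rejected"),
                     c1 = c1, c2 = c2, c3 = c3, c4 = c4, reason = reason),
      side(la, "left_"), side(ra, "right_"))
  })
}

#' Derive fill sequences for closed gaps
#'
#' The fill is the donor interval between the two placed flanks: each
#' chosen alignment's gap-proximal end is projected into the donor and
#' extended by its unaligned gap-proximal flank tail (tail bases are
#' target sequence and must not be represented twice). On the minus
#' strand the fill is reverse complemented. When the projected ends cross
#' (`gap-proximal right` at or before `gap-proximal left`) the fill is
#' empty and the overlap is tolerated up to `max_overlap`, beyond which
#' the decision is downgraded to `rejected` with reason `fill-overlap`.
#' Projections escaping the donor sequence downgrade with reason
#' `fill-out-of-bounds`.
#'
#' @param decisions a decision tibble from [evaluate_gaps()].
#' @param flanks the flank tibble the decisions were evaluated from.
#' @param donor the donor assembly.
#' @param thresholds a [closure_thresholds()] object.
#' @return the decision tibble with `fill_seq_id`, `fill_start`,
#'   `fill_end`, `fill_strand`, `fill_len`, `overlap_len`, `fill_seq`,
#'   `fill_nonn` columns added and statuses downgraded where the fill is
#'   undefined.
#' @export
extract_fills <- function(decisions, flanks, donor,
                          thresholds = closure_thresholds()) {
  donor_lens <- setNames(nchar(donor$sequence), donor$seq_id)
  fl <- flanks[match(decisions$gap_id, flanks$gap_id), ]
  n <- nrow(decisions)
  decisions$fill_seq_id <- NA_character_
  decisions$fill_start <- NA_integer_
  decisions$fill_end <- NA_integer_
  decisions$fill_strand <- NA_character_
  decisions$fill_len <- NA_integer_
  decisions$overlap_len <- NA_integer_
  decisions$fill_seq <- NA_character_
  decisions$fill_nonn <- NA_integer_
  for (i in seq_len(n)) {
    d <- decisions[i, ]
    if (d$status != "closed") next
    tail_l <- fl$left_len[i] - d$left_query_end
    tail_r <- d$right_query_start
    if (d$left_strand == "+") {
      gpl <- d$left_donor_end + tail_l
      gpr <- d$right_donor_start - tail_r
    } else {
      gpr <- d$left_donor_start - tail_l   # forward-frame fill end
      gpl <- d$right_donor_end + tail_r    # forward-frame fill start
    }
    dlen <- donor_lens[[d$left_donor_seq_id]]
    if (gpr <= gpl) {
      ov <- gpl - gpr
      if (ov > thresholds$max_overlap) {
        decisions$status[i] <- "rejected"
        decisions$reason[i] <- "fill-overlap"
        decisions$overlap_len[i] <- ov
        next
      }
      decisions$fill_seq_id[i] <- d$left_donor_seq_id
      decisions$fill_start[i] <- gpl
      decisions$fill_end[i] <- gpl
      decisions$fill_strand[i] <- d$left_strand
      decisions$fill_len[i] <- 0L
      decisions$overlap_len[i] <- ov
      decisions$fill_seq[i] <- ""
      decisions$fill_nonn[i] <- 0L
      next
    }
    if (gpl < 0 || gpr > dlen) {
      decisions$status[i] <- "rejected"
      decisions$reason[i] <- "fill-out-of-bounds"
      next
    }
    fill <- seq_slice(donor, d$left_donor_seq_id, gpl, gpr)
    if (d$left_strand == "-") fill <- revcomp(fill)
    if (thresholds$require_fill_n_free && grepl("[Nn]", fill)) {
      decisions$status[i] <- "rejected"
      decisions$reason[i] <- "fill-contains-n"
      next
    }
    decisions$fill_seq_id[i] <- d$left_donor_seq_id
    decisions$fill_start[i] <- gpl
    decisions$fill_end[i] <- gpr
    decisions$fill_strand[i] <- d$left_strand
    decisions$fill_len[i] <- gpr - gpl
    decisions$overlap_len[i] <- 0L
    decisions$fill_seq[i] <- fill
    decisions$fill_nonn[i] <- nchar(gsub("[Nn]", "", fill))
  }
  decisions
}

#' Apply closures to the target assembly
#'
#' Replaces each closed gap's N-run with its fill sequence. Closures on
#' one sequence are applied in descending start order so earlier
#' coordinates stay valid; all other bases are byte-identical to the
#' input. The report carries old and new coordinates (non-closed gaps are
#' shifted by the closures upstream of them) and the per-criterion flags
#' for every gap.
#'
#' @param assembly the target assembly.
#' @param decisions a decision tibble from [extract_fills()].
#' @param donor the donor assembly (kept in the result for provenance).
#' @return a `closure_result` list with elements `assembly` (the closed
#'   assembly tibble) and `report` (per-gap tibble); see
#'   [tidy.closure_result()] and [glance.closure_result()].
#' @export
apply_closures <- function(assembly, decisions, donor = NULL) {
  if (nrow(decisions) > 0) {
    iv <- decisions[order(decisions$seq_id, decisions$gap_start), ]
    same <- iv$seq_id[-1] == iv$seq_id[-nrow(iv)]
    if (nrow(iv) > 1 && any(same & iv$gap_start[-1] < iv$gap_end[-nrow(iv)])) {
      abort("decisions contain overlapping gap intervals")
    }
  }
  if (!("fill_seq" %in% names(decisions))) {
    abort("decisions lack fill columns; run extract_fills() first")
  }
  closed_asm <- assembly
  closed <- decisions[decisions$status == "closed", ]
  for (sid in unique(closed$seq_id)) {
    rows <- closed[closed$seq_id == sid, ]
    rows <- rows[order(-rows$gap_start), ]
    s <- closed_asm$sequence[closed_asm$seq_id == sid]
    for (j in seq_len(nrow(rows))) {
      s <- paste0(substr(s, 1L, rows$gap_start[j]),
                  rows$fill_seq[j],
                  substr(s, rows$gap_end[j] + 1L, nchar(s)))
    }
    closed_asm$sequence[closed_asm$seq_id == sid] <- s
  }
  report <- decisions %>%
    dplyr::arrange(.data$seq_id, .data$gap_start) %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::mutate(
      delta = ifelse(.data$status == "closed",
                     .data$fill_len - .data$n_length, 0L),
      shift = cumsum(dplyr::lag(.data$delta, default = 0L)),
      new_start = .data$gap_start + .data$shift,
      new_end = .data$new_start + ifelse(.data$status == "closed",
                                         .data$fill_len, .data$n_length)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"delta", -"shift", -"fill_seq")
  structure(list(assembly = closed_asm, report = report),
            class = "closure_result")
}

#' @export
print.closure_result <- function(x, ...) {
  tot <- closure_totals(x$report)
  cat(sprintf("<closure_result> %d gaps evaluated: %d closed, %d rejected, %d unevaluable\n",
              tot$n_evaluated, tot$n_closed, tot$n_rejected, tot$n_unevaluable))
  cat(sprintf("  N bases removed: %d; non-N fill bases added: %d\n",
              tot$closed_gap_n_bp, tot$fill_nonn_bp))
  invisible(x)
}

#' @rdname apply_closures
#' @param x a `closure_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.closure_result <- function(x, ...) x$report

#' @rdname apply_closures
#' @exportS3Method generics::glance
glance.closure_result <- function(x, ...) closure_totals(x$report)

#' Summarize a closure report
#'
#' @param report a per-gap report tibble (from [apply_closures()] or
#'   [extract_fills()]).
#' @return a one-row tibble: gaps evaluated / closed / rejected /
#'   unevaluable, counts of gaps failing each criterion, N bases of
#'   closed gaps, total fill bp and non-N fill bp.
#' @export
closure_totals <- function(report) {
  closed <- report[report$status == "closed", ]
  fail <- function(col) sum(!report[[col]], na.rm = TRUE)
  tibble::tibble(
    n_evaluated = nrow(report),
    n_closed = nrow(closed),
    n_rejected = sum(report$status == "rejected"),
    n_unevaluable = sum(report$status == "unevaluable"),
    n_fail_c1 = fail("c1"), n_fail_c2 = fail("c2"),
    n_fail_c3 = fail("c3"), n_fail_c4 = fail("c4"),
    closed_gap_n_bp = sum(closed$n_length, na.rm = TRUE),
    fill_bp = sum(closed$fill_len, na.rm = TRUE),
    fill_nonn_bp = sum(closed$fill_nonn, na.rm = TRUE)
  )
}

#' Run the whole closure pipeline
#'
#' Convenience wrapper: gap discovery (unless `gaps` given), flank
#' extraction, flank alignment, criterion evaluation, fill extraction and
#' application.
#'
#' @param target target assembly tibble (the one with gaps).
#' @param donor donor assembly tibble.
#' @param gaps optional gap tibble; found with [find_gaps()] if missing.
#' @param flank flank length F in bp.
#' @param thresholds a [closure_thresholds()] object.
#' @param alignments optional precomputed alignment tibble (e.g. from
#'   [read_coords()]); computed with [align_flanks()] if missing.
#' @param ... further parameters passed to [align_flanks()].
#' @return a `closure_result` (see [apply_closures()]).
#' @export
close_gaps <- function(target, donor, gaps = NULL, flank = 10000,
                       thresholds = closure_thresholds(), alignments = NULL,
                       ...) {
  if (is.null(gaps)) gaps <- find_gaps(target)
  flanks <- extract_flanks(target, gaps, flank = flank)
  if (is.null(alignments)) alignments <- align_flanks(flanks, donor, ...)
  decisions <- evaluate_gaps(flanks, alignments, donor, thresholds)
  decisions <- extract_fills(decisions, flanks, donor, thresholds)
  apply_closures(target, decisions, donor)
}
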