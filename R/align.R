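#' Build a reusable k-mer index over a donor assembly
#'
#' The index stores exact k-mer positions (2-bit packed; k-mers containing
#' N never index) and is shared across flank alignments.
#'
#' @param donor an assembly tibble.
#' @param k k-mer length (default 15, the minimum exact-match length the
#'   flank placements are anchored on).
#' @return a `donor_index` object.
#' @export
donor_index <- function(donor, k = 15) {
  structure(list(ptr = cpp_kmer_index(donor$sequence, as.integer(k)),
                 seq_ids = donor$seq_id, k = k),
            class = "donor_index")
}

#' Align one flank sequence against a donor assembly
#'
#' Deterministic anchor-chaining aligner: (1) exact k-mer anchors on both
#' strands; (2) colinear clustering of anchors on the same donor sequence
#' and strand with inter-anchor gaps at most `max_anchor_gap`;
#' (3) clusters whose anchored query span reaches `min_cluster` are kept;
#' (4) each kept cluster's spanned substrings are aligned by banded
#' global alignment (match +1, mismatch -1, gap -2, band
#' `band * span`; N matches nothing). Percent identity counts gap
#' columns in its denominator (aligned columns include indels), the usual
#' coordinate-table convention, which matters because the closure
#' criteria consume it.
#'
#' Results are sorted by descending `align_len_query`, then descending
#' `pct_identity`, then (`donor_seq_id`, `donor_start`) ascending, so the
#' first row is the [best_alignment()] default choice.
#'
#' @param flank_seq a single flank sequence (character scalar).
#' @param donor an assembly tibble or a prebuilt [donor_index()].
#' @param k,min_cluster,max_anchor_gap,band,diag_tol,min_band aligner
#'   parameters; `diag_tol` bounds the diagonal drift an anchor may
#'   introduce into a growing cluster, `min_band` floors the DP band.
#' @return a tibble of local alignments (possibly empty) with columns
#'   `query_start`, `query_end`, `donor_seq_id`, `donor_start`,
#'   `donor_end`, `strand`, `matches`, `aligned_cols`, `pct_identity`,
#'   `align_len_query`.
#' @export
align_flank <- function(flank_seq, donor, k = 15, min_cluster = 25,
                        max_anchor_gap = 500, band = 0.2, diag_tol = 100,
                        min_band = 16) {
  idx <- if (inherits(donor, "donor_index")) donor else donor_index(donor, k = k)
  raw <- cpp_align_flank(idx$ptr, flank_seq, as.integer(min_cluster),
                         as.integer(max_anchor_gap), band,
                         as.integer(diag_tol), as.integer(min_band))
  out <- tibble::as_tibble(raw) %>%
    dplyr::mutate(
      donor_seq_id = idx$seq_ids[.data$donor_idx],
      pct_identity = ifelse(.data$aligned_cols > 0,
                            100 * .data$matches / .data$aligned_cols, 0),
      align_len_query = .data$query_end - .data$query_start
    ) %>%
    dplyr::select("query_start", "query_end", "donor_seq_id", "donor_start",
                  "donor_end", "strand", "matches", "aligned_cols",
                  "pct_identity", "align_len_query")
  sort_alignments(out)
}

sort_alignments <- function(alns) {
  dplyr::arrange(alns, dplyr::desc(.data$align_len_query),
                 dplyr::desc(.data$pct_identity),
                 .data$donor_seq_id, .data$donor_start)
}

#' Align all flanks of a flank table against a donor assembly
#'
#' Builds the donor k-mer index once and runs [align_flank()] for every
#' evaluable flank side.
#'
#' @param flanks a flank tibble from [extract_flanks()].
#' @param donor an assembly tibble or a [donor_index()].
#' @inheritParams align_flank
#' @return a tibble of local alignments with `gap_id` and `flank_role`
#'   (`"left"`/`"right"`) columns prepended.
#' @export
align_flanks <- function(flanks, donor, k = 15, min_cluster = 25,
                         max_anchor_gap = 500, band = 0.2, diag_tol = 100,
                         min_band = 16) {
  idx <- if (inherits(donor, "donor_index")) donor else donor_index(donor, k = k)
  one_side <- function(i, role, seq) {
    a <- align_flank(seq, idx, k = k, min_cluster = min_cluster,
                     max_anchor_gap = max_anchor_gap, band = band,
                     diag_tol = diag_tol, min_band = min_band)
    if (nrow(a) == 0) return(NULL)
    tibble::add_column(a, gap_id = flanks$gap_id[i], flank_role = role,
                       .before = 1)
  }
  purrr::map_dfr(seq_len(nrow(flanks)), function(i) {
    dplyr::bind_rows(
      if (flanks$left_ok[i]) one_side(i, "left", flanks$left_seq[i]),
      if (flanks$right_ok[i]) one_side(i, "right", flanks$right_seq[i])
    )
  })
}

#' Pick the best alignment per flank
#'
#' Default policy: longest query coverage, then highest percent identity,
#' then (donor sequence, donor start) ascending -- a fully specified,
#' platform-independent tie-break.
#'
#' @param alignments an alignment tibble; if `gap_id`/`flank_role`
#'   columns are present the selection is per flank, otherwise the whole
#'   table is treated as one flank's candidates.
#' @return a tibble with one row per flank (zero rows for empty input).
#' @export
best_alignment <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  grouped <- all(c("gap_id", "flank_role") %in% names(alignments))
  if (grouped) {
    alignments %>%
      dplyr::group_by(.data$gap_id, .data$flank_role) %>%
      dplyr::arrange(dplyr::desc(.data$align_len_query),
                     dplyr::desc(.data$pct_identity),
                     .data$donor_seq_id, .data$donor_start, .by_group = TRUE) %>%
      dplyr::slice_head(n = 1) %>%
      dplyr::ungroup()
  } else {
    sort_alignments(alignments) %>% dplyr::slice_head(n = 1)
  }
}

#' Write flank alignments as a show-coords-style coordinate table
#'
#' Tab-separated with a header row and 1-based inclusive coordinates:
#' `query_id` (`<gap_id>|L` / `<gap_id>|R`), `target_id`, `query_start`,
#' `query_end`, `target_start`, `target_end`, `pct_identity`, `strand`.
#' Minus-strand records carry reversed target coordinates, as external
#' coordinate tables do.
#'
#' @param alignments an alignment tibble with `gap_id` and `flank_role`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_coords <- function(alignments, path) {
  out <- tibble::tibble(
    query_id = paste0(alignments$gap_id, "|",
                      ifelse(alignments$flank_role == "left", "L", "R")),
    target_id = alignments$donor_seq_id,
    query_start = alignments$query_start + 1L,
    query_end = alignments$query_end,
    target_start = ifelse(alignments$strand == "+",
                          alignments$donor_start + 1L, alignments$donor_end),
    target_end = ifelse(alignments$strand == "+",
                        alignments$donor_end, alignments$donor_start + 1L),
    pct_identity = alignments$pct_identity,
    strand = alignments$strand
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a show-coords-style coordinate table of flank alignments
#'
#' Ingestion path for externally produced alignments (e.g. NUCmer +
#' show-coords). Accepts the dialect written by [write_coords()];
#' reversed target coordinates imply the minus strand and are normalized
#' to forward donor intervals. Query ids must follow the
#' `<gap_id>|L` / `<gap_id>|R` scheme emitted by [write_flank_fasta()].
#'
#' @param path coordinate TSV (1-based inclusive input coordinates).
#' @return an alignment tibble as produced by [align_flanks()] (without
#'   `matches`/`aligned_cols`, which coordinate tables do not carry).
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("query_id", "target_id", "query_start", "query_end",
            "target_start", "target_end", "pct_identity")
  if (!all(need %in% names(tab))) {
    abort(paste0("coordinate table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  role_suffix <- stringr::str_match(tab$query_id, "^(.*)\\|([LR])$")
  bad <- which(is.na(role_suffix[, 3]))
  if (length(bad) > 0) {
    abort(sprintf("line %d: query id '%s' lacks a |L / |R flank-role suffix",
                  bad[1] + 1L, tab$query_id[bad[1]]))
  }
  rev <- tab$target_start > tab$target_end
  strand <- if ("strand" %in% names(tab)) tab$strand else
    ifelse(rev, "-", "+")
  strand[rev] <- "-"
  ds <- ifelse(rev, tab$target_end, tab$target_start) - 1L
  de <- ifelse(rev, tab$target_start, tab$target_end)
  tibble::tibble(
    gap_id = role_suffix[, 2],
    flank_role = ifelse(role_suffix[, 3] == "L", "left", "right"),
    query_start = as.integer(tab$query_start) - 1L,
    query_end = as.integer(tab$query_end),
    donor_seq_id = as.character(tab$target_id),
    donor_start = as.integer(ds),
    donor_end = as.integer(de),
    strand = strand,
    pct_identity = as.numeric(tab$pct_identity),
    align_len_query = as.integer(tab$query_end) - as.integer(tab$query_start) + 1L
  )
}
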