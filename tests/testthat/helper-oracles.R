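# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base boolean-array union length
oracle_union_length <- function(intervals, axis = NULL) {
  if (nrow(intervals) == 0) return(0)
  key <- if ("seq_id" %in% names(intervals)) intervals$seq_id else
    rep("", nrow(intervals))
  total <- 0
  for (k in unique(key)) {
    iv <- intervals[key == k, ]
    covered <- logical(max(iv$end))
    for (i in seq_len(nrow(iv))) {
      covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
    total <- total + sum(covered)
  }
  total
}

# regex-based maximal N-run finder
oracle_find_gaps <- function(asm, min_len) {
  out <- list()
  for (i in seq_len(nrow(asm))) {
    m <- gregexpr(sprintf("[Nn]{%d,}", min_len), asm$sequence[i])[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    out[[length(out) + 1L]] <- tibble::tibble(
      seq_id = asm$seq_id[i], start = starts, end = starts + lens)
  }
  if (length(out) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), seq_id, start)
}

# exhaustive pairwise comparator for the best-alignment policy
oracle_best <- function(alns) {
  if (nrow(alns) == 0) return(alns)
  better <- function(i, j) {
    if (alns$align_len_query[i] != alns$align_len_query[j])
      return(alns$align_len_query[i] > alns$align_len_query[j])
    if (alns$pct_identity[i] != alns$pct_identity[j])
      return(alns$pct_identity[i] > alns$pct_identity[j])
    if (alns$donor_seq_id[i] != alns$donor_seq_id[j])
      return(alns$donor_seq_id[i] < alns$donor_seq_id[j])
    alns$donor_start[i] < alns$donor_start[j]
  }
  best <- 1L
  for (j in seq_len(nrow(alns))[-1]) if (better(j, best)) best <- j
  alns[best, ]
}

# naive re-statement of the four closure rules from chosen alignments
oracle_closure <- function(la, ra, donor, min_aln = 5000, min_ident = 90) {
  if (is.null(la) || is.null(ra)) return(list(status = "unevaluable"))
  c1 <- la$align_len_query > min_aln && ra$align_len_query > min_aln
  c2 <- (la$pct_identity + ra$pct_identity) / 2 > min_ident
  c3 <- FALSE
  if (la$donor_seq_id == ra$donor_seq_id && la$strand == ra$strand) {
    if (la$strand == "+") c3 <- la$donor_end <= ra$donor_start
    else c3 <- ra$donor_end <= la$donor_start
  }
  seq <- donor$sequence[donor$seq_id == la$donor_seq_id]
  sub_l <- substr(seq, la$donor_start + 1, la$donor_end)
  seq_r <- donor$sequence[donor$seq_id == ra$donor_seq_id]
  sub_r <- substr(seq_r, ra$donor_start + 1, ra$donor_end)
  c4 <- !grepl("N", sub_l, ignore.case = TRUE) &&
    !grepl("N", sub_r, ignore.case = TRUE)
  list(status = if (c1 && c2 && c3 && c4) "closed" else "rejected",
       c1 = c1, c2 = c2, c3 = c3, c4 = c4)
}

# per-base physical coverage over one gap
oracle_gap_coverage <- function(pairs, seq_id, start, end) {
  p <- pairs[pairs$seq_id == seq_id, ]
  if (end <= start) return(NA_real_)
  depth <- vapply((start + 1):end, function(pos) {
    sum(p$outer_start < pos & p$outer_end >= pos)
  }, numeric(1))
  mean(depth)
}

# naive per-column match/mismatch counter over one gapped block
oracle_match_mismatch <- function(a_text, b_text, skip_n = FALSE) {
  a <- strsplit(toupper(a_text), "")[[1]]
  b <- strsplit(toupper(b_text), "")[[1]]
  m <- 0; mm <- 0
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") next
    if (a[i] == "N" || b[i] == "N") {
      if (!skip_n) mm <- mm + 1
      next
    }
    if (a[i] == b[i]) m <- m + 1 else mm <- mm + 1
  }
  c(match = m, mismatch = mm)
}

# naive identity of two equal-length strings (substitution-only model)
oracle_identity <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  100 * mean(av == bv & av != "N")
}

# a small, quick simulation configuration for unit tests
small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_sequences = 2, seq_length = 150000, n_gaps = 4,
               repeat_copies = c(12, 5, 2), mutation_rate = 0,
               frac_inversion = 0.25, frac_n_island = 0.25,
               n_variants = 40, n_genes = 25, pair_depth = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
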