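# helper: build a one-gap evaluation scenario from hand-crafted alignments
mk_flanks <- function(target, flank) {
  extract_flanks(target, find_gaps(target, min_len = 1), flank = flank)
}

mk_aln <- function(gap_id, role, qs, qe, seq, ds, de, strand = "+", ident = 100) {
  tibble::tibble(gap_id = gap_id, flank_role = role,
                 query_start = qs, query_end = qe, donor_seq_id = seq,
                 donor_start = ds, donor_end = de, strand = strand,
                 pct_identity = ident, align_len_query = qe - qs)
}

test_that("criterion thresholds are strict inequalities", {
  set.seed(51)
  donor <- assembly(c(d = rand_dna(40000)))
  target <- assembly(c(t = paste0(rand_dna(12000), strrep("N", 50), rand_dna(12000))))
  fl <- mk_flanks(target, 10000)
  gid <- fl$gap_id
  base_l <- function(len, ident = 100)
    mk_aln(gid, "left", 10000 - len, 10000, "d", 1000, 1000 + len, ident = ident)
  base_r <- function(len, ident = 100)
    mk_aln(gid, "right", 0, len, "d", 20000, 20000 + len, ident = ident)

  # alignment length exactly at the threshold fails c1
  d <- evaluate_gaps(fl, dplyr::bind_rows(base_l(5000), base_r(5000)), donor)
  expect_false(d$c1)
  expect_equal(d$status, "rejected")
  d <- evaluate_gaps(fl, dplyr::bind_rows(base_l(5001), base_r(5001)), donor)
  expect_true(d$c1)
  expect_equal(d$status, "closed")

  # mean identity exactly 90 fails c2; 90.5 passes
  d <- evaluate_gaps(fl, dplyr::bind_rows(base_l(6000, 92), base_r(6000, 88)), donor)
  expect_false(d$c2)
  d <- evaluate_gaps(fl, dplyr::bind_rows(base_l(6000, 92), base_r(6000, 87)), donor)
  expect_false(d$c2)
  d <- evaluate_gaps(fl, dplyr::bind_rows(base_l(6000, 92), base_r(6000, 89)), donor)
  expect_true(d$c2)
})

test_that("c3 requires same sequence, same strand and consistent order", {
  set.seed(52)
  donor <- assembly(c(d1 = rand_dna(40000), d2 = rand_dna(40000)))
  target <- assembly(c(t = paste0(rand_dna(12000), strrep("N", 50), rand_dna(12000))))
  fl <- mk_flanks(target, 10000)
  gid <- fl$gap_id
  l <- mk_aln(gid, "left", 2000, 10000, "d1", 1000, 9000)
  cases <- list(
    ok = mk_aln(gid, "right", 0, 8000, "d1", 9500, 17500),
    cross_seq = mk_aln(gid, "right", 0, 8000, "d2", 9500, 17500),
    strand = mk_aln(gid, "right", 0, 8000, "d1", 9500, 17500, strand = "-"),
    order = mk_aln(gid, "right", 0, 8000, "d1", 100, 8100))
  got <- vapply(cases, function(r)
    evaluate_gaps(fl, dplyr::bind_rows(l, r), donor)$c3, logical(1))
  expect_equal(unname(got), c(TRUE, FALSE, FALSE, FALSE))

  # minus strand: right image must precede the left image in the donor
  l2 <- mk_aln(gid, "left", 2000, 10000, "d1", 20000, 28000, strand = "-")
  r_ok <- mk_aln(gid, "right", 0, 8000, "d1", 5000, 13000, strand = "-")
  r_bad <- mk_aln(gid, "right", 0, 8000, "d1", 30000, 38000, strand = "-")
  expect_true(evaluate_gaps(fl, dplyr::bind_rows(l2, r_ok), donor)$c3)
  expect_false(evaluate_gaps(fl, dplyr::bind_rows(l2, r_bad), donor)$c3)
})

test_that("c4 detects N under either chosen alignment", {
  set.seed(53)
  d <- rand_dna(40000)
  substr(d, 5000, 5050) <- strrep("N", 51)
  donor <- assembly(c(d = d))
  target <- assembly(c(t = paste0(rand_dna(12000), strrep("N", 50), rand_dna(12000))))
  fl <- mk_flanks(target, 10000)
  gid <- fl$gap_id
  l_n <- mk_aln(gid, "left", 2000, 10000, "d", 2000, 10000)      # covers the island
  l_ok <- mk_aln(gid, "left", 2000, 10000, "d", 10000, 18000)
  r <- mk_aln(gid, "right", 0, 8000, "d", 20000, 28000)
  expect_false(evaluate_gaps(fl, dplyr::bind_rows(l_n, r), donor)$c4)
  expect_true(evaluate_gaps(fl, dplyr::bind_rows(l_ok, r), donor)$c4)
})

test_that("fill extraction projects gap-proximal ends and handles zero fill", {
  donor <- assembly(c(d = "AAAACCCTTTT"))
  target <- assembly(c(t = "AAAANNTTTT"))
  fl <- mk_flanks(target, 4)
  gid <- fl$gap_id
  thr <- closure_thresholds(min_aln_len = 3, min_mean_identity = 90)
  alns <- dplyr::bind_rows(
    mk_aln(gid, "left", 0, 4, "d", 0, 4),
    mk_aln(gid, "right", 0, 4, "d", 7, 11))
  dec <- extract_fills(evaluate_gaps(fl, alns, donor, thr), fl, donor, thr)
  expect_equal(dec$status, "closed")
  expect_equal(dec$fill_seq, "CCC")
  res <- apply_closures(target, dec, donor)
  expect_equal(res$assembly$sequence, "AAAACCCTTTT")

  donor2 <- assembly(c(d = "AAAATTTT"))
  alns2 <- dplyr::bind_rows(
    mk_aln(gid, "left", 0, 4, "d", 0, 4),
    mk_aln(gid, "right", 0, 4, "d", 4, 8))
  dec2 <- extract_fills(evaluate_gaps(fl, alns2, donor2, thr), fl, donor2, thr)
  expect_equal(dec2$status, "closed")
  expect_equal(dec2$fill_len, 0L)
  expect_equal(dec2$overlap_len, 0L)
  expect_equal(apply_closures(target, dec2, donor2)$assembly$sequence, "AAAATTTT")
})

test_that("overlapping flank placements reject beyond max_overlap", {
  donor <- assembly(c(d = "AAAATTTT"))
  target <- assembly(c(t = "AAAANNTTTT"))
  fl <- mk_flanks(target, 4)
  gid <- fl$gap_id
  thr <- closure_thresholds(min_aln_len = 1, min_mean_identity = 90)
  # ordered placements whose tail-extended projections cross by 1 bp:
  # left covers its whole flank (gpl = 4); the right alignment leaves a
  # 2 bp unaligned tail, projecting its gap-proximal end to 5 - 2 = 3
  alns <- dplyr::bind_rows(
    mk_aln(gid, "left", 0, 4, "d", 0, 4),
    mk_aln(gid, "right", 2, 4, "d", 5, 7))
  dec <- extract_fills(evaluate_gaps(fl, alns, donor, thr), fl, donor, thr)
  expect_equal(dec$status, "rejected")
  expect_equal(dec$reason, "fill-overlap")
  expect_equal(dec$overlap_len, 1L)

  thr2 <- closure_thresholds(min_aln_len = 1, min_mean_identity = 90,
                             max_overlap = 1)
  dec2 <- extract_fills(evaluate_gaps(fl, alns, donor, thr2), fl, donor, thr2)
  expect_equal(dec2$status, "closed")
  expect_equal(dec2$fill_len, 0L)
})

test_that("minus-strand closures reverse-complement the fill byte-exactly", {
  set.seed(54)
  bg <- rand_dna(60000)
  donor <- assembly(c(d = bg))
  # target carries the reverse complement of donor[10000, 40000); remove
  # 500 bp in its middle and plant a 60 bp N-run
  region <- revcomp(substr(bg, 10001, 40000))
  removed <- substr(region, 15001, 15500)
  tgt <- paste0(substr(region, 1, 15000), strrep("N", 60),
                substr(region, 15501, nchar(region)))
  target <- assembly(c(t = tgt))
  res <- close_gaps(target, donor, flank = 10000)
  rep <- res$report
  expect_equal(rep$status, "closed")
  expect_equal(rep$left_strand, "-")
  expect_equal(rep$fill_len, 500L)
  expect_equal(res$assembly$sequence, region)
  expect_equal(substr(res$assembly$sequence, 15001, 15500), removed)
})

test_that("apply_closures keeps bookkeeping consistent on random fixtures", {
  sim <- simulate_assembly_pair(small_config(seed = 55))
  res <- close_gaps(sim$target, sim$donor, flank = 10000)
  rep <- res$report
  old_len <- seq_lengths(sim$target)
  new_len <- seq_lengths(res$assembly)
  for (sid in old_len$seq_id) {
    closed <- rep[rep$seq_id == sid & rep$status == "closed", ]
    expect_equal(new_len$length[new_len$seq_id == sid],
                 old_len$length[old_len$seq_id == sid] -
                   sum(closed$n_length) + sum(closed$fill_len))
  }
  # flank conservation: 2F bases adjacent to each closed gap unchanged
  closed <- rep[rep$status == "closed", ]
  for (i in seq_len(nrow(closed))) {
    r <- closed[i, ]
    old_s <- sim$target$sequence[sim$target$seq_id == r$seq_id]
    new_s <- res$assembly$sequence[res$assembly$seq_id == r$seq_id]
    expect_equal(substr(new_s, r$new_start - 9999, r$new_start),
                 substr(old_s, r$gap_start - 9999, r$gap_start))
    expect_equal(substr(new_s, r$new_end + 1, r$new_end + 10000),
                 substr(old_s, r$gap_end + 1, r$gap_end + 10000))
  }
  # no closures => byte-identical output
  none <- res$report[0, ]
  dec0 <- extract_fills(none, extract_flanks(sim$target, find_gaps(sim$target)),
                        sim$donor)
  expect_equal(apply_closures(sim$target, dec0, sim$donor)$assembly,
               sim$target)
})

test_that("closure is idempotent: re-running closes nothing new", {
  sim <- simulate_assembly_pair(small_config(seed = 56))
  res1 <- close_gaps(sim$target, sim$donor, flank = 10000)
  gaps2 <- find_gaps(res1$assembly)
  # the only remaining N-runs are the rejected gaps; none become closable
  res2 <- close_gaps(res1$assembly, sim$donor, gaps = gaps2, flank = 10000)
  closed1 <- res1$report$gap_id[res1$report$status == "closed"]
  expect_equal(glance(res2)$n_closed, 0L)
  expect_equal(nrow(gaps2),
               sum(res1$report$status != "closed"))
})

test_that("closure_totals aggregates counts and reasons", {
  rep <- tibble::tibble(
    gap_id = c("g1", "g2", "g3"), status = c("closed", "closed", "rejected"),
    c1 = c(TRUE, TRUE, FALSE), c2 = TRUE, c3 = TRUE, c4 = TRUE,
    n_length = c(5L, 3L, 7L), fill_len = c(7L, 0L, NA),
    fill_nonn = c(7L, 0L, NA))
  tot <- closure_totals(rep)
  expect_equal(tot$n_closed, 2L)
  expect_equal(tot$closed_gap_n_bp, 8L)
  expect_equal(tot$fill_nonn_bp, 7L)
  expect_equal(tot$n_fail_c1, 1L)
  zero <- closure_totals(rep[0, ])
  expect_equal(zero$n_evaluated, 0L)
  expect_equal(zero$fill_bp, 0L)
})

test_that("overlapping gap intervals abort before any edit", {
  dec <- tibble::tibble(
    gap_id = c("a:0-5", "a:3-8"), seq_id = "a",
    gap_start = c(0L, 3L), gap_end = c(5L, 8L),
    status = "rejected", fill_seq = NA_character_, fill_len = NA_integer_,
    n_length = c(5L, 5L))
  expect_error(apply_closures(assembly(c(a = "NNNNNNNNNN")), dec),
               "overlapping")
})

test_that("raising thresholds never increases the closed count (small sweep)", {
  sim <- simulate_assembly_pair(small_config(seed = 57, mutation_rate = 0.01))
  gaps <- find_gaps(sim$target)
  flanks <- extract_flanks(sim$target, gaps, flank = 10000)
  alns <- align_flanks(flanks, sim$donor)
  closed_count <- function(min_aln, min_ident) {
    thr <- closure_thresholds(min_aln_len = min_aln, min_mean_identity = min_ident)
    dec <- extract_fills(evaluate_gaps(flanks, alns, sim$donor, thr),
                         flanks, sim$donor, thr)
    sum(dec$status == "closed")
  }
  grid <- expand.grid(aln = c(1000, 5000, 9000), ident = c(80, 95, 99.9))
  counts <- matrix(mapply(closed_count, grid$aln, grid$ident), nrow = 3)
  expect_true(all(apply(counts, 2, diff) <= 0))  # rows: rising min_aln
  expect_true(all(apply(counts, 1, diff) <= 0))  # cols: rising identity
})
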