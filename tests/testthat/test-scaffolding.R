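mk_layout <- function(...) dplyr::bind_rows(...)

ctg <- function(scaffold, start, end, id, part) {
  tibble::tibble(scaffold = scaffold, start = start, end = end,
                 part_number = part, type = "contig", component_id = id,
                 component_start = 0L, component_end = end - start,
                 orientation = "+", gap_length = NA_integer_,
                 gap_type = NA_character_)
}

test_that("connected contigs require >= 2 contigs in a scaffold", {
  single <- ctg("s1", 0L, 1000L, "c1", 1L)
  expect_equal(nrow(connected_contig_lengths(single)), 0)

  multi <- mk_layout(
    ctg("s2", 0L, 10000L, "c2", 1L),
    tibble::tibble(scaffold = "s2", start = 10000L, end = 10100L,
                   part_number = 2L, type = "gap", component_id = NA,
                   component_start = NA_integer_, component_end = NA_integer_,
                   orientation = NA_character_, gap_length = 100L,
                   gap_type = "scaffold"),
    ctg("s2", 10100L, 30100L, "c3", 3L),
    ctg("s2", 30100L, 60100L, "c4", 4L))
  lens <- connected_contig_lengths(multi)
  expect_equal(sort(lens$length), c(10000L, 20000L, 30000L))
})

test_that("generator scaffold-layout truth is recovered exactly", {
  sim <- simulate_assembly_pair(small_config(seed = 81))
  gaps <- find_gaps(sim$target)
  layout <- simulate_scaffold_layout(sim$target, gaps)
  lens <- connected_contig_lengths(layout)
  # every sequence with g gaps contributes g+1 connected contigs
  per_seq <- table(gaps$seq_id)
  expect_equal(nrow(lens), sum(per_seq + 1))
  expect_equal(sum(lens$length) + sum(gaps$n_length),
               sum(seq_lengths(sim$target)$length))
})

test_that("pair loading filters spans, sequences and orientation with reasons", {
  pairs <- tibble::tibble(
    seq1 = c("s", "s", "s", "s"), start1 = c(100, 100, 100, 100),
    end1 = c(251, 251, 251, 251), strand1 = "+",
    seq2 = c("s", "x", "s", "s"),
    start2 = c(11849, 11849, 1000, 11849), end2 = c(12000, 12000, 1151, 12000),
    strand2 = c("-", "-", "-", "+"))
  kept <- load_pairs(pairs)
  expect_equal(kept$span_len, c(11900, 11900))
  disc <- attr(kept, "discarded")
  expect_equal(disc$n[disc$reason == "cross-sequence"], 1)
  expect_equal(disc$n[disc$reason == "span-too-short"], 1)

  strict <- load_pairs(pairs, require_orientation = TRUE)
  expect_equal(nrow(strict), 1)
  d2 <- attr(strict, "discarded")
  expect_equal(d2$n[d2$reason == "bad-orientation"], 1)
})

test_that("generator keep/discard labels match the loader exactly", {
  cfg <- small_config(seed = 82)
  sim <- simulate_assembly_pair(cfg)
  mp <- simulate_mate_pairs(sim$target, cfg)
  kept <- load_pairs(mp$pairs)
  expect_equal(nrow(kept), sum(mp$truth$expected == "kept"))
  disc <- attr(kept, "discarded")
  for (r in disc$reason) {
    expect_equal(disc$n[disc$reason == r], sum(mp$truth$expected == r))
  }
})

test_that("per-gap physical coverage equals the per-base oracle", {
  pairs <- tibble::tibble(seq_id = "s", outer_start = 100, outer_end = 12000,
                          span_len = 11900, orientation_ok = TRUE)
  gaps <- tibble::tibble(seq_id = "s", start = 5000, end = 5100)
  lens <- tibble::tibble(seq_id = "s", length = 20000)
  cov <- physical_coverage_at_gaps(pairs, gaps, lens)
  expect_equal(cov$coverage, 1)

  none <- suppressWarnings(
    physical_coverage_at_gaps(pairs[0, ], gaps, lens))
  expect_equal(none$coverage, 0)

  set.seed(83)
  for (rep in 1:40) {
    axis <- 5000
    n <- sample(5:40, 1)
    s <- sample(0:(axis - 200), n, replace = TRUE)
    p <- tibble::tibble(seq_id = "s", outer_start = s,
                        outer_end = s + sample(50:1500, n, replace = TRUE))
    p$outer_end <- pmin(p$outer_end, axis)
    p$span_len <- p$outer_end - p$outer_start
    gs <- sample(0:(axis - 120), 5)
    g <- tibble::tibble(seq_id = "s", start = gs,
                        end = gs + sample(10:100, 5, replace = TRUE))
    got <- physical_coverage_at_gaps(p, g, tibble::tibble(seq_id = "s",
                                                          length = axis))
    want <- vapply(seq_len(nrow(g)), function(i)
      oracle_gap_coverage(p, "s", g$start[i], g$end[i]), numeric(1))
    expect_equal(got$coverage, want, tolerance = 1e-12)
    # invariant to pair order
    got2 <- physical_coverage_at_gaps(p[sample(nrow(p)), ], g,
                                      tibble::tibble(seq_id = "s", length = axis))
    expect_equal(got2$coverage, got$coverage)
  }
})

test_that("genome-wide mean equals span conservation and the profile mean", {
  set.seed(84)
  axis <- 10000
  s <- sample(0:9000, 50, replace = TRUE)
  p <- tibble::tibble(seq_id = "s", outer_start = s,
                      outer_end = pmin(s + sample(100:900, 50, TRUE), axis))
  p$span_len <- p$outer_end - p$outer_start
  lens <- tibble::tibble(seq_id = "s", length = axis)
  m <- physical_coverage_mean(p, lens)
  expect_equal(m, sum(p$span_len) / axis, tolerance = 1e-12)
  profile <- vapply(1:axis, function(pos)
    sum(p$outer_start < pos & p$outer_end >= pos), numeric(1))
  expect_equal(m, mean(profile), tolerance = 1e-9)
})

test_that("midpoint and whole-gap modes behave as documented", {
  pairs <- tibble::tibble(seq_id = "s",
                          outer_start = c(0, 400), outer_end = c(500, 1200),
                          span_len = c(500, 800), orientation_ok = TRUE)
  gaps <- tibble::tibble(seq_id = "s", start = 450, end = 470)
  lens <- tibble::tibble(seq_id = "s", length = 2000)
  expect_equal(physical_coverage_at_gaps(pairs, gaps, lens)$coverage, 2)
  expect_equal(physical_coverage_at_gaps(pairs, gaps, lens,
                                         stat = "midpoint")$coverage, 2)
  # only the second pair spans this whole gap (the first ends inside it)
  gaps2 <- tibble::tibble(seq_id = "s", start = 450, end = 600)
  expect_equal(physical_coverage_at_gaps(pairs, gaps2, lens,
                                         span_whole_gap = TRUE)$coverage, 1)
  gaps3 <- tibble::tibble(seq_id = "s", start = 450, end = 490)
  expect_equal(physical_coverage_at_gaps(pairs, gaps3, lens,
                                         span_whole_gap = TRUE)$coverage, 2)
})

test_that("simulated library reaches its nominal physical depth at gaps", {
  cfg <- small_config(seed = 85, pair_depth = 20)
  sim <- simulate_assembly_pair(cfg)
  mp <- simulate_mate_pairs(sim$target, cfg)
  kept <- load_pairs(mp$pairs)
  lens <- seq_lengths(sim$target)
  m <- physical_coverage_mean(kept, lens)
  # 3-SE band around the nominal depth (span-length randomness dominates)
  n <- nrow(kept)
  se <- cfg$pair_insert_sd * sqrt(n) / sum(lens$length)
  expect_lt(abs(m - cfg$pair_depth), 3 * se + 0.5)
  gaps <- find_gaps(sim$target)
  cov <- physical_coverage_at_gaps(kept, gaps, lens)
  expect_gt(min(cov$coverage), 5)
})

test_that("mate pairs from SAM round-trip into the same pair table", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:s\tLN:20000",
    "r1\t99\ts\t101\t60\t150M\t=\t11851\t11900\t*\t*",
    "r1\t147\ts\t11851\t60\t150M\t=\t101\t-11900\t*\t*",
    "r2\t99\ts\t201\t60\t150M\t=\t401\t350\t*\t*",
    "r2\t147\ts\t401\t60\t150M\t=\t201\t-350\t*\t*"), sam)
  pairs <- load_pairs_sam(sam, require_orientation = FALSE)
  expect_equal(nrow(pairs), 1)   # r2's span is below insert_min
  expect_equal(pairs$outer_start, 100)
  expect_equal(pairs$outer_end, 12000)
})
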