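test_that("QV follows the closed form, the cap, and the tenfold law", {
  expect_equal(compute_qv(1, 1e4), 40)
  expect_equal(compute_qv(0, 1000), 60)
  expect_equal(compute_qv(721, 1e6), 31.42, tolerance = 5e-3)
  expect_error(compute_qv(1, 0), "callable")
  expect_error(compute_qv(-1, 10))
  set.seed(71)
  for (rep in 1:20) {
    e <- sample(1:50, 1); c <- sample(1e6:2e6, 1)
    expect_equal(compute_qv(10 * e, c, cap = Inf),
                 compute_qv(e, c, cap = Inf) - 10)
    expect_lt(compute_qv(e + 1, c, cap = Inf), compute_qv(e, c, cap = Inf))
  }
})

test_that("per-sequence QV aggregates reference-allele lengths", {
  variants <- tibble::tibble(seq_id = c("chrT", "chrT"),
                             ref = c("A", "ACT"))
  callable <- tibble::tibble(seq_id = "chrT", callable_bases = 1e6)
  qv <- qv_per_sequence(variants, callable)
  expect_equal(qv$error_bases, 4)
  expect_equal(qv$qv, -10 * log10(4e-6), tolerance = 1e-10)

  qv0 <- qv_per_sequence(variants[0, ], callable)
  expect_equal(qv0$qv, 60)
  expect_error(qv_per_sequence(tibble::tibble(seq_id = "nope", ref = "A"),
                               callable), "absent")
})

test_that("planted variants round-trip through VCF to the exact QV", {
  sim <- simulate_assembly_pair(small_config(seed = 72))
  ann <- simulate_annotations(sim$donor, small_config(seed = 72))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(ann$variants, f)
  back <- read_variants_vcf(f)
  expect_equal(nrow(back), nrow(ann$variants))
  expect_equal(sum(back$ref_len), sum(ann$variants$ref_len))
  qv <- qv_per_sequence(back, ann$callable)
  truth_err <- ann$variants %>%
    dplyr::group_by(seq_id) %>%
    dplyr::summarise(e = sum(ref_len))
  expect_equal(qv$error_bases[match(truth_err$seq_id, qv$seq_id)], truth_err$e)
})

test_that("window repeat ratios tile sequences and use non-N denominators", {
  w <- window_repeat_ratios(assembly(c(a = "acgtACGT")), window = 4)
  expect_equal(w$ratio, c(1, 0))
  # all-N window dropped; terminal window shorter than W/2 dropped
  w2 <- window_repeat_ratios(assembly(c(a = paste0("ACGT", strrep("N", 4), "A"))),
                             window = 4)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$start, 0)

  set.seed(73)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    ch <- sample(c("A", "C", "g", "t", "N", "n"), n, replace = TRUE)
    asm <- assembly(setNames(paste(ch, collapse = ""), "s"))
    W <- sample(7:40, 1)
    got <- window_repeat_ratios(asm, window = W)
    for (i in seq_len(nrow(got))) {
      win <- ch[(got$start[i] + 1):got$end[i]]
      nn <- sum(!win %in% c("N", "n"))
      reps <- sum(win %in% c("g", "t", "a", "c"))
      expect_equal(got$non_n_bases[i], nn)
      expect_equal(got$repeat_bases[i], reps)
    }
    expect_lte(sum(got$non_n_bases),
               sum(!strsplit(asm$sequence, "")[[1]] %in% c("N", "n")))
  }
})

test_that("repeat-annotation BED gives the same ratios as the soft-mask", {
  sim <- simulate_donor(small_config(seed = 74))
  by_mask <- window_repeat_ratios(sim$assembly, window = 10000)
  by_bed <- window_repeat_ratios(
    dplyr::mutate(sim$assembly, sequence = toupper(sequence)),
    window = 10000, repeat_bed = sim$repeats)
  expect_equal(by_mask$ratio, by_bed$ratio)
})

test_that("the exact Mann-Whitney engine reproduces enumeration results", {
  t1 <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$p_value, 0.1)
  expect_equal(t1$method, "exact")
  # identical groups: p = 1 under enumeration
  t2 <- mwu_test(c(2, 2, 5), c(2, 2, 5))
  expect_equal(t2$p_value, 1)
  expect_error(mwu_test(numeric(0), 1), "non-empty")
  expect_equal(tidy(t1)$p.value, 0.1)
})

test_that("both engines track wilcox.test on random data", {
  set.seed(75)
  for (rep in 1:30) {
    x <- rnorm(6); y <- rnorm(7) + runif(1, -1, 1)
    expect_equal(mwu_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    xx <- rnorm(30); yy <- rnorm(25) + runif(1, -0.5, 0.5)
    expect_equal(mwu_test(xx, yy)$p_value,
                 wilcox.test(xx, yy, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 0.01)
  }
})

test_that("window group comparison assigns by >= 1 bp overlap", {
  windows <- tibble::tibble(seq_id = "s", start = seq(0, 90, 10),
                            end = seq(10, 100, 10),
                            repeat_bases = 0, non_n_bases = 10,
                            ratio = c(0.9, 0.8, rep(0.1, 8)))
  gaps <- tibble::tibble(seq_id = "s", start = 9, end = 12)
  res <- compare_window_groups(windows, gaps)
  w <- attr(res, "windows")
  expect_equal(sum(w$group == "closed-gap"), 2)
  expect_equal(res$n_x, 2)
  expect_error(compare_window_groups(windows,
                                     tibble::tibble(seq_id = "s", start = 200,
                                                    end = 300)),
               "non-empty")
})

test_that("mapping-rate comparison reports direction and exact p", {
  rates <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:3), 2),
    assembly_id = rep(c("ncmd", "ref"), each = 3),
    all_read_rate = c(99.1, 99.2, 99.3, 98.1, 98.2, 98.3),
    properly_mapped_rate = c(97.1, 97.2, 97.3, 96.1, 96.2, 96.3))
  res <- compare_mapping_rates(rates)
  expect_equal(nrow(res), 2)
  expect_equal(res$p_value, c(0.1, 0.1))
  expect_equal(res$higher_assembly, c("ncmd", "ncmd"))
  same <- dplyr::mutate(rates, all_read_rate = 99,
                        properly_mapped_rate = 97)
  expect_equal(compare_mapping_rates(same)$p_value, c(1, 1))
  expect_error(compare_mapping_rates(rates[c(1, 4), ]), "two samples")
  expect_error(compare_mapping_rates(dplyr::mutate(rates, assembly_id = "one")),
               "two assemblies")
})

test_that("ten-sample shifted fixture recovers the planted direction", {
  set.seed(76)
  rates <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:10), 2),
    assembly_id = rep(c("ncmd", "ref"), each = 10),
    all_read_rate = c(rnorm(10, 99.2, 0.05), rnorm(10, 98.4, 0.05)),
    properly_mapped_rate = c(rnorm(10, 97.5, 0.05), rnorm(10, 96.2, 0.05)))
  res <- compare_mapping_rates(rates)
  expect_true(all(res$p_value < 0.001))
  expect_true(all(res$higher_assembly == "ncmd"))
})

test_that("gene-density bins count gene starts per bin and type", {
  genes <- tibble::tibble(
    seq_id = "chr1", start = c(1e5, 5e5, 9.9e5, 1.5e6),
    end = start + 1e4, strand = "+",
    gene_id = sprintf("g%d", 1:4),
    type = c("protein_coding", "protein_coding", "non_coding", "protein_coding"))
  bins <- gene_density_bins(genes)
  expect_equal(bins$n_genes[bins$bin == 0 & bins$type == "protein_coding"], 2L)
  expect_equal(bins$n_genes[bins$bin == 0 & bins$type == "non_coding"], 1L)
  expect_equal(bins$n_genes[bins$bin == 1], 1L)
  expect_equal(nrow(gene_density_bins(genes[0, ])), 0)
  expect_warning(
    gene_density_bins(genes, seq_lengths = tibble::tibble(seq_id = "chr1",
                                                          length = 1.2e6)),
    "clamped")
})

test_that("planted genes round-trip through GFF3 into exact bin counts", {
  cfg <- small_config(seed = 77)
  sim <- simulate_donor(cfg)
  ann <- simulate_annotations(sim$assembly, cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_genes_gff(ann$genes, f)
  back <- read_genes_gff(f)
  expect_equal(nrow(back), nrow(ann$genes))
  expect_equal(sort(back$start), sort(ann$genes$start))
  got <- gene_density_bins(back, bin_size = 50000)
  want <- ann$genes %>%
    dplyr::mutate(bin = floor(start / 50000)) %>%
    dplyr::count(seq_id, bin, type)
  got <- dplyr::arrange(got, seq_id, bin, type)
  want <- dplyr::arrange(want, seq_id, bin, type)
  expect_equal(got$n_genes, want$n)
})
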