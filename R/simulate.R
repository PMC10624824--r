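#' Simulation configuration
#'
#' Defines a donor genome with repeat families, a degraded target with
#' planted gaps (with known fills), planted criterion violations, point
#' mutations, mate-pair fragments, and annotation fixtures. The defaults
#' are the "paper-scale-mini" study conditions used throughout the test
#' suite: a 5 Mbp donor in 5 sequences, 200 planted gaps whose deleted
#' segments are known byte-for-byte, 0.4% point divergence between the
#' two assemblies, 10% planted inversions (order/orientation failures)
#' and 10% donor N-islands (N-criterion failures), and a 10-15 kb
#' mate-pair library at 20x physical depth.
#'
#' @param seed integer seed; all outputs are deterministic per seed.
#' @param n_sequences,seq_length sequence universe (scalar `seq_length`
#'   is recycled).
#' @param repeat_units,repeat_copies repeat family unit lengths (bp) and
#'   copy numbers; copies are soft-masked lowercase and reported as BED.
#' @param repeat_gap_bias fraction of repeat copies placed inside planned
#'   gap segments (assembly gaps are repeat-driven, so closed-gap regions
#'   should be repeat-enriched).
#' @param n_gaps planted gaps, spread evenly over sequences.
#' @param segment_len_range deleted-segment length range, bp.
#' @param gap_n_frac planted N-run length as a fraction of the deleted
#'   segment (annotated gap sizes underestimate the missing sequence);
#'   floored at 20 bp.
#' @param mutation_rate per-bp substitution rate applied to the target
#'   outside N-runs.
#' @param frac_inversion,frac_n_island fractions of gaps with a planted
#'   right-flank inversion / donor flank N-island.
#' @param n_island_len donor N-island length, bp.
#' @param flank flank length F the closure stage will use; planted gaps
#'   are spaced >= 2F apart and >= F from sequence ends.
#' @param pair_insert_mean,pair_insert_sd,read_len,pair_depth mate-pair
#'   fragment model (outer spans ~ Normal, truncated at `read_len`).
#' @param pair_anomaly_frac extra anomalous pairs (cross-sequence /
#'   off-size) added to exercise the loader's discard reasons.
#' @param n_variants,variant_del_frac,variant_del_max planted variants
#'   (SNPs, plus a fraction of deletions with ref length up to
#'   `variant_del_max + 1`).
#' @param n_genes,gene_pc_frac planted genes and protein-coding fraction.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_sequences = 5,
                       seq_length = 1e6,
                       repeat_units = c(300, 600, 1500),
                       repeat_copies = c(200, 80, 30),
                       repeat_gap_bias = 0.5,
                       n_gaps = 200,
                       segment_len_range = c(500, 3000),
                       gap_n_frac = 0.2,
                       mutation_rate = 0.004,
                       frac_inversion = 0.1,
                       frac_n_island = 0.1,
                       n_island_len = 200,
                       flank = 10000,
                       pair_insert_mean = 12500,
                       pair_insert_sd = 1000,
                       read_len = 150,
                       pair_depth = 20,
                       pair_anomaly_frac = 0.05,
                       n_variants = 300,
                       variant_del_frac = 0.1,
                       variant_del_max = 4,
                       n_genes = 100,
                       gene_pc_frac = 0.7) {
  seq_length <- rep_len(seq_length, n_sequences)
  stopifnot(length(repeat_units) == length(repeat_copies),
            mutation_rate >= 0, mutation_rate <= 1,
            frac_inversion >= 0, frac_n_island >= 0,
            frac_inversion + frac_n_island <= 1,
            gap_n_frac > 0, gap_n_frac <= 1,
            read_len < pair_insert_mean)
  gaps_per_seq <- diff(round(seq(0, n_gaps, length.out = n_sequences + 1)))
  slot <- floor((seq_length - 2 * flank) / pmax(gaps_per_seq, 1))
  if (any(gaps_per_seq > 0 & slot < 2 * flank + segment_len_range[2])) {
    abort("gap plan too dense: need slot >= 2*flank + max segment length")
  }
  structure(list(
    seed = seed, n_sequences = n_sequences, seq_length = seq_length,
    repeat_units = repeat_units, repeat_copies = repeat_copies,
    repeat_gap_bias = repeat_gap_bias,
    n_gaps = n_gaps, gaps_per_seq = gaps_per_seq,
    segment_len_range = segment_len_range, gap_n_frac = gap_n_frac,
    mutation_rate = mutation_rate,
    frac_inversion = frac_inversion, frac_n_island = frac_n_island,
    n_island_len = n_island_len, flank = flank,
    pair_insert_mean = pair_insert_mean, pair_insert_sd = pair_insert_sd,
    read_len = read_len, pair_depth = pair_depth,
    pair_anomaly_frac = pair_anomaly_frac,
    n_variants = n_variants, variant_del_frac = variant_del_frac,
    variant_del_max = variant_del_max,
    n_genes = n_genes, gene_pc_frac = gene_pc_frac
  ), class = "sim_config")
}

# Deterministic gap/edit plan shared by simulate_donor() and
# degrade_to_target(): donor-coordinate segments, their N-run lengths and
# their planted violation class.
sim_plan <- function(config) {
  withr::with_seed(config$seed + 1L, {
    plan <- purrr::map_dfr(seq_len(config$n_sequences), function(si) {
      g <- config$gaps_per_seq[si]
      if (g == 0) return(NULL)
      len <- config$seq_length[si]
      slot <- floor((len - 2 * config$flank) / g)
      seg_len <- sample(config$segment_len_range[1]:config$segment_len_range[2],
                        g, replace = TRUE)
      slack <- slot - 2 * config$flank - seg_len
      jitter <- floor(stats::runif(g) * (slack + 1))
      start <- config$flank + (seq_len(g) - 1) * slot + jitter
      tibble::tibble(donor_seq = paste0("chr", si),
                     donor_start = as.integer(start),
                     donor_end = as.integer(start + seg_len),
                     seg_len = as.integer(seg_len),
                     n_len = pmax(20L, as.integer(round(config$gap_n_frac * seg_len))))
    })
    n <- nrow(plan)
    cls <- rep("closable", n)
    n_inv <- round(config$frac_inversion * n)
    n_isl <- round(config$frac_n_island * n)
    special <- sample(n, n_inv + n_isl)
    cls[special[seq_len(n_inv)]] <- "inversion"
    cls[special[seq_len(n_isl) + n_inv]] <- "n_island"
    plan$class <- cls
    plan
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a donor assembly with repeat families
#'
#' I.i.d. uniform ACGT background with repeat-family copies overlaid as
#' soft-masked lowercase (emitted as a BED-style tibble). A configurable
#' fraction of copies is placed inside the planned gap segments, so the
#' sequence later recovered by gap closing is repeat-enriched.
#'
#' @param config a [sim_config()].
#' @return list with `assembly` (donor tibble) and `repeats` (interval
#'   tibble `seq_id`, `start`, `end`, `family`).
#' @export
simulate_donor <- function(config) {
  plan <- sim_plan(config)
  withr::with_seed(config$seed + 2L, {
    seqs <- vapply(config$seq_length, random_dna, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_sequences))
    units <- vapply(config$repeat_units, random_dna, character(1))
    reps <- list()
    for (f in seq_along(units)) {
      unit <- tolower(units[f])
      ulen <- nchar(unit)
      for (cp in seq_len(config$repeat_copies[f])) {
        biased <- stats::runif(1) < config$repeat_gap_bias && nrow(plan) > 0
        if (biased) {
          seg <- plan[sample(nrow(plan), 1), ]
          sid <- seg$donor_seq
          pos <- if (seg$seg_len > ulen) {
            seg$donor_start + sample.int(seg$seg_len - ulen, 1) - 1L
          } else {
            seg$donor_start
          }
        } else {
          sid <- names(seqs)[sample(config$n_sequences, 1)]
          pos <- sample.int(nchar(seqs[[sid]]) - ulen, 1) - 1L
        }
        substr(seqs[[sid]], pos + 1L, pos + ulen) <- unit
        reps[[length(reps) + 1L]] <- tibble::tibble(
          seq_id = sid, start = pos, end = pos + ulen,
          family = paste0("fam", f))
      }
    }
    asm <- tibble::tibble(seq_id = names(seqs), header = names(seqs),
                          sequence = unname(seqs))
    rep_tbl <- if (length(reps) == 0) {
      tibble::tibble(seq_id = character(), start = integer(),
                     end = integer(), family = character())
    } else {
      dplyr::arrange(dplyr::bind_rows(reps), .data$seq_id, .data$start)
    }
    list(assembly = asm, repeats = rep_tbl)
  })
}

#' Degrade a donor into a gapped target with machine-readable truth
#'
#' Replaces each planned donor segment with an N-run (recording the
#' deleted segment as the expected fill), applies point mutations outside
#' N-runs, reverse-complements the right flank of "inversion" gaps
#' (planted order/orientation failures) and plants N-islands into the
#' donor under the left-flank image of "n_island" gaps (planted
#' N-criterion failures). Truth statuses are derived analytically from
#' the edit plan, never by running the closure pipeline.
#'
#' Because N-islands edit the donor, the (possibly modified) donor is
#' returned alongside the target.
#'
#' @param donor the donor list from [simulate_donor()] (or its
#'   `assembly` tibble).
#' @param config the same [sim_config()] used for the donor.
#' @return list with `target`, `donor` (N-island edits applied), and
#'   `truth`: a per-gap tibble with target-coordinate gap intervals,
#'   donor-coordinate segments, planted class, expected status/criterion
#'   and expected fill sequence.
#' @export
degrade_to_target <- function(donor, config) {
  if (!is.data.frame(donor)) donor <- donor$assembly
  plan <- sim_plan(config)
  flank_len <- config$flank
  target <- donor
  donor_out <- donor
  truth <- list()
  for (si in seq_len(nrow(donor))) {
    sid <- donor$seq_id[si]
    p <- plan[plan$donor_seq == sid, ]
    src <- donor$sequence[si]
    if (nrow(p) == 0) next
    pieces <- character(0)
    prev <- 0L
    t_pos <- 0L
    for (j in seq_len(nrow(p))) {
      before <- substr(src, prev + 1L, p$donor_start[j])
      pieces <- c(pieces, before, strrep("N", p$n_len[j]))
      t_start <- t_pos + nchar(before)
      t_end <- t_start + p$n_len[j]
      t_pos <- t_end
      truth[[length(truth) + 1L]] <- tibble::tibble(
        seq_id = sid, start = t_start, end = t_end, n_length = p$n_len[j],
        donor_seq_id = sid, donor_start = p$donor_start[j],
        donor_end = p$donor_end[j], class = p$class[j],
        expected_fill = substr(src, p$donor_start[j] + 1L, p$donor_end[j]))
      prev <- p$donor_end[j]
    }
    pieces <- c(pieces, substr(src, prev + 1L, nchar(src)))
    tgt <- paste(pieces, collapse = "")
    # planted inversions: reverse-complement the F bases right of the N-run
    tr <- dplyr::bind_rows(truth)
    tr <- tr[tr$seq_id == sid & tr$class == "inversion", ]
    for (j in seq_len(nrow(tr))) {
      a <- tr$end[j]
      substr(tgt, a + 1L, a + flank_len) <-
        revcomp(substr(tgt, a + 1L, a + flank_len))
    }
    target$sequence[si] <- tgt
    # planted donor N-islands under the left-flank image
    tr <- dplyr::bind_rows(truth)
    tr <- tr[tr$seq_id == sid & tr$class == "n_island", ]
    d <- donor_out$sequence[si]
    for (j in seq_len(nrow(tr))) {
      mid <- tr$donor_start[j] - round(flank_len / 2)
      substr(d, mid + 1L, mid + config$n_island_len) <-
        strrep("N", config$n_island_len)
    }
    donor_out$sequence[si] <- d
  }
  truth <- dplyr::bind_rows(truth)
  truth <- dplyr::arrange(truth, .data$seq_id, .data$start)
  truth$gap_id <- sprintf("%s:%d-%d", truth$seq_id, truth$start, truth$end)
  truth$expected_status <- dplyr::case_when(
    truth$class == "inversion" ~ "rejected",
    truth$class == "n_island" ~ "rejected",
    TRUE ~ "closed")
  truth$expected_fail <- dplyr::case_when(
    truth$class == "inversion" ~ "c3",
    truth$class == "n_island" ~ "c4",
    TRUE ~ NA_character_)
  # point mutations outside N-runs, case-preserving
  if (config$mutation_rate > 0) {
    target$sequence <- withr::with_seed(config$seed + 3L, {
      vapply(target$sequence, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        elig <- which(ch != "N" & ch != "n")
        n_mut <- stats::rbinom(1, length(elig), config$mutation_rate)
        if (n_mut == 0) return(s)
        pos <- sample(elig, n_mut)
        up <- toupper(ch[pos])
        alts <- c("A", "C", "G", "T")
        new <- vapply(up, function(b) sample(setdiff(alts, b), 1), character(1))
        lower <- ch[pos] != up
        new[lower] <- tolower(new[lower])
        ch[pos] <- new
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    })
  }
  list(target = target, donor = donor_out,
       truth = dplyr::select(truth, "gap_id", "seq_id", "start", "end",
                             "n_length", "donor_seq_id", "donor_start",
                             "donor_end", "class", "expected_status",
                             "expected_fail", "expected_fill"))
}

#' Simulate a donor/target assembly pair with truth
#'
#' Convenience wrapper around [simulate_donor()] and
#' [degrade_to_target()].
#'
#' @param config a [sim_config()].
#' @return list `donor`, `target`, `truth`, `repeats`.
#' @export
simulate_assembly_pair <- function(config = sim_config()) {
  d <- simulate_donor(config)
  deg <- degrade_to_target(d$assembly, config)
  list(donor = deg$donor, target = deg$target, truth = deg$truth,
       repeats = d$repeats)
}

#' Simulate a mate-pair library as an outer-span pair table
#'
#' Fragments are sampled uniformly along each sequence with lengths
#' `Normal(pair_insert_mean, pair_insert_sd)` truncated below at the read
#' length; the fragment count per sequence is
#' `round(pair_depth * length / pair_insert_mean)`. A fraction of extra
#' anomalous pairs (cross-sequence, too-short, too-long spans) is added,
#' and every row carries an analytic keep/discard truth label under the
#' [load_pairs()] default bounds.
#'
#' @param assembly the assembly the fragments are sampled from.
#' @param config a [sim_config()].
#' @return list with `pairs` (the pair-table tibble) and `truth`
#'   (`expected` keep/discard reason per row).
#' @export
simulate_mate_pairs <- function(assembly, config = sim_config()) {
  lens <- nchar(assembly$sequence)
  rl <- config$read_len
  withr::with_seed(config$seed + 4L, {
    rows <- purrr::map_dfr(seq_len(nrow(assembly)), function(si) {
      len <- lens[si]
      n <- round(config$pair_depth * len / config$pair_insert_mean)
      frag <- pmax(rl + 1, round(stats::rnorm(n, config$pair_insert_mean,
                                              config$pair_insert_sd)))
      frag <- pmin(frag, len)
      start <- floor(stats::runif(n) * (len - frag + 1))
      tibble::tibble(seq1 = assembly$seq_id[si], start1 = as.integer(start),
                     end1 = as.integer(start + rl), strand1 = "+",
                     seq2 = assembly$seq_id[si],
                     start2 = as.integer(start + frag - rl),
                     end2 = as.integer(start + frag), strand2 = "-")
    })
    n_anom <- round(config$pair_anomaly_frac * nrow(rows))
    if (n_anom > 0 && nrow(assembly) >= 1) {
      kinds <- rep_len(c("cross-sequence", "span-too-short", "span-too-long"),
                       n_anom)
      anom <- purrr::map_dfr(kinds, function(kind) {
        si <- sample(nrow(assembly), 1)
        len <- lens[si]
        frag <- switch(kind,
                       "span-too-short" = sample(500:3000, 1),
                       "span-too-long" = sample(30000:40000, 1),
                       sample(10000:15000, 1))
        frag <- min(frag, len)
        start <- sample.int(len - frag + 1, 1) - 1L
        sid2 <- if (kind == "cross-sequence" && nrow(assembly) > 1) {
          assembly$seq_id[-si][sample(nrow(assembly) - 1, 1)]
        } else assembly$seq_id[si]
        tibble::tibble(seq1 = assembly$seq_id[si], start1 = start,
                       end1 = start + rl, strand1 = "+",
                       seq2 = sid2, start2 = start + frag - rl,
                       end2 = start + frag, strand2 = "-")
      })
      rows <- dplyr::bind_rows(rows, anom)
    }
    span <- pmax(rows$end1, rows$end2) - pmin(rows$start1, rows$start2)
    expected <- dplyr::case_when(
      rows$seq1 != rows$seq2 ~ "cross-sequence",
      span < 5000 ~ "span-too-short",
      span > 25000 ~ "span-too-long",
      TRUE ~ "kept")
    list(pairs = rows, truth = tibble::tibble(expected = expected))
  })
}

#' Derive the truth scaffold layout of a gapped assembly
#'
#' Views each gapped sequence as a scaffold whose contigs are the
#' inter-gap stretches; gives the AGP-shaped layout truth the
#' scaffolding benchmark is tested against.
#'
#' @param assembly a gapped assembly tibble.
#' @param gaps its gap tibble ([find_gaps()]).
#' @return a scaffold-layout tibble as from [read_agp()].
#' @export
simulate_scaffold_layout <- function(assembly, gaps) {
  purrr::map_dfr(seq_len(nrow(assembly)), function(si) {
    sid <- assembly$seq_id[si]
    len <- nchar(assembly$sequence[si])
    g <- gaps[gaps$seq_id == sid, ]
    bounds <- rbind(c(0L, 0L), cbind(g$start, g$end), c(len, len))
    comp <- list()
    part <- 0L
    cno <- 0L
    for (j in seq_len(nrow(bounds) - 1)) {
      cs <- bounds[j, 2]; ce <- bounds[j + 1, 1]
      if (ce > cs) {
        part <- part + 1L; cno <- cno + 1L
        comp[[length(comp) + 1L]] <- tibble::tibble(
          scaffold = sid, start = cs, end = ce, part_number = part,
          type = "contig", component_id = sprintf("%s_ctg%d", sid, cno),
          component_start = 0L, component_end = ce - cs,
          orientation = "+", gap_length = NA_integer_,
          gap_type = NA_character_)
      }
      if (j < nrow(bounds) - 1) {
        part <- part + 1L
        comp[[length(comp) + 1L]] <- tibble::tibble(
          scaffold = sid, start = bounds[j + 1, 1], end = bounds[j + 1, 2],
          part_number = part, type = "gap", component_id = NA_character_,
          component_start = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_,
          gap_length = bounds[j + 1, 2] - bounds[j + 1, 1],
          gap_type = "scaffold")
      }
    }
    dplyr::bind_rows(comp)
  })
}

#' Simulate annotation fixtures (genes, variants, callable lengths)
#'
#' Variants are planted at non-N positions with reference alleles read
#' from the sequence (SNPs plus a fraction of short deletions);
#' per-sequence affected-base totals are therefore known exactly. Genes
#' are planted with uniform starts and typed protein-coding/non-coding.
#' Callable length = non-N length.
#'
#' @param assembly the assembly to annotate.
#' @param config a [sim_config()].
#' @return list `genes`, `variants`, `callable` tibbles.
#' @export
simulate_annotations <- function(assembly, config = sim_config()) {
  lens <- nchar(assembly$sequence)
  withr::with_seed(config$seed + 5L, {
    nv <- config$n_variants
    si <- sample(nrow(assembly), nv, replace = TRUE, prob = lens / sum(lens))
    is_del <- stats::runif(nv) < config$variant_del_frac
    ref_len <- ifelse(is_del, sample(2:(config$variant_del_max + 1), nv,
                                     replace = TRUE), 1L)
    variants <- purrr::map_dfr(seq_len(nv), function(i) {
      s <- assembly$sequence[si[i]]
      repeat {
        pos <- sample.int(lens[si[i]] - ref_len[i], 1) - 1L
        ref <- toupper(substr(s, pos + 1L, pos + ref_len[i]))
        if (!grepl("N", ref)) break
      }
      alt <- if (ref_len[i] == 1) {
        sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      } else {
        substr(ref, 1, 1)
      }
      tibble::tibble(seq_id = assembly$seq_id[si[i]], pos = pos,
                     ref = ref, alt = alt, ref_len = nchar(ref))
    })
    variants <- dplyr::arrange(variants, .data$seq_id, .data$pos)
    gi <- sample(nrow(assembly), config$n_genes, replace = TRUE,
                 prob = lens / sum(lens))
    glen <- sample(5000:50000, config$n_genes, replace = TRUE)
    gstart <- vapply(seq_len(config$n_genes), function(i) {
      sample.int(max(1L, lens[gi[i]] - glen[i]), 1) - 1L
    }, numeric(1))
    genes <- tibble::tibble(
      seq_id = assembly$seq_id[gi],
      start = as.integer(gstart),
      end = as.integer(pmin(gstart + glen, lens[gi])),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
      type = ifelse(stats::runif(config$n_genes) < config$gene_pc_frac,
                    "protein_coding", "non_coding")
    ) %>% dplyr::arrange(.data$seq_id, .data$start)
    callable <- tibble::tibble(
      seq_id = assembly$seq_id,
      callable_bases = vapply(assembly$sequence, function(s)
        nchar(gsub("[Nn]", "", s)), numeric(1), USE.NAMES = FALSE))
    list(genes = genes, variants = variants, callable = callable)
  })
}

#' Write a variant tibble as a minimal VCF
#'
#' @param variants tibble with `seq_id`, `pos` (0-based), `ref`, `alt`.
#' @param path output VCF.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                     variants$seq_id, variants$pos + 1L,
                     variants$ref, variants$alt))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene tibble as GFF3
#'
#' @param genes tibble with `seq_id`, `start` (0-based), `end`, `strand`,
#'   `gene_id`, `type`.
#' @param path output GFF3.
#' @return `path`, invisibly.
#' @export
write_genes_gff <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=%s",
                     genes$seq_id, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id, genes$type))
  writeLines(lines, path)
  invisible(path)
}
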