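---
title: "Reference-guided gap closing and assembly concordance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided gap closing and assembly concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfillr)
```

## The problem

A draft genome assembly records unresolved sequence as runs of `N`
("gaps"). When a second, higher-contiguity assembly of the same species
exists — here the chromosome-level NCMD assembly of the Nanchukmacdon
pig breed, used against the pig reference Sscrofa11.1 — its sequence can
be used to close those gaps: the up-to-10-kb flanks of each gap are
placed in the donor assembly, and when both flanks land uniquely,
colinearly and confidently, the donor sequence between them replaces the
N-run. gapfillr implements that closure procedure together with the
surrounding evaluation toolkit: base-level concordance in synteny
blocks, synteny coverage, assembly QV, windowed repeat-ratio
comparisons, mate-pair physical coverage at scaffold joins, and a
seeded synthetic-genome generator that makes every stage testable
without external data.

All coordinates inside the package are 0-based half-open; AGP input and
human-readable reports are converted at the boundary (1-based
inclusive). Strand is `{+,-}`, and minus-strand inputs (MAF rows,
reversed coordinate tables) are normalized to forward-strand intervals
at parse time so downstream code never sees reverse-complement
coordinates. Soft-mask case is preserved end to end because the
repeat-ratio windows read it; all base comparisons elsewhere are
case-insensitive.

## The closure criteria

For each gap, `extract_flanks()` takes the up-to-F (default 10,000 bp)
bases on each side, truncating at sequence bounds and at adjacent
annotated gaps; `evaluate_gaps()` then chooses one best alignment per
flank and applies four criteria:

* **c1 — length**: each chosen alignment covers *strictly more than*
  `min_aln_len` (default 5,000) bp of its flank. An alignment of exactly
  5,000 bp fails.
* **c2 — identity**: the mean of the two chosen alignments' percent
  identities is *strictly greater than* `min_mean_identity` (default
  90). The mean is over the two chosen records only, matching the
  per-flank phrasing of the criterion; identity counts gap columns in
  its denominator (aligned columns include indels), the convention of
  show-coords-style tables.
* **c3 — order and orientation**: both flanks place on the same donor
  sequence, on the same strand, with the left flank's donor interval
  entirely before the right one on `+` (reversed on `-`). The
  same-sequence requirement is implied rather than stated by the
  criterion's usual phrasing, but without it no fill interval exists.
* **c4 — N-free donor**: the donor bases under the two chosen
  alignments contain no N. The check deliberately covers only the
  aligned donor intervals; `require_fill_n_free = TRUE` extends it to
  the fill itself for users who want guaranteed N-free closures.

A gap with a missing flank (at a sequence end) or with no alignment on
either side is *unevaluable* rather than rejected, so the rejection
histogram reflects genuine criterion failures.

**Fill projection.** The procedure that turns two flank placements into
a fill interval is a design choice of this package: each alignment's
gap-proximal end is projected into the donor and extended by the
unaligned gap-proximal tail of its flank, because those tail bases are
target sequence that must not be represented twice. If the two
projections cross, the fill is empty and the overlap is tolerated up to
`max_overlap` (default 0 — any crossing rejects, with the auditable
reason code `fill-overlap`). Closures are applied per sequence in
descending coordinate order so earlier coordinates stay valid, and the
report carries old and new coordinates for every gap.

## The built-in flank aligner

The aligner is a deterministic stand-in for an external whole-genome
aligner at flank scale, not a NUCmer clone; for reproducing externally
computed placements bit-for-bit, the coordinate-table reader
(`read_coords()`) is the fidelity path. Its contract:

1. exact k-mer anchors (default k = 15, mirroring the minimum-match
   length such runs typically use; k-mers containing N never anchor) on
   both strands, against a donor index built once;
2. greedy colinear chaining of anchors on the same donor sequence and
   strand, with inter-anchor gaps at most `max_anchor_gap` (500 bp) and
   a diagonal-drift tolerance (`diag_tol`, 100 bp) that admits short
   indels while keeping chains deterministic;
3. clusters whose anchored query span reaches `min_cluster` (25 bp,
   mirroring a minimum cluster length) are kept;
4. each kept cluster's spanned substrings are aligned by banded global
   alignment (match +1, mismatch −1, gap −2, N matches nothing) with
   band half-width `0.2 × span` (floored at 16), taken around the
   end-gap-adjusted diagonal. When the two substrings are identical and
   N-free the alignment is returned directly — the diagonal is provably
   optimal under this scoring, and the shortcut is what makes
   zero-divergence recovery runs fast.

Output order (descending query coverage, then descending identity, then
donor coordinates) is fully specified, so `best_alignment()` is
deterministic across platforms, and a flank aligning to both strands
yields separate records that are never merged. The mapping of these
parameters onto any particular external aligner's flags is conjectural;
they are exposed so users can match their own settings.

## Concordance statistics and synteny coverage

`count_match_mismatch()` walks pairwise alignment blocks column by
column. Columns with a gap in either row are excluded from both counts —
in a match/mismatch table whose "Total" is match + mismatch, indel
columns cannot be in the denominator. N against anything (including N)
counts as mismatch by default, the conservative reading; `skip_n`
excludes such columns instead. Overlapping blocks warn and are counted
as given, with `dedup` available to greedily enforce a non-overlapping
A-side subset, covering both readings of how overlapping synteny blocks
should be counted. Synteny coverage is the merged-union length of block
intervals divided by the genome size.

## QV and mapping rates

`compute_qv()` is the standard `−10·log10(error/callable)` with a cap
(default 60) for zero-error sequences, where the raw value diverges; the
cap is configurable and raw counts are always reported so other
conventions can be re-derived. A variant contributes its
reference-allele length in error bases (SNP 1, deletion its length,
insertion the single anchor base) — the upstream convention is not
standardized, which is why the counts stay visible. Mapping-rate
comparisons between two assemblies reuse the Mann-Whitney engine per
metric and report the direction of the median difference.

## The Mann-Whitney engine

`mwu_test()` computes the two-sided Mann-Whitney U. With both groups at
most 8 observations the p-value comes from exact enumeration of all
`C(n1+n2, n1)` labelings of the pooled values (ties are handled
naturally because the enumeration works on the actual values; the
two-sided p is twice the smaller tail, capped at 1). Larger samples use
the normal approximation with tie-corrected variance and a continuity
correction of **0.6**. The correction was calibrated once, exhaustively,
against the exact engine at n = 8/8: with the textbook 0.5 the
worst-case two-sided disagreement over all attainable U is 0.0109,
concentrated at mid-range U; 0.6 brings it to 0.0074, and the
correction's influence vanishes as n grows. `stats::wilcox.test` serves
as an independent cross-check in the test suite, never as the
implementation.

Windowed repeat ratios tile each sequence with non-overlapping windows
(default 50,000 bp, the scale at which repeat context around closed
gaps is usually examined), drop terminal fragments shorter than half a
window and windows with no non-N bases, and use the non-N length as
denominator. A window joins the closed-gap group when it overlaps any
closed-gap interval by at least 1 bp — the simplest defensible mapping
from regions to windows.

## Scaffolding benchmark

Physical (fragment) coverage at a position is the number of mate-pair
outer spans containing it, computed with a difference array and prefix
sums; the per-gap statistic is the mean depth over the gap interval,
with a midpoint mode and a span-the-whole-gap mode available for
sensitivity analysis, since the position-wise reading is an
interpretation. Pair loading keeps mates on one sequence with outer
spans inside `[insert_min, insert_max]` (defaults 5,000–25,000 bp,
bracketing a 10–15 kb mate-pair library) and tallies every discard by
reason; these bounds change every downstream number and are therefore
carried into output metadata. A contig counts as "connected" during
scaffolding iff its scaffold holds at least two contig components.

## The synthetic generator

`simulate_assembly_pair()` produces the study conditions every pipeline
stage is tested under ("paper-scale-mini"):

* a 5 Mbp donor in 5 sequences of i.i.d. uniform ACGT, with three
  repeat families (units 300/600/1,500 bp; 200/80/30 copies) overlaid
  as soft-masked lowercase — about 3% repeat content, deliberately
  modest so anchor statistics stay desk-scale;
* 200 planted gaps: deleted segments of U(500, 3000) bp replaced by
  N-runs of 20% of the segment length (floored at 20 bp), because
  annotated gap lengths systematically understate the sequence that is
  actually missing — at full scale, megabases of recovered sequence
  stand against a much smaller annotated N total;
* half of all repeat copies are planted inside the deleted segments, so
  closed-gap regions are repeat-enriched, as they are in real
  assemblies where repeats are what broke the assembly in the first
  place;
* point mutations at 0.004/bp between donor and target — the scale of
  the observed base-level divergence between two assemblies of the same
  species (a match ratio around 0.996);
* 10% of gaps carry a reverse-complemented right flank (an
  order/orientation violation that must trip c3) and 10% a 200-bp
  N-island planted into the donor under the left-flank image (which
  must trip c4). Because N-islands edit the donor, the generator
  returns the edited donor alongside the target;
* a mate-pair library with outer spans ~ Normal(12,500, 1,000) bp,
  150-bp reads and 20× physical depth, plus 5% planted anomalous pairs
  (cross-sequence, off-size) carrying analytic keep/discard labels;
* planted variants with reference alleles read from the sequence (so
  per-sequence affected-base totals are exact) and planted genes with
  known starts and biotypes.

Truth statuses are derived analytically from the edit plan — never by
running the pipeline — so a generator bug and a pipeline bug cannot
cancel; the per-base identity oracle used in tests is a third, separate
implementation. Gaps are spaced at least 2F apart and F from sequence
ends, so flanks never overlap; this is a *validity* condition of the
planted truth, not a claim about real gap spacing.

What the generator does not emulate: sequencing errors and read-level
artifacts, indels between the assemblies (divergence is
substitution-only, which also means the aligner's indel handling is
exercised only by its own unit tests), heterozygosity/diploidy,
large-scale rearrangements beyond the planted flank inversions, and
biological repeat families with internal divergence. Passing the
recovery tests therefore demonstrates the correctness of the decision
logic and coordinate arithmetic under controlled conditions, not the
aligner's robustness to every kind of real-data divergence — for real
data at full scale, the coordinate-ingestion path exists precisely so a
production aligner can stand in.

## Problem sizes and numerical choices

The test suite runs the full mini fixture (5 Mbp, 200 gaps) for the
recovery and threshold-sweep checks and a 0.3 Mbp, 4-gap variant for
unit tests; the boundary-behavior fixture plants 20 gaps with
violations on a 0.52 Mbp sequence. Randomized property tests
(interval-union, gap-scan, coverage, counting oracles) run hundreds to
a thousand instances at small axis sizes under fixed seeds. Determinism
is part of every contract: identical seeds give byte-identical FASTA,
pair tables and truth files.

Degenerate inputs are handled explicitly rather than incidentally:
empty assemblies write empty FASTA; empty interval sets merge to empty;
an all-N flank yields no anchors and hence an empty alignment list;
zero-variant sequences report the QV cap; empty window groups and
single-assembly rate tables are errors, not silent NAs.

## Known limitations

* The built-in aligner chains on a single diagonal family per cluster;
  highly diverged or heavily rearranged flanks are better served by an
  external aligner via `read_coords()`.
* `best_alignment()` uses one record per flank; fragmented-but-colinear
  placements are not chained into a composite placement, so a flank
  split by a large donor insertion may fail c1 even when its pieces are
  consistent.
* Physical coverage assumes pre-computed mate placements; no duplicate
  marking or mapping-quality filtering is applied beyond the documented
  span/orientation rules.
* The QV path trusts the caller's callable-site definition; it does not
  recompute callability from alignments.
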