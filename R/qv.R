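#' Assembly quality value (QV)
#'
#' `QV = -10 * log10(error_bases / callable_bases)`, capped at `cap` for
#' zero-error sequences (where the raw value diverges). Vectorized.
#'
#' @param error_bases estimated erroneous bases (e.g. bases affected by
#'   variants called from same-individual reads).
#' @param callable_bases bases where an error could have been observed
#'   (> 0).
#' @param cap upper bound returned for zero errors (default 60).
#' @return numeric QV values.
#' @examples
#' compute_qv(1, 1e4)   # 40
#' @export
compute_qv <- function(error_bases, callable_bases, cap = 60) {
  if (any(callable_bases <= 0)) abort("callable_bases must be > 0")
  if (any(error_bases < 0 | error_bases > callable_bases)) {
    abort("error_bases must be in [0, callable_bases]")
  }
  pmin(cap, -10 * log10(error_bases / callable_bases))
}

#' Per-sequence QV from a variant and a callable-length table
#'
#' Error bases per variant = reference-allele length (SNP 1, deletion its
#' length, insertion the 1 anchor base); raw counts are kept in the
#' output so other conventions can be re-derived.
#'
#' @param variants tibble with `seq_id` and either `ref` (reference
#'   allele strings) or `ref_len`.
#' @param callable tibble with `seq_id`, `callable_bases`.
#' @param cap QV cap (default 60); sequences with zero variants report
#'   the cap.
#' @return tibble `seq_id`, `error_bases`, `callable_bases`, `qv`.
#' @export
qv_per_sequence <- function(variants, callable, cap = 60) {
  if (!("ref_len" %in% names(variants))) {
    variants <- dplyr::mutate(variants, ref_len = nchar(.data$ref))
  }
  unknown <- setdiff(unique(variants$seq_id), callable$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("variant on sequence(s) absent from callable table: ",
                 paste(unknown, collapse = ", ")))
  }
  err <- variants %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::summarise(error_bases = sum(.data$ref_len), .groups = "drop")
  callable %>%
    dplyr::left_join(err, by = "seq_id") %>%
    dplyr::mutate(error_bases = dplyr::coalesce(.data$error_bases, 0),
                  qv = compute_qv(.data$error_bases, .data$callable_bases,
                                  cap = cap)) %>%
    dplyr::select("seq_id", "error_bases", "callable_bases", "qv")
}

#' Read a minimal VCF into a variant tibble
#'
#' Only CHROM/POS/REF/ALT are used; `ref_len` is the reference-allele
#' length.
#'
#' @param path VCF file.
#' @return tibble `seq_id`, `pos` (0-based), `ref`, `alt`, `ref_len`.
#' @export
read_variants_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  tibble::tibble(seq_id = fix$CHROM,
                 pos = as.integer(fix$POS) - 1L,
                 ref = fix$REF, alt = fix$ALT,
                 ref_len = nchar(fix$REF))
}

#' Read a variant TSV (columns `seq_id`, `ref_len` at minimum)
#'
#' @param path TSV file with a header row.
#' @return a variant tibble.
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
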