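#' Read gene-level features from a GFF3 file
#'
#' Keeps `gene` features and classifies them as `protein_coding` or
#' `non_coding` from a configurable attribute key (any biotype other than
#' `protein_coding` maps to `non_coding`).
#'
#' @param path GFF3 file.
#' @param type_attribute attribute key carrying the biotype
#'   (default `"gene_biotype"`).
#' @return tibble `seq_id`, `start` (0-based), `end`, `strand`,
#'   `gene_id`, `type`.
#' @export
read_genes_gff <- function(path, type_attribute = "gene_biotype") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[as.character(g$type) == "gene"]
  bio <- if (type_attribute %in% names(S4Vectors::mcols(g))) {
    as.character(S4Vectors::mcols(g)[[type_attribute]])
  } else {
    rep(NA_character_, length(g))
  }
  tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    gene_id = if (!is.null(g$ID)) as.character(g$ID) else NA_character_,
    type = ifelse(!is.na(bio) & bio == "protein_coding",
                  "protein_coding", "non_coding")
  )
}

#' Count genes per genomic bin and type
#'
#' Each gene is assigned to the bin containing its start coordinate (a
#' gene is counted once, matching "number of genes per bin" semantics,
#' rather than overlap-weighted).
#'
#' @param genes tibble with `seq_id`, `start` (0-based) and `type`.
#' @param bin_size bin width in bp (default 1e6).
#' @param seq_lengths optional tibble (`seq_id`, `length`); when given,
#'   gene starts beyond the sequence end are clamped into the last bin
#'   with a warning.
#' @return tibble `seq_id`, `bin` (0-based index), `bin_start`,
#'   `bin_end`, `type`, `n_genes`.
#' @export
gene_density_bins <- function(genes, bin_size = 1e6, seq_lengths = NULL) {
  stopifnot(bin_size >= 1)
  if (nrow(genes) == 0) {
    return(tibble::tibble(seq_id = character(), bin = integer(),
                          bin_start = numeric(), bin_end = numeric(),
                          type = character(), n_genes = integer()))
  }
  start <- genes$start
  if (!is.null(seq_lengths)) {
    len <- seq_lengths$length[match(genes$seq_id, seq_lengths$seq_id)]
    over <- !is.na(len) & start >= len
    if (any(over)) {
      warn(sprintf("%d gene start(s) beyond sequence end; clamped", sum(over)))
      start[over] <- len[over] - 1
    }
  }
  genes %>%
    dplyr::mutate(bin = as.integer(floor(.env$start / bin_size))) %>%
    dplyr::count(.data$seq_id, .data$bin, .data$type, name = "n_genes") %>%
    dplyr::mutate(bin_start = .data$bin * bin_size,
                  bin_end = (.data$bin + 1) * bin_size) %>%
    dplyr::select("seq_id", "bin", "bin_start", "bin_end", "type", "n_genes") %>%
    dplyr::arrange(.data$seq_id, .data$bin, .data$type)
}
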