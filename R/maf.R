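#' Read pairwise alignment blocks from a MAF file
#'
#' Only strictly pairwise MAF is accepted: each `a` block must contain
#' exactly two `s` rows. Minus-strand MAF coordinates (which count from
#' the reverse-strand 5' end) are normalized to forward-strand 0-based
#' half-open intervals at parse time; the gapped alignment texts are kept
#' verbatim.
#'
#' @param path MAF file.
#' @return a tibble of aligned blocks with columns `block_id`, and for
#'   each row (`a_`/`b_` prefixes): `seq`, `start`, `end`, `strand`,
#'   `src_size`, `text`.
#' @export
read_maf_blocks <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  a_idx <- grep("^a", lines)
  parse_s <- function(line) {
    x <- strsplit(trimws(line), "\\s+")[[1]]
    start <- as.numeric(x[3]); size <- as.numeric(x[4])
    src_size <- as.numeric(x[6])
    fstart <- if (x[5] == "-") src_size - start - size else start
    list(seq = x[2], start = fstart, end = fstart + size, strand = x[5],
         src_size = src_size, text = x[7])
  }
  blocks <- purrr::imap_dfr(a_idx, function(ai, bi) {
    j <- ai + 1L
    srows <- list()
    while (j <= length(lines) && !grepl("^a", lines[j])) {
      if (grepl("^s ", lines[j])) srows[[length(srows) + 1L]] <- lines[j]
      j <- j + 1L
    }
    if (length(srows) != 2) {
      abort(sprintf("MAF block %d: expected exactly 2 's' rows, found %d",
                    bi, length(srows)))
    }
    a <- parse_s(srows[[1]]); b <- parse_s(srows[[2]])
    if (nchar(a$text) != nchar(b$text)) {
      abort(sprintf("MAF block %d: gapped row lengths differ", bi))
    }
    ungapped <- function(r) nchar(gsub("-", "", r$text, fixed = TRUE))
    if (ungapped(a) != a$end - a$start || ungapped(b) != b$end - b$start) {
      abort(sprintf("MAF block %d: row size does not match ungapped text", bi))
    }
    tibble::tibble(block_id = bi,
                   a_seq = a$seq, a_start = a$start, a_end = a$end,
                   a_strand = a$strand, a_src_size = a$src_size, a_text = a$text,
                   b_seq = b$seq, b_start = b$start, b_end = b$end,
                   b_strand = b$strand, b_src_size = b$src_size, b_text = b$text)
  })
  blocks
}

#' Write pairwise alignment blocks to MAF
#'
#' Inverse of [read_maf_blocks()] (forward-strand coordinates are
#' converted back to MAF's strand-relative starts).
#'
#' @param blocks a block tibble as returned by [read_maf_blocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  s_line <- function(seq, start, end, strand, src_size, text) {
    size <- end - start
    mstart <- if (strand == "-") src_size - end else start
    sprintf("s %s %d %d %s %d %s", seq, mstart, size, strand, src_size, text)
  }
  for (i in seq_len(nrow(blocks))) {
    r <- blocks[i, ]
    writeLines(c("", "a score=0",
                 s_line(r$a_seq, r$a_start, r$a_end, r$a_strand, r$a_src_size, r$a_text),
                 s_line(r$b_seq, r$b_start, r$b_end, r$b_strand, r$b_src_size, r$b_text)),
               con)
  }
  invisible(path)
}
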