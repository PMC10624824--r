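#' Assembly tibbles
#'
#' An assembly is represented as a tibble with one row per sequence and
#' columns `seq_id` (the first whitespace-delimited token of the FASTA
#' header), `header` (the full header line without `>`), and `sequence`
#' (the nucleotide string, case preserved: lowercase marks soft-masked
#' repeat sequence). The alphabet is restricted to `A,C,G,T,N` in either
#' case; all coordinates used throughout the package are 0-based
#' half-open.
#'
#' @param seqs named character vector of sequences.
#' @return an assembly tibble.
#' @examples
#' assembly(c(chr1 = "ACGTNNNNNACGT"))
#' @export
assembly <- function(seqs) {
  if (length(seqs) == 0) {
    return(tibble::tibble(seq_id = character(), header = character(),
                          sequence = character()))
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("every sequence must have a non-empty name")
  }
  asm <- tibble::tibble(seq_id = ids, header = ids,
                        sequence = unname(as.character(seqs)))
  validate_assembly(asm)
  asm
}

validate_assembly <- function(asm, map_ambiguous = FALSE) {
  dup <- asm$seq_id[duplicated(asm$seq_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(asm$seq_id))) abort("empty sequence id")
  for (i in seq_len(nrow(asm))) {
    bad <- stringr::str_locate(asm$sequence[i], "[^ACGTNacgtn]")[1, "start"]
    if (!is.na(bad)) {
      ch <- substr(asm$sequence[i], bad, bad)
      if (map_ambiguous && grepl("[RYSWKMBDHVryswkmbdhv]", ch)) {
        asm$sequence[i] <- stringr::str_replace_all(
          asm$sequence[i], "[RYSWKMBDHV]", "N")
        asm$sequence[i] <- stringr::str_replace_all(
          asm$sequence[i], "[ryswkmbdhv]", "n")
        next
      }
      abort(sprintf("illegal character '%s' in sequence '%s' at offset %d",
                    ch, asm$seq_id[i], bad))
    }
  }
  invisible(asm)
}

#' Sequence lengths of an assembly
#'
#' @param assembly an assembly tibble (see [assembly()]).
#' @return tibble with columns `seq_id`, `length`.
#' @export
seq_lengths <- function(assembly) {
  tibble::tibble(seq_id = assembly$seq_id,
                 length = nchar(assembly$sequence))
}

#' Read a (multi-)FASTA file into an assembly tibble
#'
#' Record order and base case are preserved. Sequence ids are the first
#' token of each header; the full header is kept in the `header` column.
#' Characters outside `{A,C,G,T,N,a,c,g,t,n}` are rejected unless
#' `map_ambiguous = TRUE`, in which case IUPAC ambiguity codes are mapped
#' to N (case kept).
#'
#' @param path FASTA file.
#' @param map_ambiguous map IUPAC ambiguity codes to N instead of erroring.
#' @return an assembly tibble.
#' @export
read_fasta <- function(path, map_ambiguous = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0) {
    return(assembly(character()))
  }
  headers <- vapply(recs, function(r) sub("^>", "", attr(r, "Annot")),
                    character(1))
  asm <- tibble::tibble(
    seq_id = unname(vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)),
    header = unname(headers),
    sequence = unname(vapply(recs, function(r) as.character(r[[1]]),
                             character(1)))
  )
  asm <- validate_assembly(asm, map_ambiguous = map_ambiguous)
  asm
}

#' Write an assembly tibble to FASTA
#'
#' Round-trips with [read_fasta()] modulo line wrapping.
#'
#' @param assembly an assembly tibble.
#' @param path output file.
#' @param line_width bases per line (>= 1, default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, line_width = 60) {
  stopifnot(line_width >= 1)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(assembly))) {
    writeLines(paste0(">", assembly$header[i]), con)
    s <- assembly$sequence[i]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1L, n, by = line_width)
      writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Reverse complement
#'
#' Case-preserving reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# slice a sequence 0-based half-open
seq_slice <- function(assembly, seq_id, start, end) {
  s <- assembly$sequence[match(seq_id, assembly$seq_id)]
  if (is.na(s)) abort(paste0("unknown sequence id: ", seq_id))
  substr(s, start + 1L, end)
}
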