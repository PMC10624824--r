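#' Read an AGP v2.x scaffold layout
#'
#' AGP's 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention at the boundary. Components must tile
#' each scaffold without gaps or overlaps (AGP's own invariant); a
#' violation is an error naming the scaffold and line.
#'
#' @param path AGP v2.0/2.1 file.
#' @return a scaffold-layout tibble with columns `scaffold`, `start`,
#'   `end` (scaffold coordinates), `part_number`, `type`
#'   (`"contig"`/`"gap"`), `component_id`, `component_start`,
#'   `component_end` (contig coordinates), `orientation`, `gap_length`,
#'   `gap_type`.
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), part_number = integer(),
                          type = character(), component_id = character(),
                          component_start = integer(), component_end = integer(),
                          orientation = character(), gap_length = integer(),
                          gap_type = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2_dfr(f, lineno, function(x, ln) {
    if (length(x) < 8) abort(sprintf("AGP line %d: expected >= 8 columns", ln))
    ctype <- x[5]
    is_gap <- ctype %in% c("N", "U")
    tibble::tibble(
      scaffold = x[1],
      start = as.integer(x[2]) - 1L,
      end = as.integer(x[3]),
      part_number = as.integer(x[4]),
      type = if (is_gap) "gap" else "contig",
      component_id = if (is_gap) NA_character_ else x[6],
      component_start = if (is_gap) NA_integer_ else as.integer(x[7]) - 1L,
      component_end = if (is_gap) NA_integer_ else as.integer(x[8]),
      orientation = if (is_gap) NA_character_ else
        (if (length(x) >= 9 && x[9] %in% c("+", "-")) x[9] else "+"),
      gap_length = if (is_gap) as.integer(x[6]) else NA_integer_,
      gap_type = if (is_gap && length(x) >= 7) x[7] else NA_character_,
      .line = ln
    )
  })
  rows <- dplyr::arrange(rows, .data$scaffold, .data$start)
  for (sc in unique(rows$scaffold)) {
    r <- rows[rows$scaffold == sc, ]
    if (r$start[1] != 0L) {
      abort(sprintf("AGP scaffold '%s': components do not tile (line %d)",
                    sc, r$.line[1]))
    }
    if (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)])) {
      i <- which(r$start[-1] != r$end[-nrow(r)])[1] + 1L
      abort(sprintf("AGP scaffold '%s': components do not tile (line %d)",
                    sc, r$.line[i]))
    }
    bad <- which(!is.na(r$component_id) &
                   (r$component_end - r$component_start) != (r$end - r$start))
    if (length(bad) > 0) {
      abort(sprintf("AGP scaffold '%s': component span mismatch (line %d)",
                    sc, r$.line[bad[1]]))
    }
  }
  dplyr::select(rows, -".line")
}

#' Write a scaffold layout to AGP v2.1
#'
#' Inverse of [read_agp()]; internal 0-based half-open coordinates are
#' converted back to AGP's 1-based inclusive convention.
#'
#' @param layout a scaffold-layout tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  layout <- dplyr::arrange(layout, .data$scaffold, .data$start)
  lines <- c("##agp-version\t2.1")
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    if (r$type == "gap") {
      lines <- c(lines, paste(r$scaffold, r$start + 1L, r$end, r$part_number,
                              "N", r$end - r$start,
                              ifelse(is.na(r$gap_type), "scaffold", r$gap_type),
                              "yes", "paired-ends", sep = "\t"))
    } else {
      lines <- c(lines, paste(r$scaffold, r$start + 1L, r$end, r$part_number,
                              "W", r$component_id, r$component_start + 1L,
                              r$component_end, r$orientation, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
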