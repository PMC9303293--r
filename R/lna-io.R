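#' Parse "+N" LNA notation
#'
#' In probe files an LNA nucleoside is written with a "+" prefix, e.g.
#' `"T+C+C+C+TCCTCC"` is the 10-mer TCCCTCCTCC with LNA at positions 2-5.
#'
#' @param text A single string matching `((\\+)?[ACGT])+` (case-insensitive).
#' @return List with `bases` (plain DNA string) and `lna_mask` (1-based
#'   integer positions).
#' @seealso [format_lna_sequence()] for the exact inverse.
#' @export
parse_lna_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(gsub("\\s", "", text))
  if (!nzchar(text) || !grepl("^(\\+?[ACGT])+$", text)) {
    abort(sprintf("Invalid LNA sequence notation: '%s'.", text),
          class = "g4_error_parse")
  }
  toks <- regmatches(text, gregexpr("\\+?[ACGT]", text))[[1]]
  list(bases = paste(sub("^\\+", "", toks), collapse = ""),
       lna_mask = which(startsWith(toks, "+")))
}

#' Write "+N" LNA notation
#'
#' @param bases Plain DNA string.
#' @param lna_mask 1-based LNA positions.
#' @return A single string; `parse_lna_sequence()` inverts it exactly.
#' @export
format_lna_sequence <- function(bases, lna_mask) {
  bases <- validate_dna(bases, "bases")
  lna_mask <- as.integer(lna_mask)
  if (any(lna_mask < 1 | lna_mask > nchar(bases))) {
    abort("`lna_mask` positions outside the sequence.", class = "g4_error_parse")
  }
  ch <- strsplit(bases, "")[[1]]
  ch[lna_mask] <- paste0("+", ch[lna_mask])
  paste(ch, collapse = "")
}

#' Read / write probe FASTA with LNA notation
#'
#' FASTA-like records whose sequence line carries the "+N" LNA notation.
#' Plain FASTA (no "+") parses identically, so the same reader serves for
#' unmodified sequences. Read/write round-trips are bit-exact.
#'
#' @param path File path.
#' @return `read_lna_fasta()`: tibble with columns `name`, `bases`,
#'   `lna_mask` (list column), `lna` (notation string).
#' @export
read_lna_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) abort("Not a FASTA file (no leading '>' header).",
                                  class = "g4_error_parse")
  idx <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste, character(1), collapse = "")
  parsed <- lapply(unname(seqs), parse_lna_sequence)
  tibble(name = names,
         bases = vapply(parsed, `[[`, character(1), "bases"),
         lna_mask = lapply(parsed, `[[`, "lna_mask"),
         lna = unname(seqs))
}

#' @param probes Tibble as returned by [read_lna_fasta()] or
#'   [g4_probe_catalog()], or a list of `g4_probe` objects.
#' @rdname read_lna_fasta
#' @export
write_lna_fasta <- function(probes, path) {
  if (is.list(probes) && !is.data.frame(probes)) {
    probes <- dplyr::bind_rows(lapply(probes, tibble::as_tibble))
  }
  lines <- unlist(purrr::map2(probes$name,
                              purrr::map2_chr(probes$bases, probes$lna_mask,
                                              format_lna_sequence),
                              ~ c(paste0(">", .x), .y)))
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular assay inputs
#'
#' Thin readr wrappers for the package's CSV dialects (comma-separated,
#' "." decimal, mandatory header): kinetic traces (`time_s,signal_au`),
#' melting curves (`temp_C,abs260`), force-extension cycles
#' (`force_pN,extension_nm,phase`), gel lane profiles
#' (`position,intensity`) and reporter wells
#' (`condition,renilla,firefly,...`).
#'
#' @param path CSV file path.
#' @return A tibble with the expected columns (validated).
#' @name g4_read
NULL

read_csv_checked <- function(path, required) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  basename(path), paste(missing, collapse = ", ")),
          class = "g4_error_parse")
  }
  df
}

#' @rdname g4_read
#' @export
read_trace_csv <- function(path) read_csv_checked(path, c("time_s", "signal_au"))

#' @rdname g4_read
#' @export
read_melt_csv <- function(path) read_csv_checked(path, c("temp_C", "abs260"))

#' @rdname g4_read
#' @export
read_cycle_csv <- function(path) {
  df <- read_csv_checked(path, c("force_pN", "extension_nm", "phase"))
  bad <- setdiff(unique(df$phase), c("stretch", "relax"))
  if (length(bad)) abort(sprintf("Unknown phase label(s): %s.",
                                 paste(bad, collapse = ", ")),
                         class = "g4_error_parse")
  df
}

#' @rdname g4_read
#' @export
read_lane_csv <- function(path) read_csv_checked(path, c("position", "intensity"))

#' @rdname g4_read
#' @export
read_wells_csv <- function(path) read_csv_checked(path, c("condition", "renilla", "firefly"))
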