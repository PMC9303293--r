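#' @keywords internal
#' @noRd
validate_dna <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("`%s` must be a single non-empty DNA string.", arg),
          class = "g4_error_alphabet")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    abort(sprintf("`%s` contains non-ACGT characters: %s. Degenerate IUPAC codes are not expanded.",
                  arg, paste(bad, collapse = ", ")),
          class = "g4_error_alphabet")
  }
  seq
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement, written 5'->3'. An invader probe is the
#' reverse complement of the G4-forming strand it targets.
#'
#' @param seq Single DNA string over A/C/G/T (case-insensitive).
#' @return A single uppercase DNA string.
#' @examples
#' reverse_complement("GGGTTAGGGTTAGGGTTAGGG")
#' @export
reverse_complement <- function(seq) {
  seq <- validate_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Annotate G-tracts and loops in a G4-forming sequence
#'
#' Finds all maximal runs of guanine of length at least `min_run` (the
#' G-tracts contributing to the tetrad core) and the loop intervals between
#' consecutive tracts. Coordinates are 1-based inclusive, on the given
#' strand, 5'->3'.
#'
#' @param seq Single DNA string over A/C/G/T.
#' @param min_run Minimum guanines per tract (default 3, one per tetrad
#'   layer of a three-layer G4).
#' @param id Optional label for the sequence.
#' @return A `g4_target` object: list with `id`, `bases`, `min_run`, and
#'   tibbles `tracts` and `loops` (columns `start`, `end`).
#' @examples
#' find_g_tracts("GGGTTAGGGTTAGGGTTAGGG", id = "hTelo")
#' @export
find_g_tracts <- function(seq, min_run = 3, id = NULL) {
  bases <- validate_dna(seq)
  stopifnot(is.numeric(min_run), min_run >= 1)
  m <- gregexpr(sprintf("G{%d,}", as.integer(min_run)), bases)[[1]]
  if (m[1] == -1L) {
    tracts <- tibble(start = integer(), end = integer())
  } else {
    tracts <- tibble(start = as.integer(m),
                     end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  loops <- if (nrow(tracts) >= 2) {
    tibble(start = tracts$end[-nrow(tracts)] + 1L, end = tracts$start[-1] - 1L)
  } else {
    tibble(start = integer(), end = integer())
  }
  structure(list(id = id %||% "target", bases = bases,
                 min_run = as.integer(min_run),
                 tracts = tracts, loops = loops),
            class = "g4_target")
}

#' @export
print.g4_target <- function(x, ...) {
  cat(sprintf("<g4_target> %s (%d nt, min G-run %d)\n  5'-%s-3'\n",
              x$id, nchar(x$bases), x$min_run, x$bases))
  fmt <- function(df) if (nrow(df)) paste(sprintf("[%d,%d]", df$start, df$end), collapse = " ") else "none"
  cat("  tracts:", fmt(x$tracts), "\n  loops: ", fmt(x$loops), "\n")
  invisible(x)
}

#' Middle guanine of a tract
#'
#' For an even-length tract the tie is broken toward the target 5' end,
#' i.e. position `floor((start + end) / 2)`.
#' @keywords internal
#' @noRd
tract_middle <- function(start, end) as.integer(floor((start + end) / 2))

#' Bundled G4 target sequences
#'
#' The two model G4-forming sequences the probe catalogue is designed
#' against: the human telomeric repeat (hTelo, 21 nt) and the c-KIT
#' promoter G4 (c-KIT1). For c-KIT1 both the 22-nt genomic footprint (the
#' region the probes pair with) and the 24-nt FRET-labelled construct are
#' provided.
#'
#' @return Named list of [find_g_tracts()] annotated `g4_target` objects:
#'   `hTelo`, `cKIT1` (22-nt genomic footprint) and `cKIT1_fret` (24 nt).
#' @export
g4_targets <- function() {
  list(
    hTelo = find_g_tracts("GGGTTAGGGTTAGGGTTAGGG", id = "hTelo"),
    cKIT1 = find_g_tracts("GGGAGGGCGCTGGGAGGAGGGA", id = "cKIT1"),
    cKIT1_fret = find_g_tracts("AGGGAGGGCGCTGGGAGGAGGGGC", id = "cKIT1_fret")
  )
}
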