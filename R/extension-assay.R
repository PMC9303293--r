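#' The packaged single-extension template and primer
#'
#' The 91-nt template carrying the c-KIT1 G4-forming motif (positions
#' 33-53) and the 20-nt Cy5-labelled primer used for the polymerase
#' stop assay.
#'
#' @return List with `template`, `primer`, `g4_interval`.
#' @export
extension_assay_sequences <- function() {
  list(
    template = paste0("TCTGCTTTGGGAACCCGAGAGGAGCGCTTATAGGGAGGGCGCTGGGAGGAG",
                      "GGAGGAGACTCAGCCGAGCAGCCGAGCACTCTAGCTCTAG"),
    primer = "CTAGAGCTAGAGTGCTCGGC",
    g4_interval = c(33L, 53L)
  )
}

#' Predict full-length and stall product lengths for a stop assay
#'
#' Locates the primer on the template (its reverse complement must occur
#' exactly once), then computes the product lengths: the full-length
#' product runs to the template 5' end; the stalled product ends when the
#' polymerase reaches the G4, with the last incorporated nucleotide
#' complementary to the template position `stall_offset` positions 3' of
#' the motif's 3'-most guanine (offset 0, the default, means the enzyme
#' halts immediately at the structure; the exact halt position is
#' configurable because it is not measurable from gel data alone).
#'
#' @param template Template DNA string, 5'->3'.
#' @param primer Primer DNA string, 5'->3'.
#' @param g4_interval Interval (start, end) of the G4 motif on the
#'   template, or `NULL` for no-structure (e.g. Li+) conditions.
#' @param stall_offset Extra nucleotides incorporated past the default
#'   halt position (default 0).
#' @return List of class `g4_template_assembly`: `template`, `primer`,
#'   `primer_site`, `g4_interval`, `full_length_nt`, `stall_length_nt`
#'   (NA when `g4_interval` is NULL).
#' @examples
#' sq <- extension_assay_sequences()
#' predict_stall_product_length(sq$template, sq$primer, sq$g4_interval)
#' @export
predict_stall_product_length <- function(template, primer, g4_interval = NULL,
                                         stall_offset = 0) {
  template <- validate_dna(template, "template")
  primer <- validate_dna(primer, "primer")
  prc <- reverse_complement(primer)
  hits <- gregexpr(prc, template, fixed = TRUE)[[1]]
  if (hits[1] == -1L) abort("Primer does not match the template.",
                            class = "g4_error_assembly")
  if (length(hits) > 1L) abort("Primer matches the template more than once.",
                               class = "g4_error_assembly")
  site <- c(as.integer(hits), as.integer(hits) + nchar(primer) - 1L)
  stall <- NA_integer_
  if (!is.null(g4_interval)) {
    g4_interval <- as.integer(g4_interval)
    if (g4_interval[2] >= site[1]) {
      abort("G4 interval overlaps or lies 3' of the primer site.",
            class = "g4_error_assembly")
    }
    # extension proceeds 3'->5' along the template from site[1]-1 down to
    # the first position still 3' of the motif
    stall <- nchar(primer) + (site[1] - 1L - g4_interval[2]) +
      as.integer(stall_offset)
  }
  structure(list(template = template, primer = primer, primer_site = site,
                 g4_interval = g4_interval,
                 full_length_nt = nchar(primer) + site[1] - 1L,
                 stall_length_nt = stall),
            class = "g4_template_assembly")
}

#' @export
print.g4_template_assembly <- function(x, ...) {
  cat(sprintf("<g4_template_assembly> template %d nt, primer %d nt at %d-%d\n",
              nchar(x$template), nchar(x$primer), x$primer_site[1], x$primer_site[2]))
  cat(sprintf("  full-length product: %d nt; stalled product: %s\n",
              x$full_length_nt,
              if (is.na(x$stall_length_nt)) "none (no G4)" else paste0(x$stall_length_nt, " nt")))
  invisible(x)
}

#' Quantify full-length and stalled bands in a gel lane profile
#'
#' Background (the median intensity outside all band windows) is
#' subtracted, band intensities are summed over their windows, and the
#' polymerase progression ratio i_full / i_stalled is reported. An
#' optional `probe_duplex` window (the high-molecular-weight probe/template
#' duplex band) is integrated but excluded from the ratio.
#'
#' @param lane Data frame with columns `position`, `intensity`.
#' @param windows Named list of `c(lo, hi)` position intervals; must
#'   include `full` and `stalled`, optionally `probe_duplex`.
#' @param condition Optional condition label carried into the result.
#' @return One-row tibble of class `g4_progression`: `condition`,
#'   `i_full`, `i_stalled`, `i_probe_duplex`, `ratio`.
#' @export
quantify_lane <- function(lane, windows, condition = NA_character_) {
  stopifnot(all(c("position", "intensity") %in% names(lane)))
  if (!all(c("full", "stalled") %in% names(windows))) {
    abort("`windows` must name `full` and `stalled` intervals.",
          class = "g4_error_parse")
  }
  in_win <- function(w) lane$position >= w[1] & lane$position <= w[2]
  any_win <- Reduce(`|`, lapply(windows, in_win))
  bg_vals <- lane$intensity[!any_win]
  if (!length(bg_vals)) abort("No out-of-window positions to estimate background.",
                              class = "g4_error_parse")
  bg <- median(bg_vals)
  net <- lane$intensity - bg
  band_sum <- function(w) sum(net[in_win(w)])
  i_full <- band_sum(windows$full)
  i_stalled <- band_sum(windows$stalled)
  noise_floor <- 3 * sd(bg_vals) * sqrt(sum(in_win(windows$stalled)))
  if (!is.finite(i_stalled) || i_stalled <= max(noise_floor, 0)) {
    abort("Stalled band is at background: progression ratio undefined.",
          class = "g4_error_band")
  }
  out <- tibble(condition = condition, i_full = i_full, i_stalled = i_stalled,
                i_probe_duplex = if ("probe_duplex" %in% names(windows))
                  band_sum(windows$probe_duplex) else NA_real_,
                ratio = i_full / i_stalled)
  class(out) <- unique(c("g4_progression", class(out)))
  out
}

#' Compare polymerase progression between two conditions
#'
#' Fold change of mean full/stalled ratios and an unpaired two-tailed
#' Student t test on the replicate ratios.
#'
#' @param a,b Numeric vectors of replicate ratios, or `g4_progression` /
#'   data frames with a `ratio` column (>= 2 replicates each).
#' @return Tibble: `fold_change` (mean a / mean b), `t`, `df`, `p`.
#' @export
compare_progression <- function(a, b) {
  get_ratio <- function(x) if (is.numeric(x)) x else x$ratio
  ra <- get_ratio(a); rb <- get_ratio(b)
  if (length(ra) < 2 || length(rb) < 2) {
    abort("Need at least 2 replicates per condition.", class = "g4_error_stats")
  }
  if (mean(rb) == 0) abort("Zero denominator: reference mean ratio is 0.",
                           class = "g4_error_stats")
  tt <- t.test(ra, rb, var.equal = TRUE)
  tibble(fold_change = mean(ra) / mean(rb),
         t = abs(unname(tt$statistic)), df = unname(tt$parameter),
         p = tt$p.value)
}

#' @method autoplot g4_progression
#' @export
autoplot.g4_progression <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("i_full", "i_stalled"),
                            names_to = "band", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$intensity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Band intensity (a.u.)",
                  title = sprintf("full/stalled = %.2f", object$ratio[1])) +
    ggplot2::theme_minimal()
}
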