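probe_strategies <- c("LOOP_3P", "TRACT_3P", "MIDDLE_G",
                      "SCRAMBLED_LOOPS", "SCRAMBLED_MIXED", "UNMODIFIED")

new_g4_probe <- function(name, bases, lna_mask, strategy, target_id,
                         footprint, pairing) {
  structure(list(name = name, bases = bases,
                 lna_mask = sort(as.integer(lna_mask)),
                 strategy = strategy, target_id = target_id,
                 footprint = as.integer(footprint),
                 pairing = as.integer(pairing)),
            class = "g4_probe")
}

#' @export
print.g4_probe <- function(x, ...) {
  cat(sprintf("<g4_probe> %s (%s on %s, footprint %d-%d)\n  5'-%s-3'  LNA at {%s}\n",
              x$name, x$strategy, x$target_id, x$footprint[1], x$footprint[2],
              format_lna_sequence(x$bases, x$lna_mask),
              paste(x$lna_mask, collapse = ",")))
  invisible(x)
}

#' @method as_tibble g4_probe
#' @export
as_tibble.g4_probe <- function(x, ...) {
  tibble(name = x$name, bases = x$bases,
         lna = format_lna_sequence(x$bases, x$lna_mask),
         lna_mask = list(x$lna_mask), n_lna = length(x$lna_mask),
         length_nt = nchar(x$bases), strategy = x$strategy,
         target = x$target_id,
         footprint_start = x$footprint[1], footprint_end = x$footprint[2])
}

#' Align a probe onto its target by antiparallel complementarity
#'
#' Slides the probe along the target and returns the contiguous
#' antiparallel footprint minimising Watson-Crick mismatches (probe
#' position i pairs with footprint end - i + 1). Ties are broken toward
#' the target 3' end. Needed because probes may be shorter than the
#' labelled construct they are tested on.
#'
#' @param probe A `g4_probe` or DNA string (5'->3').
#' @param target A `g4_target` or DNA string (5'->3').
#' @return List with `footprint` (start, end), `pairing` (target position
#'   paired with each probe position), and `mismatches`.
#' @export
map_probe_to_target <- function(probe, target) {
  pb <- if (inherits(probe, "g4_probe")) probe$bases else validate_dna(probe, "probe")
  tb <- if (inherits(target, "g4_target")) target$bases else validate_dna(target, "target")
  l <- nchar(pb); L <- nchar(tb)
  if (l > L) abort("Probe is longer than the target.", class = "g4_error_footprint")
  rc <- strsplit(reverse_complement(pb), "")[[1]]
  tchars <- strsplit(tb, "")[[1]]
  starts <- seq_len(L - l + 1L)
  mism <- vapply(starts, function(s) sum(rc != tchars[s:(s + l - 1L)]), integer(1))
  best <- max(starts[mism == min(mism)])  # ties toward the target 3' end
  if (min(mism) >= 0.5 * l) {
    abort("No alignment with fewer than 50% mismatches; probe does not target this sequence.",
          class = "g4_error_footprint")
  }
  fp <- c(best, best + l - 1L)
  list(footprint = fp, pairing = fp[2] - seq_len(l) + 1L,
       mismatches = min(mism))
}

#' Design a full-length LNA invader probe against a G4 target
#'
#' The probe is the reverse complement of the chosen target footprint,
#' with LNA modifications placed by strategy:
#' \describe{
#'   \item{TRACT_3P}{opposite the guanines of the target's 3'-most G-tract,
#'     extending into the adjacent 5' loop base when the tract has fewer
#'     than `n_lna` guanines.}
#'   \item{MIDDLE_G}{opposite the central guanine of each G-tract (even
#'     tracts: tie toward the target 5' end).}
#'   \item{LOOP_3P}{opposite the 3'-most bases of the target's 3'-most loop.}
#'   \item{SCRAMBLED_LOOPS, SCRAMBLED_MIXED}{fixed masks supplied via
#'     `lna_positions` (scrambled placements are fixtures, not draws).}
#'   \item{UNMODIFIED}{no LNA.}
#' }
#'
#' @param target A `g4_target` from [find_g_tracts()].
#' @param footprint Interval (start, end) on the target; default the whole
#'   sequence.
#' @param strategy One of `r paste(probe_strategies, collapse = ", ")`.
#' @param n_lna Number of LNA modifications (default 4).
#' @param name Probe name.
#' @param lna_positions Probe-coordinate LNA mask for SCRAMBLED strategies.
#' @param drop_5prime Drop this many bases from the probe 5' end after
#'   design (per-design length override; default 0).
#' @return A `g4_probe`.
#' @examples
#' kit <- g4_targets()$cKIT1
#' design_full_probe(kit, strategy = "MIDDLE_G", name = "KIT_LNA3")
#' @export
design_full_probe <- function(target, footprint = NULL, strategy, n_lna = 4,
                              name = NULL, lna_positions = NULL,
                              drop_5prime = 0) {
  stopifnot(inherits(target, "g4_target"))
  strategy <- match.arg(strategy, probe_strategies)
  L <- nchar(target$bases)
  footprint <- as.integer(footprint %||% c(1L, L))
  if (footprint[1] < 1 || footprint[2] > L || footprint[1] > footprint[2]) {
    abort("`footprint` must lie within the target.", class = "g4_error_footprint")
  }
  plen <- footprint[2] - footprint[1] + 1L
  if (strategy == "UNMODIFIED") n_lna <- 0L
  if (n_lna > plen) abort("`n_lna` exceeds the footprint length.",
                          class = "g4_error_strategy")
  bases <- reverse_complement(substr(target$bases, footprint[1], footprint[2]))
  to_probe <- function(tpos) footprint[2] - as.integer(tpos) + 1L

  clip <- function(df) {  # intervals intersected with the footprint
    df <- df[df$end >= footprint[1] & df$start <= footprint[2], , drop = FALSE]
    df$start <- pmax(df$start, footprint[1]); df$end <- pmin(df$end, footprint[2])
    df
  }
  tracts <- clip(target$tracts); loops <- clip(target$loops)

  mask <- switch(strategy,
    UNMODIFIED = integer(),
    TRACT_3P = {
      if (!nrow(tracts)) abort("No G-tract in footprint.", class = "g4_error_strategy")
      tr <- tracts[which.max(tracts$end), ]
      # 3'->5' along the target: tract guanines, then adjacent loop bases
      tpos <- seq(tr$end, footprint[1])
      if (length(tpos) < n_lna) abort("TRACT_3P needs more placements than available.",
                                      class = "g4_error_strategy")
      to_probe(tpos[seq_len(n_lna)])
    },
    MIDDLE_G = {
      mids <- tract_middle(tracts$start, tracts$end)
      mids <- mids[mids >= footprint[1] & mids <= footprint[2]]
      if (length(mids) < n_lna) {
        abort(sprintf("MIDDLE_G needs %d tracts in the footprint, found %d.",
                      n_lna, length(mids)), class = "g4_error_strategy")
      }
      to_probe(sort(mids, decreasing = TRUE)[seq_len(n_lna)])  # 3'-most tracts
    },
    LOOP_3P = {
      if (!nrow(loops)) abort("No loop in footprint.", class = "g4_error_strategy")
      lp <- loops[which.max(loops$end), ]
      tpos <- seq(lp$end, lp$start)
      if (length(tpos) < n_lna) abort("LOOP_3P: the 3' loop has fewer bases than `n_lna`.",
                                      class = "g4_error_strategy")
      to_probe(tpos[seq_len(n_lna)])
    },
    SCRAMBLED_LOOPS = ,
    SCRAMBLED_MIXED = {
      if (is.null(lna_positions)) {
        abort("SCRAMBLED strategies take a stored `lna_positions` mask, not a random draw.",
              class = "g4_error_strategy")
      }
      lna_positions <- as.integer(lna_positions)
      if (any(lna_positions < 1 | lna_positions > plen)) {
        abort("`lna_positions` outside the probe.", class = "g4_error_strategy")
      }
      if (length(lna_positions) != n_lna) {
        abort("`lna_positions` must contain exactly `n_lna` positions.",
              class = "g4_error_strategy")
      }
      lna_positions
    })

  design <- new_g4_probe(name %||% paste0(target$id, "_", strategy),
                         bases, mask, strategy, target$id, footprint,
                         pairing = footprint[2] - seq_len(plen) + 1L)
  if (drop_5prime > 0) {
    d <- as.integer(drop_5prime)
    design$bases <- substr(design$bases, d + 1L, nchar(design$bases))
    design$lna_mask <- sort(design$lna_mask[design$lna_mask > d] - d)
    design$pairing <- design$pairing[-seq_len(d)]
    design$footprint <- c(design$footprint[1], design$footprint[2] - d)
  }
  design
}

#' Truncate a probe from its 3' (target-5') side
#'
#' Keeps the first `keep` nucleotides from the probe 5' end; LNA positions
#' beyond `keep` are dropped and the footprint/pairing re-derived. This is
#' the truncation rule that produced the 10-nt "short" probes.
#'
#' @param design A `g4_probe`.
#' @param keep Number of 5' nucleotides to keep (default 10).
#' @return A `g4_probe`. Keeping at least the full length is the identity.
#' @export
truncate_probe <- function(design, keep = 10) {
  stopifnot(inherits(design, "g4_probe"), keep >= 1)
  keep <- as.integer(keep)
  l <- nchar(design$bases)
  if (keep >= l) return(design)
  new_g4_probe(
    name = if (grepl("_short$", design$name)) design$name else paste0(design$name, "_short"),
    bases = substr(design$bases, 1L, keep),
    lna_mask = design$lna_mask[design$lna_mask <= keep],
    strategy = design$strategy, target_id = design$target_id,
    footprint = c(design$footprint[2] - keep + 1L, design$footprint[2]),
    pairing = design$pairing[seq_len(keep)]
  )
}

#' Annotate probe positions by the structural role of the paired target base
#'
#' Each probe position is labelled by where its Watson-Crick partner falls
#' in the G4 target: `TETRAD_G` (inside a G-tract), `TETRAD_G_MIDDLE`
#' (additionally the tract's central guanine), `LOOP`, or `FLANK`.
#'
#' @param design A `g4_probe` whose pairing is defined against `target`.
#' @param target The `g4_target` it was designed against.
#' @return Tibble with columns `probe_pos`, `pairs_with`, `target_base`,
#'   `category`, `lna`.
#' @export
annotate_probe_positions <- function(design, target) {
  stopifnot(inherits(design, "g4_probe"), inherits(target, "g4_target"))
  L <- nchar(target$bases)
  if (any(design$pairing < 1 | design$pairing > L)) {
    abort("Pairing references positions outside the target.",
          class = "g4_error_footprint")
  }
  in_iv <- function(p, df) any(df$start <= p & p <= df$end)
  cat_of <- function(p) {
    hit <- target$tracts$start <= p & p <= target$tracts$end
    if (any(hit)) {
      tr <- target$tracts[which(hit)[1], ]
      if (p == tract_middle(tr$start, tr$end)) "TETRAD_G_MIDDLE" else "TETRAD_G"
    } else if (in_iv(p, target$loops)) "LOOP" else "FLANK"
  }
  tibble(
    probe_pos = seq_along(design$pairing),
    pairs_with = design$pairing,
    target_base = strsplit(target$bases, "")[[1]][design$pairing],
    category = vapply(design$pairing, cat_of, character(1)),
    lna = seq_along(design$pairing) %in% design$lna_mask
  )
}

#' Predict the kinetic class of an LNA placement
#'
#' Heuristic read-out of the placement rules: LNA contacts opposite tetrad
#' guanines accelerate G4 disruption, contacts scattered over several loops
#' decelerate it, and a block confined to one single (tract-adjacent) loop
#' behaves like the unmodified probe. Mixed placements are ACCELERATING
#' when more than half the contacts are tetrad guanines, NEUTRAL otherwise.
#' This is the package's documented convention, not asserted biology.
#'
#' @param annotations Output of [annotate_probe_positions()].
#' @return One of `"ACCELERATING"`, `"NEUTRAL"`, `"DECELERATING"`.
#' @export
predict_kinetic_class <- function(annotations) {
  ann <- dplyr::filter(annotations, .data$lna)
  if (!nrow(ann)) abort("No LNA positions: kinetic class undefined.",
                        class = "g4_error_strategy")
  tetrad <- ann$category %in% c("TETRAD_G", "TETRAD_G_MIDDLE")
  loop <- ann$category == "LOOP"
  if (all(tetrad)) return("ACCELERATING")
  if (all(loop)) {
    # contiguous all-loop contacts necessarily sit in one single loop
    single_loop <- diff(range(ann$pairs_with)) == length(ann$pairs_with) - 1L
    return(if (single_loop) "NEUTRAL" else "DECELERATING")
  }
  if (mean(tetrad) > 0.5) "ACCELERATING" else "NEUTRAL"
}

#' The probe catalogue
#'
#' Regenerates, from the design rules alone, every probe studied against
#' the c-KIT1 and hTelo G4s: the four full-length KIT LNA placements plus
#' the unmodified DNA control, the hTelo set, and the 10-nt truncations.
#' Scrambled placements carry their fixed masks; KIT_LNA1 carries its
#' documented 21-nt length override (5'-terminal T dropped).
#'
#' @param as_tibble Return a tibble view (default) or the list of
#'   `g4_probe` objects.
#' @return A tibble (one row per probe) or named list of `g4_probe`s.
#' @examples
#' g4_probe_catalog()
#' @export
g4_probe_catalog <- function(as_tibble = TRUE) {
  tg <- g4_targets()
  kit <- tg$cKIT1; ht <- tg$hTelo
  probes <- list(
    KIT_LNA1 = design_full_probe(kit, strategy = "LOOP_3P", name = "KIT_LNA1",
                                 drop_5prime = 1),
    KIT_LNA2 = design_full_probe(kit, strategy = "TRACT_3P", name = "KIT_LNA2"),
    KIT_LNA3 = design_full_probe(kit, strategy = "MIDDLE_G", name = "KIT_LNA3"),
    KIT_LNA4 = design_full_probe(kit, strategy = "SCRAMBLED_LOOPS",
                                 name = "KIT_LNA4",
                                 lna_positions = c(5, 7, 12, 14)),
    KIT_DNA1 = design_full_probe(kit, strategy = "UNMODIFIED", name = "KIT_DNA1"),
    hTelo_LNA1 = design_full_probe(ht, strategy = "TRACT_3P", name = "hTelo_LNA1"),
    hTelo_LNA2 = design_full_probe(ht, strategy = "SCRAMBLED_MIXED",
                                   name = "hTelo_LNA2",
                                   lna_positions = c(4, 9, 12, 17)),
    hTelo_DNA1 = design_full_probe(ht, strategy = "UNMODIFIED", name = "hTelo_DNA1")
  )
  rename <- function(d, nm) { d$name <- nm; d }
  probes$KIT_LNA_short <- rename(truncate_probe(probes$KIT_LNA2), "KIT_LNA_short")
  probes$KIT_DNA_short <- rename(truncate_probe(probes$KIT_DNA1), "KIT_DNA_short")
  probes$hTelo_LNA_short <- rename(truncate_probe(probes$hTelo_LNA1), "hTelo_LNA_short")
  probes$hTelo_LNA_short2 <- design_full_probe(
    ht, footprint = c(12, 21), strategy = "SCRAMBLED_MIXED",
    name = "hTelo_LNA_short2", lna_positions = c(2, 4, 7, 10))
  probes$hTelo_DNA_short <- rename(truncate_probe(probes$hTelo_DNA1), "hTelo_DNA_short")
  if (!as_tibble) return(probes)
  dplyr::bind_rows(lapply(probes, tibble::as_tibble))
}
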