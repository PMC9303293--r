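#' Elasticity parameters for single-stranded DNA
#'
#' Defaults describe ssDNA at 24 degC under the extensible Marko-Siggia
#' worm-like chain: persistence length 0.75 nm, stretch modulus 800 pN,
#' kBT = 4.114 pN nm, 0.45 nm contour per nucleotide. All exposed because
#' tether elasticity varies with buffer and construct.
#'
#' @param lp Persistence length, nm.
#' @param kBT Thermal energy, pN nm.
#' @param K Stretch (elastic) modulus, pN; `Inf` for the inextensible WLC.
#' @param contour_per_nt Contour length per nucleotide, nm.
#' @return List of class `g4_elasticity`.
#' @export
elasticity_params <- function(lp = 0.75, kBT = 4.114, K = 800,
                              contour_per_nt = 0.45) {
  stopifnot(lp > 0, kBT > 0, K > 0, contour_per_nt > 0)
  structure(list(lp = lp, kBT = kBT, K = K, contour_per_nt = contour_per_nt),
            class = "g4_elasticity")
}

#' Analysis configuration for multi-G4 pulling experiments
#'
#' @param per_g4_delta_l Contour length released per unfolded G4, nm
#'   (default 9, the telomeric G4 value).
#' @param force_min,force_max Force window used for the delta-L profile,
#'   pN (default 10-50: above 10 pN disrupted G4s do not refold, and by
#'   50 pN all are disrupted).
#' @param grid_step Force grid step, pN (default 0.5).
#' @param smooth Running-median window (odd; default 5) applied to the
#'   delta-L profile before counting; 1 disables smoothing.
#' @return List of class `g4_mech_config`.
#' @export
mechanics_config <- function(per_g4_delta_l = 9, force_min = 10,
                             force_max = 50, grid_step = 0.5, smooth = 5) {
  stopifnot(per_g4_delta_l > 0, force_min < force_max, grid_step > 0,
            smooth >= 1, smooth %% 2 == 1)
  structure(list(per_g4_delta_l = per_g4_delta_l, force_min = force_min,
                 force_max = force_max, grid_step = grid_step, smooth = smooth),
            class = "g4_mech_config")
}

#' Fractional extension of the extensible Marko-Siggia WLC
#'
#' Solves F = (kBT/Lp) * (1/(4(1-phi)^2) - 1/4 + phi) for phi by vectorised
#' bisection, then adds the enthalpic term F/K.
#' @keywords internal
#' @noRd
wlc_fractional_extension <- function(force, params) {
  phi <- numeric(length(force))
  pos <- force > 0
  if (any(pos)) {
    f <- force[pos]
    lo <- rep(0, length(f)); hi <- rep(1 - 1e-12, length(f))
    scale <- params$kBT / params$lp
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      val <- scale * (0.25 / (1 - mid)^2 - 0.25 + mid)
      high <- val > f
      hi[high] <- mid[high]; lo[!high] <- mid[!high]
    }
    phi[pos] <- (lo + hi) / 2
  }
  phi + force / params$K
}

#' Extension of ssDNA at a given force
#'
#' Extensible Marko-Siggia worm-like chain: x = Lc * (phi(F) + F/K) where
#' phi solves F = (kBT/Lp)(1/(4(1-phi)^2) - 1/4 + phi). Strictly increasing
#' in force and contour length; x -> Lc (1 + F/K) as F grows.
#'
#' @param force Force, pN (vectorised, >= 0).
#' @param contour_length Contour length Lc, nm (> 0).
#' @param params [elasticity_params()].
#' @return Extension in nm.
#' @examples
#' ss_extension(c(5, 25, 50), contour_length = 1000)
#' @export
ss_extension <- function(force, contour_length, params = elasticity_params()) {
  if (any(force < 0)) abort("Force must be non-negative.", class = "g4_error_mech")
  stopifnot(contour_length > 0)
  contour_length * wlc_fractional_extension(force, params)
}

#' Contour-length-change profile from a stretch/relax pull cycle
#'
#' The hysteresis between the stretch curve (G4s unfolding as force rises)
#' and the relax curve (fully unfolded tether; no refolding above 10 pN)
#' measures the contour length still sequestered in folded G4s:
#' delta-L(F) = (x_relax(F) - x_stretch(F)) / phi(F), with phi(F) the WLC
#' fractional extension at unit contour length. Both curves are
#' interpolated onto a force grid inside the 10-50 pN window and the
#' profile smoothed with a running median.
#'
#' @param cycle Data frame with columns `force_pN`, `extension_nm`,
#'   `phase` (values `"stretch"`, `"relax"`), e.g. from [gen_pull_cycle()]
#'   or [read_cycle_csv()].
#' @param params [elasticity_params()].
#' @param config [mechanics_config()].
#' @return Tibble of class `g4_delta_l` with columns `force_pN`,
#'   `delta_l_nm`.
#' @export
build_delta_l_profile <- function(cycle, params = elasticity_params(),
                                  config = mechanics_config()) {
  stopifnot(all(c("force_pN", "extension_nm", "phase") %in% names(cycle)))
  st <- cycle[cycle$phase == "stretch", ]
  rx <- cycle[cycle$phase == "relax", ]
  if (!nrow(st) || !nrow(rx)) abort("Cycle needs both stretch and relax phases.",
                                    class = "g4_error_mech")
  for (cv in list(st, rx)) {
    if (min(cv$force_pN) > config$force_min || max(cv$force_pN) < config$force_max) {
      abort(sprintf("Curves must cover the %g-%g pN window.",
                    config$force_min, config$force_max),
            class = "g4_error_mech")
    }
  }
  grid <- seq(config$force_min, config$force_max, by = config$grid_step)
  x_s <- approx(st$force_pN, st$extension_nm, xout = grid, ties = mean)$y
  x_r <- approx(rx$force_pN, rx$extension_nm, xout = grid, ties = mean)$y
  phi <- wlc_fractional_extension(grid, params)
  dl <- (x_r - x_s) / phi
  if (config$smooth > 1 && length(dl) > config$smooth) {
    dl <- as.numeric(runmed(dl, config$smooth, endrule = "median"))
  }
  out <- tibble(force_pN = grid, delta_l_nm = dl)
  class(out) <- c("g4_delta_l", class(out))
  attr(out, "params") <- params
  attr(out, "config") <- config
  out
}

#' Convert a delta-L profile into folded-G4 counts
#'
#' Each folded telomeric G4 sequesters `per_g4_delta_l` (9 nm by default)
#' of contour length, so n_folded(F) = round(delta-L(F) / 9 nm); the total
#' number of G4s in the tether is the count at the lower force boundary
#' (10 pN).
#'
#' @param profile A `g4_delta_l` tibble from [build_delta_l_profile()].
#' @param config [mechanics_config()].
#' @return Tibble of class `g4_mech_summary` with `force_pN`, `delta_l_nm`,
#'   `n_folded`; attributes `n_total` and `delta_l_at_min` give the count
#'   and delta-L at the lower boundary.
#' @export
count_folded_g4 <- function(profile, config = mechanics_config()) {
  stopifnot(all(c("force_pN", "delta_l_nm") %in% names(profile)))
  out <- dplyr::mutate(profile,
                       n_folded = as.integer(round(.data$delta_l_nm / config$per_g4_delta_l)))
  class(out) <- unique(c("g4_mech_summary", class(out)))
  attr(out, "n_total") <- out$n_folded[1]
  attr(out, "delta_l_at_min") <- out$delta_l_nm[1]
  attr(out, "config") <- config
  out
}

#' Half-disruption force F1/2
#'
#' The force at which half of the folded G4 units present at the lower
#' force boundary have been mechanically disrupted: the smallest grid
#' force where n_folded drops to n_total/2, refined by linear
#' interpolation between the bracketing grid points.
#'
#' @param summary A `g4_mech_summary` from [count_folded_g4()].
#' @return F1/2 in pN.
#' @export
half_force <- function(summary) {
  stopifnot(inherits(summary, "g4_mech_summary"))
  n_total <- attr(summary, "n_total")
  if (is.na(n_total) || n_total < 2) {
    abort("F1/2 needs at least 2 folded G4 units at the lower boundary.",
          class = "g4_error_mech")
  }
  half <- n_total / 2
  nf <- summary$n_folded; ff <- summary$force_pN
  idx <- which(nf <= half)[1]
  if (is.na(idx)) abort("n_folded never falls to half within the force window.",
                        class = "g4_error_mech")
  if (idx == 1) return(ff[1])
  i0 <- idx - 1L
  ff[i0] + (nf[i0] - half) / (nf[i0] - nf[idx]) * (ff[idx] - ff[i0])
}

#' Analyse one pull cycle end to end
#'
#' Convenience wrapper: delta-L profile, folded-G4 counts and F1/2 from a
#' single stretch/relax cycle.
#'
#' @inheritParams build_delta_l_profile
#' @return One-row tibble: `n_total`, `f_half_pN`, `delta_l_at_10pN_nm`.
#' @export
analyze_pull_cycle <- function(cycle, params = elasticity_params(),
                               config = mechanics_config()) {
  prof <- build_delta_l_profile(cycle, params, config)
  cnt <- count_folded_g4(prof, config)
  fh <- tryCatch(half_force(cnt), error = function(e) NA_real_)
  tibble(n_total = attr(cnt, "n_total"), f_half_pN = fh,
         delta_l_at_10pN_nm = attr(cnt, "delta_l_at_min"))
}

#' Summarise per-molecule mechanics across conditions
#'
#' Mean and SEM of the folded-G4 count and F1/2 per condition, with
#' pairwise unpaired two-tailed t tests between conditions (the same
#' summary-statistic machinery as [compare_half_lives()]).
#'
#' @param molecules Data frame with one row per molecule: columns
#'   `condition`, `n_total`, `f_half_pN`.
#' @param min_molecules Emit a warning below this many molecules per
#'   condition (default 5); fewer than 2 is an error.
#' @return List of class `g4_mech_comparison`: `summary` tibble and
#'   `tests` tibble (pairwise, both metrics).
#' @export
summarize_molecules <- function(molecules, min_molecules = 5) {
  stopifnot(all(c("condition", "n_total", "f_half_pN") %in% names(molecules)))
  counts <- table(molecules$condition)
  if (any(counts < 2)) abort("Need at least 2 molecules per condition.",
                             class = "g4_error_stats")
  if (any(counts < min_molecules)) {
    warn(sprintf("Fewer than %d molecules in condition(s): %s.", min_molecules,
                 paste(names(counts)[counts < min_molecules], collapse = ", ")))
  }
  summ <- molecules |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_molecules = dplyr::n(),
                     mean_n_total = mean(.data$n_total),
                     sem_n_total = sd(.data$n_total) / sqrt(dplyr::n()),
                     mean_f_half = mean(.data$f_half_pN),
                     sem_f_half = sd(.data$f_half_pN) / sqrt(dplyr::n()),
                     .groups = "drop")
  conds <- unique(as.character(molecules$condition))
  pairs <- if (length(conds) >= 2) utils::combn(conds, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(pairs, function(pr) {
    xa <- molecules[molecules$condition == pr[1], ]
    xb <- molecules[molecules$condition == pr[2], ]
    purrr::map_dfr(c(n_total = "n_total", f_half = "f_half_pN"), function(col) {
      compare_half_lives(xa[[col]], xb[[col]])
    }, .id = "metric") |>
      dplyr::mutate(condition_a = pr[1], condition_b = pr[2], .before = 1)
  })
  structure(list(summary = summ, tests = tests), class = "g4_mech_comparison")
}

#' @export
print.g4_mech_comparison <- function(x, ...) {
  cat("<g4_mech_comparison>\n")
  print(x$summary)
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' @method autoplot g4_delta_l
#' @export
autoplot.g4_delta_l <- function(object, ...) {
  per <- attr(object, "config")$per_g4_delta_l %||% 9
  ggplot2::ggplot(object, ggplot2::aes(x = .data$force_pN, y = .data$delta_l_nm)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(sec.axis = ggplot2::sec_axis(~ . / per,
                                                             name = "Folded G4s")) +
    ggplot2::labs(x = "Force (pN)", y = expression(Delta * L ~ "(nm)")) +
    ggplot2::theme_minimal()
}
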