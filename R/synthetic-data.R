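#' Condition presets for the bulk FRET disruption assay
#'
#' One row per probe/target condition with the measured apparent
#' half-life (mean +- SEM, n = 3 replicates) and the sampling interval the
#' assay used (30 s for hTelo, 120 s for c-KIT1). The hTelo_DNA_short
#' condition is biphasic: the tabulated half-life is its slow phase, and
#' the generator adds a 40% amplitude fast component with a 100 s
#' half-life.
#'
#' @return Tibble with columns `condition`, `target`, `t_half_s`, `sem_s`,
#'   `n`, `sampling_interval_s`, `biphasic`, `fast_t_half_s`,
#'   `fast_fraction`.
#' @export
g4_condition_presets <- function() {
  out <- tibble::tribble(
    ~condition,          ~target,  ~t_half_s, ~sem_s,
    "KIT_DNA1",          "cKIT1",  1753,      70,
    "KIT_LNA1",          "cKIT1",  1481,      144,
    "KIT_LNA2",          "cKIT1",  1087,      24,
    "KIT_LNA3",          "cKIT1",  628,       40,
    "KIT_LNA4",          "cKIT1",  4247,      494,
    "KIT_LNA_short",     "cKIT1",  831,       8,
    "hTelo_DNA1",        "hTelo",  1967,      65,
    "hTelo_LNA1",        "hTelo",  1539,      18,
    "hTelo_LNA2",        "hTelo",  2179,      39,
    "hTelo_LNA_short",   "hTelo",  1655,      105,
    "hTelo_LNA_short2",  "hTelo",  3014,      18,
    "hTelo_DNA_short",   "hTelo",  8551,      593
  )
  out$n <- 3L
  out$sampling_interval_s <- ifelse(out$target == "hTelo", 30, 120)
  out$biphasic <- out$condition == "hTelo_DNA_short"
  out$fast_t_half_s <- ifelse(out$biphasic, 100, NA_real_)
  out$fast_fraction <- ifelse(out$biphasic, 0.4, NA_real_)
  out
}

#' Condition presets for the single-molecule pulling assay
#'
#' Folded-G4 counts at 10 pN and half-disruption forces measured on the
#' multi-telomeric-G4 tether in buffer and after probe treatment.
#'
#' @return Tibble with `condition`, `n_g4`, `f_half_pN`.
#' @export
g4_mechanics_presets <- function() {
  tibble::tribble(
    ~condition,         ~n_g4, ~f_half_pN,
    "buffer",           55L,   25.4,
    "hTelo_DNA_short",  32L,   26.8,
    "hTelo_LNA_short",  21L,   34.5
  )
}

#' Condition presets for the polymerase stop assay
#'
#' Full/stalled progression ratios per condition. Only fold differences
#' are published (~6-fold Li+ over K+, ~5-fold K+ + LNA over K+), so the
#' absolute ratios here are the package's fixed realisation of those
#' folds.
#'
#' @return Tibble with `condition`, `ratio`, plus band areas used by
#'   [gen_gel_lane()] (total product area is fixed; the ratio splits it).
#' @export
g4_gel_presets <- function() {
  tibble::tribble(
    ~condition,      ~ratio,
    "K",             0.5,
    "Li",            3.0,
    "K_LNA_short",   2.5,
    "K_DNA_short",   0.55
  )
}

#' Simulate a bulk FRET disruption trace
#'
#' signal(t) = baseline + amplitude * (f_fast (1 - e^(-k_f t)) +
#' (1 - f_fast)(1 - e^(-k_s t))) + Gaussian noise with sd
#' `noise_sd * amplitude`. Deterministic under a fixed seed.
#'
#' @param t_half Slow-phase (or only) half-life, s.
#' @param sampling_interval Sampling interval, s (30 or 120 in the study).
#' @param duration Total duration, s; default 3 * `t_half` (a warning is
#'   emitted below that, where the plateau is poorly constrained).
#' @param noise_sd Noise sd as a fraction of the amplitude (default 0.02).
#' @param baseline,amplitude Raw signal at t = 0 and total signal change.
#' @param fast_t_half,fast_fraction Optional fast component (biphasic
#'   traces): its half-life and amplitude fraction (0 <= f < 1).
#' @param seed Integer seed; every generator in the package is a pure
#'   function of its arguments including the seed.
#' @return Tibble with `time_s`, `signal_au`.
#' @examples
#' gen_fret_trace(t_half = 600, sampling_interval = 30, duration = 1800,
#'                noise_sd = 0, seed = 1)
#' @export
gen_fret_trace <- function(t_half, sampling_interval = 120, duration = NULL,
                           noise_sd = 0.02, baseline = 0, amplitude = 100,
                           fast_t_half = NULL, fast_fraction = 0, seed = 1) {
  if (!is.numeric(t_half) || t_half <= 0) abort("`t_half` must be positive.",
                                                class = "g4_error_sim")
  stopifnot(fast_fraction >= 0, fast_fraction < 1)
  duration <- duration %||% (3 * t_half)
  if (duration < 3 * t_half) {
    warn("Trace shorter than 3 half-lives: the plateau will be poorly constrained.")
  }
  times <- seq(0, duration, by = sampling_interval)
  ks <- log(2) / t_half
  frac <- if (is.null(fast_t_half)) {
    1 - exp(-ks * times)
  } else {
    kf <- log(2) / fast_t_half
    fast_fraction * (1 - exp(-kf * times)) +
      (1 - fast_fraction) * (1 - exp(-ks * times))
  }
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(times), 0, noise_sd * amplitude))
  } else 0
  tibble(time_s = times, signal_au = baseline + amplitude * frac + noise)
}

#' Simulate a UV melting curve
#'
#' Two-state sigmoid in temperature with additive Gaussian noise on the
#' absorbance; heating branch only.
#'
#' @param tm Midpoint temperature, degC.
#' @param width Transition width, degC (default 2.5).
#' @param temp_range Scanned range, degC (default 25-95).
#' @param step Temperature step, degC (default 0.5).
#' @param a_low,a_high Absorbance asymptotes.
#' @param noise_sd Additive noise sd in absorbance units.
#' @param seed Integer seed.
#' @return Tibble with `temp_C`, `abs260`.
#' @export
gen_melt_curve <- function(tm, width = 2.5, temp_range = c(25, 95),
                           step = 0.5, a_low = 0.30, a_high = 0.55,
                           noise_sd = 0.002, seed = 1) {
  if (tm <= temp_range[1] || tm >= temp_range[2]) {
    abort("`tm` must lie inside the temperature range.", class = "g4_error_sim")
  }
  tt <- seq(temp_range[1], temp_range[2], by = step)
  a <- a_low + (a_high - a_low) / (1 + exp(-(tt - tm) / width))
  noise <- if (noise_sd > 0) withr::with_seed(seed, rnorm(length(tt), 0, noise_sd)) else 0
  tibble(temp_C = tt, abs260 = a + noise)
}

#' Simulate a stretch/relax pull cycle of a multi-G4 tether
#'
#' Draws `n_g4` unfolding forces from a normal distribution truncated to
#' > 10 pN (below which disrupted G4s could refold). On the stretch
#' branch, the tether contour length at force F is the ssDNA handle plus
#' 9 nm (configurable) per G4 already unfolded at or below F; folded G4s
#' contribute no extension. The relax branch is the fully unfolded tether.
#' Extensions follow the extensible Marko-Siggia WLC with additive
#' Gaussian noise.
#'
#' @param n_g4 Number of folded G4 units in the tether (>= 0).
#' @param unfold_force_mean,unfold_force_sd Unfolding-force distribution,
#'   pN (defaults 25.4 and 4).
#' @param per_g4_delta_l Contour release per G4, nm (default 9).
#' @param handle_contour ssDNA handle contour length, nm (default 3000).
#' @param params [elasticity_params()].
#' @param force_range,force_step Sampled force ramp, pN (defaults 0.5-55
#'   by 0.1; the acquisition rate at the study's 5.5 pN/s loading rate).
#' @param extension_noise_sd Additive extension noise, nm (default 0).
#' @param seed Integer seed.
#' @return Tibble with `force_pN`, `extension_nm`, `phase`; the drawn
#'   unfolding forces are attached as attribute `unfold_forces`.
#' @export
gen_pull_cycle <- function(n_g4, unfold_force_mean = 25.4, unfold_force_sd = 4,
                           per_g4_delta_l = 9, handle_contour = 3000,
                           params = elasticity_params(),
                           force_range = c(0.5, 55), force_step = 0.1,
                           extension_noise_sd = 0, seed = 1) {
  stopifnot(n_g4 >= 0, handle_contour > 0, per_g4_delta_l > 0)
  forces_up <- seq(force_range[1], force_range[2], by = force_step)
  forces_down <- rev(forces_up)
  sim <- withr::with_seed(seed, {
    uf <- numeric(0)
    while (length(uf) < n_g4) {
      draw <- rnorm(n_g4 - length(uf), unfold_force_mean, unfold_force_sd)
      uf <- c(uf, draw[draw > 10])
    }
    list(uf = sort(uf),
         noise_s = rnorm(length(forces_up), 0, extension_noise_sd),
         noise_r = rnorm(length(forces_down), 0, extension_noise_sd))
  })
  n_unfolded <- findInterval(forces_up, sim$uf)
  lc_stretch <- handle_contour + per_g4_delta_l * n_unfolded
  phi_up <- wlc_fractional_extension(forces_up, params)
  x_stretch <- lc_stretch * phi_up +
    (if (extension_noise_sd > 0) sim$noise_s else 0)
  lc_full <- handle_contour + per_g4_delta_l * n_g4
  x_relax <- lc_full * rev(phi_up) +
    (if (extension_noise_sd > 0) sim$noise_r else 0)
  out <- dplyr::bind_rows(
    tibble(force_pN = forces_up, extension_nm = x_stretch, phase = "stretch"),
    tibble(force_pN = forces_down, extension_nm = x_relax, phase = "relax"))
  attr(out, "unfold_forces") <- sim$uf
  out
}

#' Simulate a 1-D gel lane profile
#'
#' Sum of Gaussian bands (full-length and stalled products, optionally the
#' probe/template duplex) over a flat background, with additive pixel
#' noise and multiplicative area jitter between replicates.
#'
#' @param full_area,stalled_area Band areas (a.u.; their ratio is the
#'   progression ratio being emulated).
#' @param duplex_area Optional third band area (default 0 = absent).
#' @param full_pos,stalled_pos,duplex_pos Band centres on the migration
#'   coordinate (ascending coordinate = smaller product).
#' @param band_sd Gaussian band width (default 2.5).
#' @param background Flat background level (default 20).
#' @param noise_sd Additive pixel noise sd (default 0.5).
#' @param area_jitter_sd Multiplicative sd on each band area (default 0,
#'   i.e. exact areas; replicate lanes use e.g. 0.05).
#' @param positions Migration coordinate grid.
#' @param seed Integer seed.
#' @return Tibble with `position`, `intensity`; attribute `windows` gives
#'   the +-4 sd band windows for [quantify_lane()].
#' @export
gen_gel_lane <- function(full_area, stalled_area, duplex_area = 0,
                         full_pos = 35, stalled_pos = 65, duplex_pos = 85,
                         band_sd = 2.5, background = 20, noise_sd = 0.5,
                         area_jitter_sd = 0, positions = seq(0, 100, by = 0.2),
                         seed = 1) {
  stopifnot(full_area >= 0, stalled_area >= 0, duplex_area >= 0, band_sd > 0)
  sim <- withr::with_seed(seed, list(
    jit = rnorm(3, 1, area_jitter_sd),
    noise = rnorm(length(positions), 0, noise_sd)))
  jit <- if (area_jitter_sd > 0) pmax(sim$jit, 0) else rep(1, 3)
  gauss <- function(area, mu) area * jit_next() *
    exp(-(positions - mu)^2 / (2 * band_sd^2)) / (band_sd * sqrt(2 * pi))
  i <- 0
  jit_next <- function() { i <<- i + 1; jit[i] }
  intensity <- background +
    gauss(full_area, full_pos) + gauss(stalled_area, stalled_pos) +
    gauss(duplex_area, duplex_pos) +
    (if (noise_sd > 0) sim$noise else 0)
  out <- tibble(position = positions, intensity = pmax(intensity, 0))
  win <- function(mu) c(mu - 4 * band_sd, mu + 4 * band_sd)
  attr(out, "windows") <- c(list(full = win(full_pos), stalled = win(stalled_pos)),
                            if (duplex_area > 0) list(probe_duplex = win(duplex_pos)))
  out
}

#' Simulate a dual-luciferase reporter dataset
#'
#' Normally distributed Renilla/Firefly ratios per condition; Firefly is
#' fixed at a common level so the generated wells carry realistic raw
#' luminescence columns.
#'
#' @param conditions Data frame with `condition`, `mean_ratio`, `sd_ratio`
#'   and optionally `n` (default `n_per_condition`).
#' @param n_per_condition Replicates per condition (default 3).
#' @param firefly Common Firefly luminescence level (default 1e5 a.u.).
#' @param dataset Dataset (biological batch) label, default 1.
#' @param seed Integer seed.
#' @return Tibble with `condition`, `dataset`, `replicate`, `renilla`,
#'   `firefly`.
#' @export
gen_reporter_dataset <- function(conditions, n_per_condition = 3,
                                 firefly = 1e5, dataset = 1L, seed = 1) {
  stopifnot(all(c("condition", "mean_ratio", "sd_ratio") %in% names(conditions)))
  if (!"n" %in% names(conditions)) conditions$n <- n_per_condition
  if (any(conditions$n < 2)) abort("Need n >= 2 per condition.",
                                   class = "g4_error_sim")
  ratios <- withr::with_seed(seed, purrr::pmap(conditions, function(condition, mean_ratio, sd_ratio, n, ...) {
    tibble(condition = condition, dataset = dataset,
           replicate = seq_len(n),
           renilla = pmax(rnorm(n, mean_ratio, sd_ratio), 1e-6) * firefly,
           firefly = firefly)
  }))
  dplyr::bind_rows(ratios)
}
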