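# Shared helpers for the test suite. Oracles here are deliberately
# independent of the implementation paths they check.

# character-table reverse complement, independent of Biostrings
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

preset_row <- function(cond) {
  p <- g4_condition_presets()
  p[p$condition == cond, ]
}

# generate + normalise + fit a monophasic preset trace for one seed
fit_preset_seed <- function(t_half, interval, seed, noise_sd = 0.02) {
  tr <- gen_fret_trace(t_half = t_half, sampling_interval = interval,
                       noise_sd = noise_sd, seed = seed)
  fit_one_phase(normalize_trace(tr))$t_half
}

# build a pull cycle directly from chosen unfolding forces (independent of
# gen_pull_cycle's force draw), noise-free
make_cycle <- function(unfold_forces, per_g4 = 9, handle = 3000,
                       params = elasticity_params()) {
  f_up <- seq(0.5, 55, by = 0.1)
  n_unf <- findInterval(f_up, sort(unfold_forces))
  phi <- ss_extension(f_up, 1, params)  # fractional extension per unit contour
  x_s <- phi * (handle + per_g4 * n_unf)
  lc_full <- handle + per_g4 * length(unfold_forces)
  dplyr::bind_rows(
    tibble::tibble(force_pN = f_up, extension_nm = x_s, phase = "stretch"),
    tibble::tibble(force_pN = rev(f_up),
                   extension_nm = ss_extension(rev(f_up), lc_full, params),
                   phase = "relax"))
}
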