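test_that("trace normalisation is the stated affine map and is idempotent", {
  tr <- gen_fret_trace(t_half = 600, sampling_interval = 30, duration = 3000,
                       noise_sd = 0, baseline = 120, amplitude = 360, seed = 1)
  norm <- normalize_trace(tr)
  # affine definition: (signal - 120) / (480 - 120) * 100
  expect_equal(norm$percent, (tr$signal_au - 120) / 360 * 100, tolerance = 1e-6)
  # half-life definition: 50% at t = t_half
  expect_equal(norm$percent[norm$time_s == 600], 50, tolerance = 1e-6)
  # idempotence
  renorm <- normalize_trace(norm)
  expect_equal(renorm$percent, norm$percent, tolerance = 1e-6)

  flat <- tibble::tibble(time_s = seq(0, 120, 30), signal_au = rep(100, 5))
  expect_error(normalize_trace(flat), class = "g4_error_fit")
})

test_that("one-phase fit recovers a noise-free exponential exactly", {
  tr <- gen_fret_trace(t_half = 600, sampling_interval = 30, duration = 3000,
                       noise_sd = 0, seed = 1)
  fit <- fit_one_phase(normalize_trace(tr))
  expect_equal(fit$t_half, 600, tolerance = 1e-6)
  expect_equal(fit$plateau, 100, tolerance = 1e-6)
  expect_error(fit_one_phase(tibble::tibble(time_s = seq(0, 120, 30),
                                            percent = rep(50, 5))),
               class = "g4_error_fit")
})

test_that("t_half * k = ln(2) identity holds for every fit", {
  for (seed in 1:10) {
    th <- c(628, 1753, 8551)[seed %% 3 + 1]
    fit <- fit_one_phase(normalize_trace(
      gen_fret_trace(th, 120, noise_sd = 0.02, seed = seed)))
    expect_identical(fit$t_half, log(2) / fit$k)
    expect_identical(glance(fit)$t_half_s * glance(fit)$k, log(2))
  }
})

test_that("fits recover preset half-lives with small bias and honest errors", {
  # parameter-recovery study: bias < 2%, ~2 SE coverage >= 90%
  seeds <- 1:100
  for (th in c(628, 1753, 8551)) {
    fits <- lapply(seeds, function(s) fit_one_phase(normalize_trace(
      gen_fret_trace(th, 120, noise_sd = 0.02, seed = s))))
    est <- vapply(fits, `[[`, numeric(1), "t_half")
    se <- vapply(fits, `[[`, numeric(1), "se_t_half")
    expect_lt(abs(mean(est) / th - 1), 0.02)
    expect_gte(mean(abs(est - th) <= 2 * se), 0.90)
  }
})

test_that("biphasic traces are detected and the slow phase recovered", {
  # 40% fast (t1/2 100 s) + 60% slow component
  tr <- normalize_trace(gen_fret_trace(8551, 30, noise_sd = 0.02,
                                       fast_t_half = 100, fast_fraction = 0.4,
                                       seed = 11))
  ph <- select_slow_phase(tr)
  expect_true(ph$biphasic)
  expect_lt(ph$p_value, 0.05)
  slow_fit <- fit_one_phase(ph$trace)
  expect_lt(abs(slow_fit$t_half / 8551 - 1), 0.05)

  mono <- normalize_trace(gen_fret_trace(1753, 120, noise_sd = 0.02, seed = 2))
  ph_mono <- select_slow_phase(mono)
  expect_false(ph_mono$biphasic)
  expect_identical(ph_mono$trace$percent, mono$percent)

  fast_only <- normalize_trace(gen_fret_trace(100, 30, duration = 900,
                                              noise_sd = 0.01, seed = 3))
  expect_false(select_slow_phase(fast_only)$biphasic)
})

test_that("summary-statistic t test reproduces the published comparisons", {
  a <- tibble::tibble(n = 3, mean_t_half = 1753, sem_t_half = 70)
  b <- tibble::tibble(n = 3, mean_t_half = 628, sem_t_half = 40)
  res <- compare_half_lives(a, b)
  expect_equal(res$t, 13.95, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0002, tolerance = 0.25)  # printed to 1 significant figure

  res2 <- compare_half_lives(
    tibble::tibble(n = 3, mean_t_half = 4247, sem_t_half = 494), a)
  expect_equal(res2$p, 0.0075, tolerance = 0.01)

  same <- compare_half_lives(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("summary-statistic t equals the classic pooled t on raw replicates", {
  withr::with_seed(42, {
    for (i in 1:5) {
      x <- rnorm(3, 1700, 100); y <- rnorm(3, 900, 80)
      raw <- compare_half_lives(x, y)
      summ <- compare_half_lives(summarize_replicates(x), summarize_replicates(y))
      expect_equal(raw$t, summ$t, tolerance = 1e-10)
      expect_equal(raw$p, summ$p, tolerance = 1e-10)
      expect_equal(raw$df, summ$df)
    }
  })
  expect_error(compare_half_lives(1500, c(1, 2)), class = "g4_error_stats")
})

test_that("Tm extraction hits sigmoid midpoints and rejects degenerate ramps", {
  mf <- extract_tm(gen_melt_curve(tm = 65, noise_sd = 0.002, seed = 1))
  expect_equal(mf$tm, 65, tolerance = 0.1)

  tm_a <- extract_tm(gen_melt_curve(tm = 62, noise_sd = 0.002, seed = 2))$tm
  tm_b <- extract_tm(gen_melt_curve(tm = 70, noise_sd = 0.002, seed = 3))$tm
  expect_equal(tm_b - tm_a, 8, tolerance = 0.2)

  ramp <- tibble::tibble(temp_C = seq(25, 95, 0.5))
  ramp$abs260 <- 0.3 + 0.003 * (ramp$temp_C - 25)
  expect_error(extract_tm(ramp), class = "g4_error_fit")
})
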