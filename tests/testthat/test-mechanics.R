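test_that("WLC extension obeys limits and monotonicity", {
  p <- elasticity_params()
  expect_equal(ss_extension(0, 1000, p), 0)
  expect_error(ss_extension(-1, 1000, p), class = "g4_error_mech")

  # closed form: at half extension (phi = 0.5, inextensible limit)
  # F = 1.25 kBT / Lp = 6.857 pN for Lp = 0.75 nm, kBT = 4.114 pN nm
  p_inext <- elasticity_params(K = 1e12)
  f_half_ext <- 1.25 * p_inext$kBT / p_inext$lp
  expect_equal(ss_extension(f_half_ext, 1000, p_inext), 500, tolerance = 1e-6)

  # high-force asymptote phi ~ 1 - sqrt(kBT / (4 Lp F))
  expect_equal(ss_extension(1000, 1000, p_inext),
               1000 * (1 - sqrt(p_inext$kBT / (4 * p_inext$lp * 1000))),
               tolerance = 1e-3)
  expect_gte(ss_extension(1000, 1000, p_inext), 950)

  forces <- seq(0.5, 55, by = 0.5)
  x <- ss_extension(forces, 1000, p)
  expect_true(all(diff(x) > 0))                   # increasing in F
  expect_true(all(ss_extension(20, c(10, 100, 1000), p) ==
                    10 * c(1, 10, 100) * ss_extension(20, 10, p) / 10))
  expect_true(all(x <= 1000 * (1 + forces / p$K)))  # enthalpic bound
})

test_that("delta-L profile inverts simulated unfolding events", {
  # stretch == relax -> delta-L identically zero
  relax_only <- gen_pull_cycle(0, seed = 1)
  prof0 <- build_delta_l_profile(relax_only)
  expect_true(all(abs(prof0$delta_l_nm) < 1e-9))

  # one 9-nm event at 28 pN: 9 nm below, 0 above
  cyc1 <- make_cycle(28)
  prof1 <- build_delta_l_profile(cyc1)
  expect_equal(prof1$delta_l_nm[prof1$force_pN <= 27],
               rep(9, sum(prof1$force_pN <= 27)), tolerance = 0.01)
  expect_true(all(abs(prof1$delta_l_nm[prof1$force_pN >= 29]) < 0.1))

  # 55 events: 495 nm at 10 pN (9 nm additivity)
  uf55 <- withr::with_seed(5, rnorm(55, 25.4, 4))
  uf55 <- uf55[uf55 > 10]
  prof55 <- build_delta_l_profile(make_cycle(uf55))
  expect_equal(prof55$delta_l_nm[1], 9 * length(uf55), tolerance = 0.01 * 9 * 55)

  expect_error(build_delta_l_profile(
    tibble::tibble(force_pN = c(1, 5, 5, 1), extension_nm = c(1, 2, 3, 4),
                   phase = c("stretch", "stretch", "relax", "relax"))),
    class = "g4_error_mech")
})

test_that("delta-L additivity and monotonicity hold on noise-free cycles", {
  single <- build_delta_l_profile(make_cycle(30))
  five <- build_delta_l_profile(make_cycle(rep(30, 5)))
  below <- five$force_pN < 29
  expect_equal(five$delta_l_nm[below], 5 * single$delta_l_nm[below],
               tolerance = 0.01 * max(five$delta_l_nm))

  uf <- withr::with_seed(9, rnorm(21, 25.4, 4)); uf <- uf[uf > 10]
  prof <- build_delta_l_profile(make_cycle(uf))
  expect_true(all(diff(prof$delta_l_nm) <= 1e-9))
  expect_lt(abs(prof$delta_l_nm[nrow(prof)]), 0.5)  # ~0 at 50 pN
})

test_that("G4 counting rounds delta-L/9 nm and recovers generator presets exactly", {
  for (n in c(1, 5, 21, 32, 55)) {
    cyc <- gen_pull_cycle(n, seed = 100 + n)
    cnt <- count_folded_g4(build_delta_l_profile(cyc))
    expect_identical(attr(cnt, "n_total"), as.integer(n))
  }
  flat0 <- count_folded_g4(tibble::tibble(force_pN = seq(10, 50, 0.5),
                                          delta_l_nm = 0))
  expect_identical(attr(flat0, "n_total"), 0L)
  one <- count_folded_g4(tibble::tibble(force_pN = seq(10, 50, 0.5),
                                        delta_l_nm = 9.4))
  expect_identical(attr(one, "n_total"), 1L)
})

test_that("F1/2 is the interpolated half-count force", {
  # all events at one force: F1/2 equals that force
  cnt30 <- count_folded_g4(build_delta_l_profile(make_cycle(rep(30, 6))))
  expect_equal(half_force(cnt30), 30, tolerance = 0.5)

  # symmetric draw: F1/2 tracks the sample median across seeds
  for (seed in 1:5) {
    cyc <- gen_pull_cycle(55, unfold_force_mean = 25.4, unfold_force_sd = 4,
                          seed = seed)
    med <- median(attr(cyc, "unfold_forces"))
    fh <- half_force(count_folded_g4(build_delta_l_profile(cyc)))
    expect_lt(abs(fh - med), 1)
  }

  # uniform unfolding forces on [10, 50]: F1/2 near 30 pN
  uf_unif <- withr::with_seed(77, runif(60, 10.5, 49.5))
  fh_u <- half_force(count_folded_g4(build_delta_l_profile(make_cycle(uf_unif))))
  expect_equal(fh_u, median(uf_unif), tolerance = 1)
  expect_equal(fh_u, 30, tolerance = 3)

  expect_error(half_force(count_folded_g4(build_delta_l_profile(make_cycle(28)))),
               class = "g4_error_mech")
})

test_that("per-condition molecule summaries and tests behave", {
  sim_cond <- function(n_g4, cond, seeds) {
    purrr::map_dfr(seeds, function(s) {
      dplyr::mutate(analyze_pull_cycle(gen_pull_cycle(n_g4, seed = s)),
                    condition = cond)
    })
  }
  mols <- dplyr::bind_rows(sim_cond(55, "buffer", 1:5),
                           sim_cond(21, "LNA", 11:15))
  cmp <- summarize_molecules(mols)
  expect_equal(nrow(cmp$summary), 2)
  ntest <- cmp$tests[cmp$tests$metric == "n_total", ]
  expect_lt(ntest$p, 0.05)
  expect_equal(cmp$summary$mean_n_total[cmp$summary$condition == "buffer"], 55,
               tolerance = 0.01)

  expect_error(summarize_molecules(mols[c(1, 6), ]), class = "g4_error_stats")
  expect_warning(summarize_molecules(dplyr::bind_rows(sim_cond(5, "a", 1:2),
                                                      sim_cond(5, "b", 3:4))),
                 "Fewer than")
})
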