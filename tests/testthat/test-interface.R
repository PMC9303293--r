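test_that("LNA '+N' notation parses and writes losslessly", {
  p <- parse_lna_sequence("T+C+C+C+TCCTCC")
  expect_equal(p$bases, "TCCCTCCTCC")
  expect_equal(p$lna_mask, 2:5)
  expect_equal(parse_lna_sequence("ACGT")$lna_mask, integer())
  expect_error(parse_lna_sequence("A++G"), class = "g4_error_parse")
  expect_error(parse_lna_sequence("AC+"), class = "g4_error_parse")
  expect_error(parse_lna_sequence("A+XG"), class = "g4_error_parse")

  # round trip on every catalogued probe
  for (p in g4_probe_catalog(as_tibble = FALSE)) {
    txt <- format_lna_sequence(p$bases, p$lna_mask)
    back <- parse_lna_sequence(txt)
    expect_equal(back$bases, p$bases)
    expect_equal(back$lna_mask, p$lna_mask)
  }
})

test_that("probe FASTA reader/writer round-trips bit-exactly", {
  src <- system.file("extdata", "probes.fa", package = "g4invader")
  probes <- read_lna_fasta(src)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_lna_fasta(probes, tmp)
  expect_identical(readLines(tmp), readLines(src))
  expect_identical(read_lna_fasta(tmp), probes)
})

test_that("CSV readers validate their dialects", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen_fret_trace(600, 30, duration = 1800, seed = 1), tmp)
  tr <- read_trace_csv(tmp)
  expect_named(tr, c("time_s", "signal_au"))
  readr::write_csv(tibble::tibble(a = 1, b = 2), tmp)
  expect_error(read_trace_csv(tmp), class = "g4_error_parse")

  readr::write_csv(gen_pull_cycle(2, seed = 1), tmp)
  expect_named(read_cycle_csv(tmp), c("force_pN", "extension_nm", "phase"))
  bad <- gen_pull_cycle(2, seed = 1)
  bad$phase[1] <- "pull"
  readr::write_csv(bad, tmp)
  expect_error(read_cycle_csv(tmp), class = "g4_error_parse")
})

test_that("the design pipeline regenerates golden probes from the packaged targets", {
  out <- withr::local_tempfile(fileext = ".fa")
  run_pipeline(list(subcommand = "design",
                    target = system.file("extdata", "targets.fa",
                                         package = "g4invader"),
                    strategy = "middle_g", n_lna = 4, out = out))
  written <- read_lna_fasta(out)
  kit3 <- g4_probe_catalog(as_tibble = FALSE)$KIT_LNA3
  row <- written[written$name == "cKIT1_middle_g", ]
  expect_equal(row$bases, kit3$bases)
  expect_equal(row$lna_mask[[1]], kit3$lna_mask)
  expect_true(file.exists(paste0(out, ".runlog.json")))
})

test_that("simulate-then-fit round trip recovers the simulated half-life", {
  dir <- withr::local_tempdir()
  spec <- file.path(dir, "spec.json")
  trace <- file.path(dir, "trace.csv")
  fitjson <- file.path(dir, "fit.json")
  jsonlite::write_json(list(t_half = 1200, sampling_interval = 60,
                            noise_sd = 0.01, seed = 42),
                       spec, auto_unbox = TRUE)
  run_pipeline(list(subcommand = "simulate_fret", spec = spec, out = trace))
  run_pipeline(list(subcommand = "kinetics_fit", trace = trace, out = fitjson))
  rep <- jsonlite::read_json(fitjson)
  expect_equal(rep$t_half_s, 1200, tolerance = 0.05 * 1200)
  expect_false(rep$biphasic)

  # reruns are byte-identical
  fitjson2 <- file.path(dir, "fit2.json")
  run_pipeline(list(subcommand = "kinetics_fit", trace = trace, out = fitjson2))
  expect_identical(readLines(fitjson), readLines(fitjson2))
})

test_that("invalid configurations fail loudly without partial output", {
  out <- withr::local_tempfile(fileext = ".json")
  expect_error(run_pipeline(list(subcommand = "kinetics_fit",
                                 trace = "does-not-exist.csv", out = out)),
               class = "g4_error_config")
  expect_false(file.exists(out))
  expect_error(run_pipeline(list(subcommand = "frobnicate")),
               class = "g4_error_config")
  expect_error(run_pipeline(list(subcommand = "design", strategy = "middle_g")),
               class = "g4_error_config")
})

test_that("pull and extension pipeline stages emit the documented JSON reports", {
  dir <- withr::local_tempdir()
  cyc_csv <- file.path(dir, "cycle.csv")
  readr::write_csv(gen_pull_cycle(21, seed = 8), cyc_csv)
  outj <- file.path(dir, "pull.json")
  run_pipeline(list(subcommand = "pull_analyze", cycle = cyc_csv, out = outj))
  rep <- jsonlite::read_json(outj)
  expect_equal(rep$n_total, 21)
  expect_equal(rep$delta_l_at_10pN_nm, 21 * 9, tolerance = 1)

  stallj <- file.path(dir, "stall.json")
  run_pipeline(list(
    subcommand = "extension_stall_site",
    template = system.file("extdata", "extension_template.fa", package = "g4invader"),
    primer = system.file("extdata", "extension_primer.fa", package = "g4invader"),
    g4 = "33:53", out = stallj))
  srep <- jsonlite::read_json(stallj)
  expect_equal(srep$full_length_nt, 91)
  expect_equal(srep$stall_length_nt, 38)
})
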