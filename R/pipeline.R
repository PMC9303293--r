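#' Run a pipeline stage from a configuration list
#'
#' Programmatic entry point behind the `g4invader` command line script.
#' Validates the configuration, executes the requested stage through the
#' package functions, writes the outputs plus a machine-readable JSON run
#' log (inputs, parameters, seeds, package version), and returns the
#' result invisibly. Invalid configurations signal an error of class
#' `g4_error_config`; no partial output is written in that case.
#'
#' @param config Named list: `subcommand` plus stage arguments (below).
#'   Supported subcommands:
#' \describe{
#'   \item{design}{`target` (FASTA path), `strategy`, `n_lna`, optional
#'     `truncate`, `out`.}
#'   \item{kinetics_fit}{`trace` (CSV path), optional `saturation`,
#'     `slow_phase`, `out` (JSON).}
#'   \item{melt}{`curve` (CSV path), `out` (JSON).}
#'   \item{pull_analyze}{`cycle` (CSV path), optional `per_g4`, `lp`, `k`,
#'     `out` (JSON).}
#'   \item{extension_stall_site}{`template` and `primer` (FASTA paths),
#'     `g4` ("start:end"), `out` (JSON).}
#'   \item{extension_analyze}{`lane` (CSV), `windows` (JSON sidecar),
#'     `out` (JSON).}
#'   \item{reporter_analyze}{`wells` (CSV), `control`, `out` (TSV).}
#'   \item{simulate_fret, simulate_melt, simulate_pull, simulate_gel,
#'     simulate_reporter}{`spec` (JSON path mirroring the generator
#'     arguments), `out` (CSV).}
#' }
#' @param log_path Optional run-log path; default `<out>.runlog.json` when
#'   an `out` is configured.
#' @return The stage result, invisibly.
#' @export
run_pipeline <- function(config, log_path = NULL) {
  if (!is.list(config) || is.null(config$subcommand)) {
    abort("`config` must be a list with a `subcommand`.", class = "g4_error_config")
  }
  need <- function(keys) {
    miss <- keys[!keys %in% names(config)]
    if (length(miss)) abort(sprintf("Config for '%s' is missing: %s.",
                                    config$subcommand, paste(miss, collapse = ", ")),
                            class = "g4_error_config")
  }
  need_file <- function(path) {
    if (!file.exists(path)) abort(sprintf("Input file not found: %s.", path),
                                  class = "g4_error_config")
    path
  }
  read_spec <- function(path) jsonlite::read_json(need_file(path), simplifyVector = TRUE)
  write_json_out <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                           digits = NA, pretty = TRUE)

  result <- switch(config$subcommand,
    design = {
      need(c("target", "strategy", "out"))
      targets <- read_lna_fasta(need_file(config$target))
      designs <- purrr::pmap(targets, function(name, bases, ...) {
        tg <- find_g_tracts(bases, id = name)
        d <- design_full_probe(tg, strategy = toupper(config$strategy),
                               n_lna = config$n_lna %||% 4,
                               name = paste0(name, "_", tolower(config$strategy)))
        if (!is.null(config$truncate)) d <- truncate_probe(d, config$truncate)
        d
      })
      write_lna_fasta(designs, config$out)
      designs
    },
    kinetics_fit = {
      need(c("trace", "out"))
      tr <- normalize_trace(read_trace_csv(need_file(config$trace)),
                            saturation = config$saturation %||% "fit")
      phase <- select_slow_phase(tr)
      fit <- fit_one_phase(if (isTRUE(config$slow_phase) && phase$biphasic)
        phase$trace else tr)
      rep <- list(k = fit$k, t_half_s = fit$t_half, se = fit$se_t_half,
                  plateau = fit$plateau, biphasic = phase$biphasic)
      write_json_out(rep, config$out)
      rep
    },
    melt = {
      need(c("curve", "out"))
      mf <- extract_tm(read_melt_csv(need_file(config$curve)))
      write_json_out(list(tm_C = mf$tm, width_C = mf$width), config$out)
      mf
    },
    pull_analyze = {
      need(c("cycle", "out"))
      params <- elasticity_params(lp = config$lp %||% 0.75, K = config$k %||% 800)
      cfg <- mechanics_config(per_g4_delta_l = config$per_g4 %||% 9)
      res <- analyze_pull_cycle(read_cycle_csv(need_file(config$cycle)), params, cfg)
      write_json_out(as.list(res), config$out)
      res
    },
    extension_stall_site = {
      need(c("template", "primer", "g4", "out"))
      tmpl <- read_lna_fasta(need_file(config$template))$bases[1]
      prm <- read_lna_fasta(need_file(config$primer))$bases[1]
      iv <- as.integer(strsplit(config$g4, ":")[[1]])
      asm <- predict_stall_product_length(tmpl, prm, iv,
                                          stall_offset = config$stall_offset %||% 0)
      write_json_out(list(full_length_nt = asm$full_length_nt,
                          stall_length_nt = asm$stall_length_nt,
                          primer_site = asm$primer_site), config$out)
      asm
    },
    extension_analyze = {
      need(c("lane", "windows", "out"))
      windows <- lapply(read_spec(config$windows), as.numeric)
      res <- quantify_lane(read_lane_csv(need_file(config$lane)), windows)
      write_json_out(as.list(res), config$out)
      res
    },
    reporter_analyze = {
      need(c("wells", "control", "out"))
      res <- analyze_reporter(read_wells_csv(need_file(config$wells)),
                              control = config$control)
      out_tbl <- res$tests$comparisons
      readr::write_tsv(out_tbl, config$out)
      res
    },
    simulate_fret = {
      need(c("spec", "out"))
      df <- do.call(gen_fret_trace, read_spec(config$spec))
      readr::write_csv(df, config$out)
      df
    },
    simulate_melt = {
      need(c("spec", "out"))
      df <- do.call(gen_melt_curve, read_spec(config$spec))
      readr::write_csv(df, config$out)
      df
    },
    simulate_pull = {
      need(c("spec", "out"))
      df <- do.call(gen_pull_cycle, read_spec(config$spec))
      readr::write_csv(df, config$out)
      df
    },
    simulate_gel = {
      need(c("spec", "out"))
      df <- do.call(gen_gel_lane, read_spec(config$spec))
      readr::write_csv(df, config$out)
      df
    },
    simulate_reporter = {
      need(c("spec", "out"))
      spec <- read_spec(config$spec)
      spec$conditions <- as_tibble(spec$conditions)
      df <- do.call(gen_reporter_dataset, spec)
      readr::write_csv(df, config$out)
      df
    },
    abort(sprintf("Unknown subcommand '%s'.", config$subcommand),
          class = "g4_error_config")
  )
  if (!is.null(config$out)) {
    log_path <- log_path %||% paste0(config$out, ".runlog.json")
    log <- list(subcommand = config$subcommand,
                config = config[setdiff(names(config), "subcommand")],
                package = "g4invader",
                version = as.character(utils::packageVersion("g4invader")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, null = "null")
  }
  invisible(result)
}
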