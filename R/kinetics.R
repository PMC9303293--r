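#' One-phase exponential association fit (internal engine)
#'
#' Fits P(t) = baseline + (plateau - baseline) * (1 - exp(-k t)) by
#' Levenberg-Marquardt least squares. k is initialised from a log-linear
#' regression of log(plateau_hat - P) on t with plateau_hat = 1.05 * max(P),
#' and bounded to (1e-7, 1) 1/s.
#' @keywords internal
#' @noRd
fit_exp_core <- function(times, signal, fit_baseline = FALSE) {
  s0 <- signal[1]
  plateau0 <- 1.05 * max(signal)
  if (plateau0 <= s0 || diff(range(signal)) < 1e-9 * max(abs(signal), 1)) {
    abort("Trace is flat or decreasing: no disruption signal to fit.",
          class = "g4_error_fit")
  }
  resid0 <- pmax(plateau0 - signal, 1e-9 * (plateau0 - s0))
  k0 <- -unname(coef(lm(log(resid0) ~ times))[2])
  k0 <- min(max(k0, 1e-6), 0.5)
  df <- data.frame(t = times, y = signal)
  fit <- tryCatch({
    if (fit_baseline) {
      minpack.lm::nlsLM(y ~ b + (A - b) * (1 - exp(-k * t)), data = df,
                        start = list(A = plateau0, k = k0, b = s0),
                        lower = c(A = -Inf, k = 1e-7, b = -Inf),
                        upper = c(A = Inf, k = 1, b = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ s0 + (A - s0) * (1 - exp(-k * t)), data = df,
                        start = list(A = plateau0, k = k0),
                        lower = c(A = -Inf, k = 1e-7), upper = c(A = Inf, k = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(paste0("One-phase fit did not converge: ", conditionMessage(e)),
          class = "g4_error_fit")
  })
  cf <- coef(fit)
  b <- if (fit_baseline) unname(cf["b"]) else s0
  if (cf[["k"]] <= 1e-7 || cf[["A"]] <= b) {
    abort("One-phase fit degenerate (k <= 0 or plateau <= baseline).",
          class = "g4_error_fit")
  }
  list(fit = fit, k = unname(cf["k"]), plateau = unname(cf["A"]), baseline = b)
}

check_trace <- function(data, time_col, signal_col) {
  if (!all(c(time_col, signal_col) %in% names(data))) {
    abort(sprintf("Trace needs columns `%s` and `%s`.", time_col, signal_col),
          class = "g4_error_parse")
  }
  t <- data[[time_col]]; y <- data[[signal_col]]
  if (length(t) < 5) abort("Need at least 5 points to fit.", class = "g4_error_fit")
  if (any(diff(t) <= 0)) abort("Times must be strictly increasing.",
                               class = "g4_error_parse")
  list(times = t - t[1], signal = y)
}

#' Normalise a FRET disruption trace to the 0-100% scale
#'
#' Rescales a raw fluorescence trace so the signal at t = 0 is 0% and the
#' saturation level is 100%. The saturation level is the plateau of a
#' one-phase exponential fit (robust to noise in the final points);
#' `saturation = "last5"` uses the mean of the last 5 points instead.
#' Idempotent on already-normalised traces.
#'
#' @param data Data frame with columns `time_s` and `signal_au` (or
#'   `percent`, which is accepted as the signal).
#' @param saturation `"fit"` (default) or `"last5"`.
#' @return Tibble with columns `time_s` and `percent`.
#' @export
normalize_trace <- function(data, saturation = c("fit", "last5")) {
  saturation <- match.arg(saturation)
  sig_col <- if ("signal_au" %in% names(data)) "signal_au" else "percent"
  tr <- check_trace(data, "time_s", sig_col)
  s0 <- tr$signal[1]
  sat <- if (saturation == "fit") {
    fit_exp_core(tr$times, tr$signal)$plateau
  } else {
    mean(utils::tail(tr$signal, 5))
  }
  if (abs(sat - s0) < 1e-9 * max(abs(tr$signal), 1)) {
    abort("Flat trace: saturation equals the starting signal (no disruption).",
          class = "g4_error_fit")
  }
  tibble(time_s = tr$times, percent = (tr$signal - s0) / (sat - s0) * 100)
}

#' Fit pseudo-first-order disruption kinetics to a normalised trace
#'
#' Least-squares fit of P(t) = plateau * (1 - exp(-k t)) on the 0-100%
#' scale, the pseudo-first-order model for probe invasion with the probe in
#' excess. The apparent half-life is t1/2 = ln(2)/k; its standard error is
#' propagated from se(k).
#'
#' @param data Normalised trace (columns `time_s`, `percent`), e.g. from
#'   [normalize_trace()].
#' @return Object of class `g4_kinfit` with [tidy()], [glance()] and
#'   [autoplot()] methods; elements `k`, `t_half`, `se_t_half`, `plateau`,
#'   `baseline`, `rss`, `converged`.
#' @examples
#' tr <- gen_fret_trace(t_half = 600, sampling_interval = 30,
#'                      duration = 1800, noise_sd = 0, seed = 1)
#' fit_one_phase(normalize_trace(tr))
#' @export
fit_one_phase <- function(data) {
  tr <- check_trace(data, "time_s", if ("percent" %in% names(data)) "percent" else "signal_au")
  # the baseline is co-fitted: anchoring the curve at the (noisy) first point
  # would leak its noise into k and understate se(k)
  core <- fit_exp_core(tr$times, tr$signal, fit_baseline = TRUE)
  se_k <- tryCatch(sqrt(diag(vcov(core$fit)))[["k"]], error = function(e) NA_real_)
  structure(list(
    k = core$k, t_half = log(2) / core$k,
    se_k = se_k, se_t_half = se_k * log(2) / core$k^2,
    plateau = core$plateau, baseline = core$baseline,
    rss = sum(stats::resid(core$fit)^2), n = length(tr$times),
    converged = TRUE, data = tibble(time_s = tr$times, percent = tr$signal),
    fit = core$fit), class = "g4_kinfit")
}

#' @export
print.g4_kinfit <- function(x, ...) {
  cat(sprintf("<g4_kinfit> k = %.4g 1/s, t1/2 = %.1f s (se %.2g), plateau = %.1f%%\n",
              x$k, x$t_half, x$se_t_half, x$plateau))
  invisible(x)
}

#' @method tidy g4_kinfit
#' @export
tidy.g4_kinfit <- function(x, ...) {
  tibble(term = c("k", "t_half", "plateau"),
         estimate = c(x$k, x$t_half, x$plateau),
         std.error = c(x$se_k, x$se_t_half, NA_real_))
}

#' @method glance g4_kinfit
#' @export
glance.g4_kinfit <- function(x, ...) {
  tibble(k = x$k, t_half_s = x$t_half, se_t_half_s = x$se_t_half,
         plateau = x$plateau, baseline = x$baseline, rss = x$rss,
         n = x$n, converged = x$converged)
}

#' @method autoplot g4_kinfit
#' @export
autoplot.g4_kinfit <- function(object, ...) {
  pred <- tibble(time_s = seq(0, max(object$data$time_s), length.out = 200))
  pred$percent <- object$baseline +
    (object$plateau - object$baseline) * (1 - exp(-object$k * pred$time_s))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s, y = .data$percent)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "G4 disrupted (%)",
                  title = sprintf("t1/2 = %.0f s", object$t_half)) +
    ggplot2::theme_minimal()
}

#' Detect a biphasic trace and isolate its slow phase
#'
#' Fits one- and two-phase exponential association models and compares
#' them by the extra-sum-of-squares F-test at alpha = 0.05. If the trace is
#' biphasic, the fitted fast component is subtracted and the remainder
#' rescaled to a 0-100% slow-phase trace, ready for [fit_one_phase()]; the
#' slow phase is the component with the smaller rate constant. Monophasic
#' traces pass through unchanged.
#'
#' @param data Normalised trace (columns `time_s`, `percent`).
#' @param alpha F-test significance level (default 0.05).
#' @return List of class `g4_phase_report`: `trace` (tibble), `biphasic`,
#'   `f_statistic`, `p_value`, and when biphasic `fast`/`slow` tibbles
#'   (amplitude, k, t_half).
#' @export
select_slow_phase <- function(data, alpha = 0.05) {
  tr <- check_trace(data, "time_s", "percent")
  one <- fit_exp_core(tr$times, tr$signal)
  rss1 <- sum(stats::resid(one$fit)^2)
  n <- length(tr$times)
  df2 <- data.frame(t = tr$times, y = tr$signal)
  two <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Af * (1 - exp(-kf * t)) + As * (1 - exp(-ks * t)), data = df2,
      start = list(Af = 0.3 * one$plateau, kf = min(5 * one$k, 0.5),
                   As = 0.7 * one$plateau, ks = one$k / 3),
      lower = c(Af = 0, kf = 1e-7, As = 0, ks = 1e-7),
      upper = c(Af = Inf, kf = 1, As = Inf, ks = 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  passthrough <- function(f = NA_real_, p = NA_real_) {
    structure(list(trace = tibble(time_s = tr$times, percent = tr$signal),
                   biphasic = FALSE, f_statistic = f, p_value = p),
              class = "g4_phase_report")
  }
  if (is.null(two)) return(passthrough())
  rss2 <- sum(stats::resid(two)^2)
  f_stat <- ((rss1 - rss2) / 2) / (rss2 / (n - 4))
  p_val <- pf(f_stat, 2, n - 4, lower.tail = FALSE)
  cf <- coef(two)
  rates <- c(cf[["kf"]], cf[["ks"]]); amps <- c(cf[["Af"]], cf[["As"]])
  slow <- which.min(rates); fast <- which.max(rates)
  distinct <- rates[fast] / rates[slow] > 1.5 && all(amps > 0.05 * sum(amps))
  if (!(is.finite(f_stat) && f_stat > 0 && p_val < alpha && distinct)) {
    return(passthrough(f_stat, p_val))
  }
  slow_pct <- (tr$signal - amps[fast] * (1 - exp(-rates[fast] * tr$times))) *
    100 / amps[slow]
  structure(list(
    trace = tibble(time_s = tr$times, percent = slow_pct),
    biphasic = TRUE, f_statistic = f_stat, p_value = p_val,
    fast = tibble(amplitude = amps[fast], k = rates[fast],
                  t_half = log(2) / rates[fast]),
    slow = tibble(amplitude = amps[slow], k = rates[slow],
                  t_half = log(2) / rates[slow])), class = "g4_phase_report")
}

#' @export
print.g4_phase_report <- function(x, ...) {
  if (x$biphasic) {
    cat(sprintf("<g4_phase_report> biphasic (F = %.1f, p = %.2g); slow t1/2 = %.0f s, fast t1/2 = %.0f s\n",
                x$f_statistic, x$p_value, x$slow$t_half, x$fast$t_half))
  } else {
    cat("<g4_phase_report> monophasic (passthrough)\n")
  }
  invisible(x)
}

#' Replicate summary of fitted half-lives
#'
#' @param t_half Numeric vector of per-replicate half-lives (n >= 2).
#' @return One-row tibble: `n`, `mean_t_half`, `sem_t_half`.
#' @export
summarize_replicates <- function(t_half) {
  t_half <- t_half[is.finite(t_half)]
  if (length(t_half) < 2) abort("Need at least 2 replicates.",
                                class = "g4_error_stats")
  tibble(n = length(t_half), mean_t_half = mean(t_half),
         sem_t_half = sd(t_half) / sqrt(length(t_half)))
}

#' Unpaired two-tailed t test from replicate summaries
#'
#' Student's t computed from summary statistics, as used for published
#' mean +- SEM half-lives: t = |m_a - m_b| / sqrt(sem_a^2 + sem_b^2) with
#' df = n_a + n_b - 2. With equal group sizes and SEMs consistent with the
#' sample SDs this is exactly the classic pooled two-sample t test.
#'
#' @param a,b One-row data frames with columns `n`, `mean_t_half`,
#'   `sem_t_half` (from [summarize_replicates()] or built by hand), or
#'   numeric vectors of raw replicate values (raw-replicate mode, which
#'   uses [stats::t.test()] with pooled variance).
#' @return Tibble with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' a <- tibble::tibble(n = 3, mean_t_half = 1753, sem_t_half = 70)
#' b <- tibble::tibble(n = 3, mean_t_half = 628, sem_t_half = 40)
#' compare_half_lives(a, b)  # p ~ 0.0002
#' @export
compare_half_lives <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) < 2 || length(b) < 2) abort("Need n >= 2 per group.",
                                              class = "g4_error_stats")
    if (sd(a) == 0 && sd(b) == 0) {  # degenerate: all replicates identical
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(tibble(t = if (same) 0 else Inf,
                    df = length(a) + length(b) - 2,
                    p = if (same) 1 else 0, mean_a = mean(a), mean_b = mean(b)))
    }
    tt <- t.test(a, b, var.equal = TRUE)
    return(tibble(t = abs(unname(tt$statistic)), df = unname(tt$parameter),
                  p = tt$p.value, mean_a = mean(a), mean_b = mean(b)))
  }
  need <- c("n", "mean_t_half", "sem_t_half")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    abort("Summaries need columns n, mean_t_half, sem_t_half.",
          class = "g4_error_stats")
  }
  if (a$n < 2 || b$n < 2) abort("Need n >= 2 per group.", class = "g4_error_stats")
  pooled_se <- sqrt(a$sem_t_half^2 + b$sem_t_half^2)
  if (pooled_se <= 0) abort("Zero pooled standard error.", class = "g4_error_stats")
  t_stat <- abs(a$mean_t_half - b$mean_t_half) / pooled_se
  df <- a$n + b$n - 2
  tibble(t = t_stat, df = df, p = 2 * pt(-t_stat, df),
         mean_a = a$mean_t_half, mean_b = b$mean_t_half)
}
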