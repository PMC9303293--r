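#' Renilla/Firefly ratios per well
#'
#' The Renilla gene sits behind the G4-containing promoter; Firefly is the
#' co-transfected control, so the per-well ratio normalises for
#' transfection efficiency.
#'
#' @param wells Data frame with columns `condition`, `renilla`, `firefly`
#'   (both luminescence values must be positive); extra columns
#'   (`dataset`, `replicate`, ...) pass through.
#' @return The input tibble with a `ratio` column.
#' @export
rr_ff_ratio <- function(wells) {
  stopifnot(all(c("condition", "renilla", "firefly") %in% names(wells)))
  if (any(wells$firefly <= 0) || any(wells$renilla <= 0)) {
    abort("Luminescence values must be positive.", class = "g4_error_stats")
  }
  dplyr::mutate(as_tibble(wells), ratio = .data$renilla / .data$firefly)
}

#' Normalise values so the dataset maximum is 100%
#'
#' @param values Numeric vector with at least one positive value.
#' @return `values * 100 / max(values)`; the maximum maps to exactly 100.
#' @examples
#' normalize_to_max(c(4, 2, 1))
#' @export
normalize_to_max <- function(values) {
  if (!length(values) || all(!is.finite(values)) || max(values, na.rm = TRUE) <= 0) {
    abort("Need at least one positive value to normalise.",
          class = "g4_error_stats")
  }
  values * 100 / max(values, na.rm = TRUE)
}

#' Shapiro-Wilk normality test
#'
#' Wrapper around Royston's approximation as implemented in
#' [stats::shapiro.test()], with the degenerate cases made explicit. At the
#' study's n = 3 the test has very low power; a non-significant result
#' there is compatible with normality, not evidence of it.
#'
#' @param sample Numeric vector, 3 <= n <= 50.
#' @return One-row tibble: `n`, `W`, `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3 || n > 50) abort("Shapiro-Wilk requires 3 <= n <= 50.",
                             class = "g4_error_stats")
  if (sd(sample) == 0) abort("Zero-variance sample: W undefined.",
                             class = "g4_error_stats")
  sw <- shapiro.test(sample)
  tibble(n = n, W = unname(sw$statistic), p = sw$p.value)
}

#' Dunnett many-to-one adjusted p-value
#'
#' Two-sided adjusted p for the maximum-modulus statistic over k
#' comparisons against a shared control, from the k-variate central t
#' distribution with the Dunnett correlation structure
#' rho_jl = sqrt(n_j n_l / ((n_j + n0)(n_l + n0))) (1/2 for balanced
#' designs). For k <= 3 the integral uses mvtnorm's deterministic TVPACK
#' quadrature; larger k falls back to seeded Genz-Bretz quasi-Monte-Carlo
#' at 1e-4 tolerance.
#' @keywords internal
#' @noRd
dunnett_p_adjust <- function(t_stat, n_treat, n_control, df) {
  k <- length(n_treat)
  if (k == 1) return(2 * pt(-abs(t_stat), df))
  g <- sqrt(n_treat / (n_treat + n_control))
  # Conditioning on the shared control variate z0 and the pooled-scale chi
  # variate s factorises P(max|T_i| <= t) for the Dunnett correlation
  # rho_ij = g_i g_j into a product of normal probabilities:
  #   E_{z0,s} prod_i [ Phi((t s - g_i z0)/h_i) - Phi((-t s - g_i z0)/h_i) ]
  # with h_i = sqrt(1 - g_i^2); evaluated by trapezoidal quadrature.
  z0 <- seq(-8, 8, length.out = 201)
  wz <- stats::dnorm(z0); wz <- wz / sum(wz)
  s_hi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  s <- seq(1e-4, s_hi, length.out = 201)
  ds <- s[2] - s[1]
  log_fs <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(s) - df * s^2 / 2
  ws <- exp(log_fs) * ds; ws <- ws / sum(ws)
  h <- sqrt(1 - g^2)
  vapply(abs(t_stat), function(tv) {
    prod_i <- matrix(1, length(s), length(z0))
    for (i in seq_len(k)) {
      upper <- outer(tv * s, g[i] * z0, function(a, b) (a - b) / h[i])
      lower <- outer(-tv * s, g[i] * z0, function(a, b) (a - b) / h[i])
      prod_i <- prod_i * (stats::pnorm(upper) - stats::pnorm(lower))
    }
    p_in <- sum((prod_i %*% wz) * ws)
    min(max(1 - p_in, 0), 1)
  }, numeric(1))
}

#' One-way ANOVA followed by Dunnett's many-to-one comparisons
#'
#' The reporter-assay testing scheme: a one-way ANOVA across all
#' conditions gates the analysis, then each condition is compared with the
#' control by Dunnett's test (two-sided, pooled error variance, equal-
#' correlation multivariate t for the family-wise adjustment).
#'
#' @param data Data frame with a grouping column and a value column.
#' @param control Label of the control condition.
#' @param value Name of the value column (default `"ratio"`).
#' @param condition Name of the grouping column (default `"condition"`).
#' @return Object of class `g4_dunnett`: `anova` tibble
#'   (`f`, `df1`, `df2`, `p`) and `comparisons` tibble (`condition`,
#'   `estimate`, `t`, `df`, `p_unadjusted`, `p_adjusted`).
#' @examples
#' set.seed(1)
#' d <- data.frame(condition = rep(c("ctrl", "a", "b"), each = 3),
#'                 ratio = rnorm(9, rep(c(1, 1, 2), each = 3), 0.1))
#' anova_dunnett(d, control = "ctrl")
#' @export
anova_dunnett <- function(data, control, value = "ratio",
                          condition = "condition") {
  stopifnot(all(c(value, condition) %in% names(data)))
  grp <- as.character(data[[condition]])
  y <- data[[value]]
  if (!control %in% grp) abort(sprintf("Control condition '%s' not present.", control),
                               class = "g4_error_stats")
  ns <- table(grp)
  if (length(ns) < 2 || any(ns < 2)) {
    abort("Need the control plus >= 1 condition, n >= 2 each.",
          class = "g4_error_stats")
  }
  fit <- aov(y ~ g, data = data.frame(y = y, g = factor(grp)))
  an <- summary(fit)[[1]]
  anova_tbl <- tibble(f = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                      p = an$`Pr(>F)`[1])
  s2 <- an$`Mean Sq`[2]          # pooled error variance
  df_err <- an$Df[2]
  treats <- setdiff(names(ns), control)
  m0 <- mean(y[grp == control]); n0 <- ns[[control]]
  est <- unname(vapply(treats, function(g) mean(y[grp == g]) - m0, numeric(1)))
  n_t <- unname(vapply(treats, function(g) ns[[g]], numeric(1)))
  t_stat <- est / sqrt(s2 * (1 / n_t + 1 / n0))
  comparisons <- tibble(
    condition = treats, estimate = est, t = t_stat, df = df_err,
    p_unadjusted = 2 * pt(-abs(t_stat), df_err),
    p_adjusted = dunnett_p_adjust(t_stat, n_t, n0, df_err))
  structure(list(anova = anova_tbl, comparisons = comparisons,
                 control = control), class = "g4_dunnett")
}

#' @export
print.g4_dunnett <- function(x, ...) {
  cat(sprintf("<g4_dunnett> one-way ANOVA F(%d,%d) = %.2f, p = %.3g; control = %s\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p, x$control))
  print(x$comparisons)
  invisible(x)
}

#' @method tidy g4_dunnett
#' @export
tidy.g4_dunnett <- function(x, ...) x$comparisons

#' @method glance g4_dunnett
#' @export
glance.g4_dunnett <- function(x, ...) x$anova

#' Full reporter-assay pipeline
#'
#' Per-well Renilla/Firefly ratios, max-normalisation within each
#' biological dataset (or on condition means), then ANOVA + Dunnett
#' against the control.
#'
#' @param wells Data frame with `condition`, `renilla`, `firefly` and
#'   optionally `dataset` (biological replicate batch).
#' @param control Control condition label.
#' @param normalize `"replicates"` (default): normalise replicate ratios
#'   within each dataset; `"means"`: normalise condition means.
#' @return List of class `g4_reporter_result`: `data` (normalised tibble),
#'   `normality` (per-condition Shapiro-Wilk), `tests` (`g4_dunnett`).
#' @export
analyze_reporter <- function(wells, control,
                             normalize = c("replicates", "means")) {
  normalize <- match.arg(normalize)
  df <- rr_ff_ratio(wells)
  if (!"dataset" %in% names(df)) df$dataset <- 1L
  df <- df |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(percent = normalize_to_max(.data$ratio)) |>
    dplyr::ungroup()
  value_col <- "percent"
  if (normalize == "means") {
    df <- df |>
      dplyr::group_by(.data$condition, .data$dataset) |>
      dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop") |>
      dplyr::group_by(.data$dataset) |>
      dplyr::mutate(percent = normalize_to_max(.data$ratio)) |>
      dplyr::ungroup()
  }
  # a condition that holds the dataset maximum everywhere is constant after
  # max-normalisation; report NA rather than fail the whole analysis
  sw_safe <- function(x) tryCatch(shapiro_wilk(x), error = function(e)
    tibble(n = length(x), W = NA_real_, p = NA_real_))
  normality <- df |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(sw_safe(.data$percent), .groups = "drop")
  tests <- anova_dunnett(df, control = control, value = value_col)
  structure(list(data = df, normality = normality, tests = tests),
            class = "g4_reporter_result")
}

#' @export
print.g4_reporter_result <- function(x, ...) {
  cat("<g4_reporter_result>\n")
  print(x$tests)
  invisible(x)
}

#' @method autoplot g4_reporter_result
#' @export
autoplot.g4_reporter_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$condition, y = .data$percent)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.7) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "Renilla/Firefly (% of max)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
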