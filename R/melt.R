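#' Extract the melting temperature from a UV melting curve
#'
#' Normalises the heating branch of a 260 nm absorbance melting curve with
#' the lower and upper asymptotes set to 0% and 100%, then reports the
#' linearly interpolated temperature of the 50% crossing. Asymptotes are
#' estimated from a two-state (logistic) fit, which also guards against
#' degenerate curves with no plateaus; among multiple noise-induced 50%
#' crossings the one nearest the logistic midpoint is used.
#'
#' @param data Data frame with ascending `temp_C` and `abs260` columns
#'   (heating branch; a cooling branch, if present as a `branch` column,
#'   is dropped).
#' @param min_points Minimum number of points (default 10).
#' @return List of class `g4_meltfit`: `tm`, `normalized` (tibble
#'   `temp_C`, `percent`), `asymptotes`, `width`.
#' @examples
#' mc <- gen_melt_curve(tm = 65, noise_sd = 0, seed = 1)
#' extract_tm(mc)$tm
#' @export
extract_tm <- function(data, min_points = 10) {
  if ("branch" %in% names(data)) data <- data[data$branch == "heating", ]
  if (!all(c("temp_C", "abs260") %in% names(data))) {
    abort("Melt curve needs columns `temp_C` and `abs260`.",
          class = "g4_error_parse")
  }
  tt <- data$temp_C; A <- data$abs260
  if (length(tt) < min_points) abort("Too few points for Tm extraction.",
                                     class = "g4_error_fit")
  if (any(diff(tt) <= 0)) abort("Temperatures must be strictly increasing.",
                                class = "g4_error_parse")
  span <- diff(range(tt))
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ lo + (hi - lo) / (1 + exp(-(tt - tm) / w)),
                      start = list(lo = min(A), hi = max(A),
                                   tm = tt[which.min(abs(A - mean(range(A))))],
                                   w = span / 20),
                      lower = c(lo = -Inf, hi = -Inf, tm = min(tt), w = 1e-3),
                      upper = c(lo = Inf, hi = Inf, tm = max(tt), w = span),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) abort("Two-state fit failed: cannot locate asymptotes.",
                          class = "g4_error_fit")
  cf <- coef(fit)
  # a transition needs both plateaus inside the scanned range
  if (cf[["w"]] > span / 4 || cf[["hi"]] - cf[["lo"]] <= 0 ||
      cf[["tm"]] - 2 * cf[["w"]] < min(tt) || cf[["tm"]] + 2 * cf[["w"]] > max(tt)) {
    abort("No sigmoidal transition with both asymptotes inside the range.",
          class = "g4_error_fit")
  }
  pct <- (A - cf[["lo"]]) / (cf[["hi"]] - cf[["lo"]]) * 100
  cross <- which(diff(sign(pct - 50)) != 0)
  if (!length(cross)) abort("Normalised curve never crosses 50%.",
                            class = "g4_error_fit")
  i <- cross[which.min(abs(tt[cross] - cf[["tm"]]))]
  tm <- tt[i] + (50 - pct[i]) / (pct[i + 1] - pct[i]) * (tt[i + 1] - tt[i])
  structure(list(tm = tm,
                 normalized = tibble(temp_C = tt, percent = pct),
                 asymptotes = c(lower = unname(cf[["lo"]]), upper = unname(cf[["hi"]])),
                 width = unname(cf[["w"]])),
            class = "g4_meltfit")
}

#' @export
print.g4_meltfit <- function(x, ...) {
  cat(sprintf("<g4_meltfit> Tm = %.1f degC (transition width %.2f degC)\n",
              x$tm, x$width))
  invisible(x)
}

#' @method autoplot g4_meltfit
#' @export
autoplot.g4_meltfit <- function(object, ...) {
  ggplot2::ggplot(object$normalized,
                  ggplot2::aes(x = .data$temp_C, y = .data$percent)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$tm, colour = "firebrick") +
    ggplot2::labs(x = "Temperature (degC)", y = "Unfolded (%)",
                  title = sprintf("Tm = %.1f degC", object$tm)) +
    ggplot2::theme_minimal()
}
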