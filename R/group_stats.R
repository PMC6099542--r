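#' Dose-normalized activity concentrations
#'
#' `percent_id_per_g()` expresses a tissue concentration as percentage of
#' the injected dose per gram; `suv()` normalizes by injected dose per body
#' weight (standardized uptake value).
#'
#' @param conc activity concentration (per g for %ID/g, per mL for SUV).
#' @param injected_dose injected activity, > 0 (same activity unit as conc).
#' @param body_weight body weight in g, > 0.
#' @return numeric, vectorized over `conc`.
#' @export
percent_id_per_g <- function(conc, injected_dose) {
  if (any(injected_dose <= 0)) stop("injected dose must be positive")
  100 * conc / injected_dose
}

#' @rdname percent_id_per_g
#' @export
suv <- function(conc, injected_dose, body_weight) {
  if (any(injected_dose <= 0)) stop("injected dose must be positive")
  if (any(body_weight <= 0)) stop("body weight must be positive")
  conc / (injected_dose / body_weight)
}

#' Area under a time-activity curve
#'
#' Trapezoid rule over frame mid-times, with the curve anchored at 0 at
#' t = 0 (no activity before injection) and held at the last frame's value
#' out to the end of the scan, so the integral covers the full 0-7200 s
#' acquisition. Times in seconds, so for a 120-minute scan in %ID/g the
#' result is in %ID/g.s and of order 10^4.
#'
#' @param x a `tac` in %ID/g.
#' @return the AUC in %ID/g.s.
#' @examples
#' auc_trapezoid(tac(default_frame_schedule(), rep(1, 25)))  # ~7200
#' @export
auc_trapezoid <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (x$unit != "%ID/g")
    stop("AUC is defined for %ID/g curves; got unit '", x$unit, "'")
  nf <- length(x$value)
  t_end <- x$schedule$start_s[nf] + x$schedule$duration_s[nf]
  t <- c(0, x$schedule$mid_s, t_end)
  y <- c(0, x$value, x$value[nf])
  sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
}

#' Welch two-sample comparison
#'
#' Welch's unequal-variance t test of group `b` against group `a`, wrapping
#' `stats::t.test`. For one-sided tests the hypothesized direction is
#' `mean(b) > mean(a)` by default (in this study: LPS greater than control).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param sides `"one"` or `"two"`.
#' @param direction `"b_greater"` (default) or `"two_sided"`; ignored when
#'   `sides = "two"`.
#' @param parameter label carried into the result.
#' @return list of class `group_comparison`: per-group mean and sd, `t_stat`
#'   (positive when mean(b) > mean(a)), `df`, `p_value`, `welch = TRUE`,
#'   `sides`, `direction`.
#' @export
welch_t_test <- function(a, b, sides = c("one", "two"),
                         direction = "b_greater", parameter = "") {
  sides <- match.arg(sides)
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: each group needs at least 2 observations")
  alt <- if (sides == "two") "two.sided" else "greater"
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (se < .Machine$double.eps * max(abs(mean(a)), abs(mean(b)), 1)) {
    # degenerate (constant) samples: t.test refuses; report the limit
    d <- mean(b) - mean(a)
    ht <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               parameter = length(a) + length(b) - 2,
               p.value = if (d == 0) {
                 if (sides == "two") 1 else 0.5
               } else if (sides == "two" || d > 0) .Machine$double.xmin
               else 1)
  } else {
    ht <- stats::t.test(x = b, y = a, alternative = alt, var.equal = FALSE)
  }
  structure(
    list(parameter = parameter,
         mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
         mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
         t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), welch = TRUE, sides = sides,
         direction = if (sides == "two") "two_sided" else direction),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison>%s a: %.3f +/- %.3f (n=%d); b: %.3f +/- %.3f (n=%d)\n",
    if (nzchar(x$parameter)) paste0(" ", x$parameter, ":") else "",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  Welch t = %.3f, df = %.2f, %s-sided p = %.4g\n",
              x$t_stat, x$df, x$sides, x$p_value))
  invisible(x)
}

#' Fold change between group means
#'
#' Ratio of two positive means, reported to 2 decimals (densitometry
#' convention).
#'
#' @param mean_numerator,mean_denominator positive means.
#' @return `round(mean_numerator / mean_denominator, 2)`.
#' @examples
#' fold_change(0.93, 0.43)   # 2.16
#' @export
fold_change <- function(mean_numerator, mean_denominator) {
  if (any(mean_denominator <= 0)) stop("denominator mean must be positive")
  round(mean_numerator / mean_denominator, 2)
}

#' Group summary table for kinetic fits
#'
#' Per-parameter mean +/- SD per group with Welch tests: one-sided
#' (treated > control) for K1, k2, k3/k4, Kb and VT, two-sided for the
#' regional AUC when provided. Fits are expected to be exclusion-filtered
#' already.
#'
#' @param fits_control,fits_lps non-empty lists of `kinetic_fit` objects.
#' @param auc_control,auc_lps optional numeric AUC vectors per group.
#' @return data.frame with one row per parameter: group means, SDs, n,
#'   Welch t, df, p, and the sides used.
#' @export
summarize_groups <- function(fits_control, fits_lps,
                             auc_control = NULL, auc_lps = NULL) {
  if (length(fits_control) == 0L || length(fits_lps) == 0L)
    stop("insufficient data: both groups must be non-empty")
  pull <- function(fits, what) vapply(fits, what, numeric(1L))
  extractors <- list(
    K1 = function(f) f$params$K1,
    k2 = function(f) f$params$k2,
    `k3/k4` = function(f) f$macro$BPND,
    Kb = function(f) f$params$Kb,
    VT = function(f) f$macro$VT)
  rows <- lapply(names(extractors), function(nm) {
    a <- pull(fits_control, extractors[[nm]])
    b <- pull(fits_lps, extractors[[nm]])
    cmp <- welch_t_test(a, b, sides = "one", parameter = nm)
    data.frame(parameter = nm,
               control_mean = cmp$mean_a, control_sd = cmp$sd_a,
               control_n = cmp$n_a,
               lps_mean = cmp$mean_b, lps_sd = cmp$sd_b, lps_n = cmp$n_b,
               t_stat = cmp$t_stat, df = cmp$df, p_value = cmp$p_value,
               sides = cmp$sides)
  })
  if (!is.null(auc_control) && !is.null(auc_lps)) {
    cmp <- welch_t_test(auc_control, auc_lps, sides = "two",
                        parameter = "AUC")
    rows <- c(rows, list(data.frame(
      parameter = "AUC",
      control_mean = cmp$mean_a, control_sd = cmp$sd_a, control_n = cmp$n_a,
      lps_mean = cmp$mean_b, lps_sd = cmp$sd_b, lps_n = cmp$n_b,
      t_stat = cmp$t_stat, df = cmp$df, p_value = cmp$p_value,
      sides = cmp$sides)))
  }
  do.call(rbind, rows)
}
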