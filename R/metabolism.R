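#' Hill-type parent-fraction model
#'
#' The fraction of measured radioactivity still attributable to intact
#' (unmetabolized) tracer at time t after injection, in plasma or in brain.
#' The integrated-Hill form
#' \deqn{PF(t) = 1 - a \frac{t^n}{t^n + t_{50}^n}}
#' guarantees PF(0) = 1 and monotone decline towards the asymptote 1 - a,
#' where `a` is the asymptotic metabolized fraction. This 3-parameter family
#' is standard practice for PET metabolite curves and can interpolate the
#' sparse parent-fraction measurements typical of terminal small-animal
#' sampling.
#'
#' @param compartment `"plasma"` or `"brain"`.
#' @param a asymptotic metabolized fraction, in [0, 1].
#' @param t50 half-metabolism time scale in minutes, > 0.
#' @param n Hill exponent, > 0.
#' @return an object of class `pf_model`.
#' @export
pf_model <- function(compartment = c("plasma", "brain"), a, t50, n) {
  compartment <- match.arg(compartment)
  if (!is.finite(a) || a < 0 || a > 1) stop("a must lie in [0, 1]")
  if (!is.finite(t50) || t50 <= 0) stop("t50 must be positive (minutes)")
  if (!is.finite(n) || n <= 0) stop("Hill exponent n must be positive")
  structure(list(compartment = compartment, form = "hill",
                 a = a, t50 = t50, n = n),
            class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf("<pf_model> %s Hill: a = %.4f, t50 = %.2f min, n = %.3f\n",
              x$compartment, x$a, x$t50, x$n))
  invisible(x)
}

#' Evaluate a parent-fraction model
#'
#' @param model a `pf_model`.
#' @param t time(s) in minutes, >= 0 (vectorized).
#' @return parent fraction(s) in [1 - a, 1].
#' @examples
#' m <- pf_model("plasma", a = 0.7, t50 = 40, n = 1.5)
#' pf_evaluate(m, 0)    # exactly 1
#' @export
pf_evaluate <- function(model, t) {
  stopifnot(inherits(model, "pf_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0")
  tn <- t^model$n
  1 - model$a * tn / (tn + model$t50^model$n)
}

#' Calibrate a parent-fraction model to measured points
#'
#' Least-squares fit of (a, t50, n) to (time, fraction) pairs. With exactly
#' two points the Hill exponent is fixed (default n = 2) so the problem is
#' determined. With >= 3 noiseless points the three-parameter family
#' interpolates them (residuals reported on the returned object).
#'
#' @param time_min calibration times in minutes, > 0.
#' @param fraction measured parent fractions in (0, 1].
#' @param compartment `"plasma"` or `"brain"`.
#' @param n_fixed Hill exponent used when only 2 points are given.
#' @return a `pf_model` with attribute `residuals` (per-point fit residuals).
#' @examples
#' m <- pf_calibrate(c(15, 30, 120), c(0.85, 0.60, 0.35), "plasma")
#' pf_evaluate(m, 30)   # ~0.60
#' @export
pf_calibrate <- function(time_min, fraction,
                         compartment = c("plasma", "brain"), n_fixed = 2) {
  compartment <- match.arg(compartment)
  time_min <- as.numeric(time_min)
  fraction <- as.numeric(fraction)
  if (length(time_min) < 2L)
    stop("insufficient data: at least 2 calibration points are required")
  if (length(fraction) != length(time_min))
    stop("time_min and fraction must have equal length")
  if (any(time_min <= 0)) stop("calibration times must be positive")
  if (any(fraction <= 0 | fraction > 1))
    stop("calibration fractions must lie in (0, 1]")

  two_points <- length(time_min) == 2L
  resid_fn <- function(par) {
    a <- par[1L]; t50 <- exp(par[2L])
    n <- if (two_points) n_fixed else exp(par[3L])
    tn <- time_min^n
    (1 - a * tn / (tn + t50^n)) - fraction
  }
  met <- 1 - fraction                        # metabolized fractions
  start <- c(min(max(max(met) * 1.2, 0.1), 0.99), log(stats::median(time_min)))
  if (!two_points) start <- c(start, log(1.5))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(0, log(1e-3), if (!two_points) log(0.05)),
    upper = c(1, log(1e5), if (!two_points) log(20)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (fit$info < 1 || fit$info > 4)
    stop("parent-fraction calibration did not converge: ", fit$message)
  par <- fit$par
  model <- pf_model(compartment, a = par[1L], t50 = exp(par[2L]),
                    n = if (two_points) n_fixed else exp(par[3L]))
  attr(model, "residuals") <- resid_fn(par)
  model
}

#' Parent fraction from chromatographic peak activities
#'
#' The intact-tracer proportion of total activity given separately counted
#' parent and metabolite peaks.
#'
#' @param parent_peak parent peak activity, >= 0.
#' @param metabolite_peak metabolite peak activity, >= 0.
#' @return `parent_peak / (parent_peak + metabolite_peak)`.
#' @export
parent_fraction_from_counts <- function(parent_peak, metabolite_peak) {
  if (any(parent_peak < 0) || any(metabolite_peak < 0))
    stop("peak activities must be >= 0")
  total <- parent_peak + metabolite_peak
  if (any(total == 0))
    stop("undefined fraction: parent and metabolite peaks are both zero")
  parent_peak / total
}

#' Correct a brain TAC for radiometabolites
#'
#' Multiplies each frame's value by the brain parent fraction at the frame
#' mid-time, yielding the time-activity curve of intact tracer only. The
#' result is tagged `corrected = TRUE`.
#'
#' @param x a brain-region `tac`.
#' @param brain_pf a `pf_model` with `compartment = "brain"`.
#' @return the metabolite-corrected `tac`.
#' @export
correct_tac_for_metabolites <- function(x, brain_pf) {
  stopifnot(inherits(x, "tac"), inherits(brain_pf, "pf_model"))
  if (brain_pf$compartment != "brain")
    stop("compartment mismatch: brain TAC correction needs a brain ",
         "parent-fraction model, got '", brain_pf$compartment, "'")
  pf <- pf_evaluate(brain_pf, x$schedule$mid_min)
  out <- x
  out$value <- x$value * pf
  out$corrected <- TRUE
  out
}
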