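#' Metabolite-corrected arterial input function
#'
#' Continuous-time representation of the parent (unmetabolized) tracer
#' concentration in arterial plasma, Ca(t), plus the total whole-blood curve
#' Cwb(t) feeding the vascular term. Between knots the curves are
#' piecewise-linear; beyond the last knot both decay mono-exponentially at
#' rate `tail_lambda`.
#'
#' @param knot_min knot times in minutes, strictly increasing, starting at 0.
#' @param parent_plasma parent plasma concentration Ca at knots.
#' @param total_blood whole-blood concentration Cwb at knots.
#' @param tail_lambda extrapolation decay rate (min^-1), > 0.
#' @return an object of class `input_function`.
#' @export
input_function <- function(knot_min, parent_plasma, total_blood, tail_lambda) {
  knot_min <- as.numeric(knot_min)
  parent_plasma <- as.numeric(parent_plasma)
  total_blood <- as.numeric(total_blood)
  if (length(knot_min) == 0L ||
      length(parent_plasma) != length(knot_min) ||
      length(total_blood) != length(knot_min))
    stop("knot_min, parent_plasma and total_blood must have equal length")
  if (abs(knot_min[1L]) > 1e-12 || any(diff(knot_min) <= 0))
    stop("knots must be strictly increasing and start at 0")
  if (any(parent_plasma < 0) || any(total_blood < 0))
    stop("input-function values must be >= 0")
  if (any(parent_plasma > total_blood + 1e-9 * pmax(total_blood, 1)))
    stop("parent plasma cannot exceed total blood at any knot")
  if (!is.finite(tail_lambda) || tail_lambda <= 0)
    stop("tail_lambda must be positive")
  structure(list(knot_min = knot_min, parent_plasma = parent_plasma,
                 total_blood = total_blood, tail_lambda = tail_lambda),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function> %d knots, 0 to %.1f min, tail lambda %.4f /min\n",
    length(x$knot_min), max(x$knot_min), x$tail_lambda))
  invisible(x)
}

#' Build the arterial input function from plasma samples
#'
#' Applies the plasma parent-fraction model to the total-plasma samples
#' (parent = total x PF), anchors a (0, 0) knot if absent, and fits the
#' extrapolation tail by log-linear regression on the last three parent
#' knots. The whole-blood curve is total plasma scaled by
#' `blood_to_plasma` (default 1: no hematocrit information).
#'
#' @param samples a `plasma_series`.
#' @param pf a plasma-compartment `pf_model`.
#' @param blood_to_plasma whole-blood to total-plasma concentration ratio.
#' @return an `input_function`.
#' @export
build_aif <- function(samples, pf, blood_to_plasma = 1) {
  stopifnot(inherits(samples, "plasma_series"), inherits(pf, "pf_model"))
  if (pf$compartment != "plasma")
    stop("compartment mismatch: AIF construction needs a plasma ",
         "parent-fraction model, got '", pf$compartment, "'")
  if (length(samples$time_min) < 3L)
    stop("insufficient data: at least 3 plasma samples are required ",
         "to estimate the extrapolation tail")
  t <- samples$time_min
  total <- samples$total_plasma
  parent <- total * pf_evaluate(pf, t)
  if (t[1L] > 0) {
    t <- c(0, t); total <- c(0, total); parent <- c(0, parent)
  }
  last3 <- seq(length(t) - 2L, length(t))
  p3 <- parent[last3]
  if (all(p3 > 0)) {
    tail_lambda <- -stats::coef(stats::lm(log(p3) ~ t[last3]))[[2L]]
    if (!is.finite(tail_lambda) || tail_lambda <= 0) {
      warning("non-decaying parent tail; using fallback tail_lambda = 0.1/min")
      tail_lambda <- 0.1
    }
  } else {
    warning("zero parent activity in tail samples; ",
            "using fallback tail_lambda = 0.1/min")
    tail_lambda <- 0.1
  }
  input_function(t, parent, total * blood_to_plasma, tail_lambda)
}

#' Evaluate an input function
#'
#' Piecewise-linear interpolation between knots; mono-exponential decay at
#' rate `tail_lambda` beyond the last knot. Continuous everywhere,
#' vectorized over `t`.
#'
#' @param aif an `input_function`.
#' @param t time(s) in minutes, >= 0.
#' @param curve `"parent"` (Ca, default) or `"blood"` (Cwb).
#' @return concentration value(s).
#' @export
aif_value <- function(aif, t, curve = c("parent", "blood")) {
  stopifnot(inherits(aif, "input_function"))
  curve <- match.arg(curve)
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0")
  y <- if (curve == "parent") aif$parent_plasma else aif$total_blood
  t_last <- aif$knot_min[length(aif$knot_min)]
  y_last <- y[length(y)]
  out <- numeric(length(t))
  inside <- t <= t_last
  if (any(inside)) {
    out[inside] <- if (length(aif$knot_min) == 1L) y_last else
      stats::approx(aif$knot_min, y, xout = t[inside], rule = 2)$y
  }
  if (any(!inside))
    out[!inside] <- y_last * exp(-aif$tail_lambda * (t[!inside] - t_last))
  out
}
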