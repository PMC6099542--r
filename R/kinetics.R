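#' Kinetic parameters of the two-tissue-compartment + vascular-trapping model
#'
#' The model has a non-displaceable tissue compartment (influx K1, efflux
#' k2), a specific TSPO-binding compartment (exchange k3, k4), and an
#' irreversible vascular compartment fed from whole blood at rate Kb,
#' representing slow binding of the tracer to TSPO on the vascular
#' endothelium. `vB` is the fractional cerebral blood volume weighting the
#' vascular signal; it is fixed (not estimated) to preserve identifiability.
#'
#' @param K1 influx constant, mL.cm^-3.min^-1, >= 0.
#' @param k2,k3,k4,Kb rate constants, min^-1, >= 0.
#' @param vB blood volume fraction, in [0, 0.2]; default 0.05.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, k4, Kb, vB = 0.05) {
  v <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Kb = Kb, vB = vB)
  if (any(!is.finite(v))) stop("kinetic parameters must be finite")
  if (any(v[1:5] < 0)) stop("rate constants must be >= 0")
  if (vB < 0 || vB > 0.2) stop("vB must lie in [0, 0.2]")
  structure(as.list(v), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> K1=%.4f k2=%.4f k3=%.4f k4=%.4f Kb=%.4f vB=%.3f\n",
    x$K1, x$k2, x$k3, x$k4, x$Kb, x$vB))
  invisible(x)
}

#' Impulse response of the reversible tissue compartments
#'
#' Eigen-decomposition of the two-tissue system. The eigenrates are
#' \deqn{\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp
#'   \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}}{2}}
#' and the tissue response to a unit plasma impulse is
#' \deqn{h(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right].}
#' When the eigenrates coincide the confluent limit
#' \eqn{h(t) = K_1 e^{-\alpha t}[1 + (k_3+k_4-\alpha)t]} is used.
#'
#' @param p a `kinetic_params`.
#' @return list with `alpha1`, `alpha2` (min^-1, alpha1 <= alpha2),
#'   amplitudes `A1`, `A2` such that h(t) = A1 e^(-alpha1 t) + A2 e^(-alpha2 t)
#'   (distinct case), and `confluent` flag; in the confluent case `A1`, `A2`
#'   are the coefficients of e^(-alpha t) and t e^(-alpha t).
#' @examples
#' impulse_response(kinetic_params(0.58, 0.35, 0.017, 0.05, 0.53))
#' @export
impulse_response <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  s <- p$k2 + p$k3 + p$k4
  if (s <= 0)
    stop("degenerate model: k2 + k3 + k4 must be positive")
  disc <- s^2 - 4 * p$k2 * p$k4
  disc <- max(disc, 0)                      # clip FP noise at confluence
  root <- sqrt(disc)
  alpha1 <- (s - root) / 2
  alpha2 <- (s + root) / 2
  confluent <- root <= 1e-10 * max(s, 1e-12)
  if (!confluent) {
    A1 <- p$K1 * (p$k3 + p$k4 - alpha1) / (alpha2 - alpha1)
    A2 <- p$K1 * (alpha2 - p$k3 - p$k4) / (alpha2 - alpha1)
  } else {
    alpha1 <- alpha2 <- s / 2
    A1 <- p$K1                              # coefficient of e^(-alpha t)
    A2 <- p$K1 * (p$k3 + p$k4 - alpha1)     # coefficient of t e^(-alpha t)
  }
  list(alpha1 = alpha1, alpha2 = alpha2, A1 = A1, A2 = A2,
       confluent = confluent)
}

# Recursive convolution of e^(-alpha t) with a sampled curve on a uniform
# grid: y[i] = E y[i-1] + dt/2 (ca[i] + E ca[i-1]), trapezoid within each
# step. Run through stats::filter's C-level recursive filter, O(n).
.expconv <- function(alpha, ca, dt) {
  n <- length(ca)
  E <- exp(-alpha * dt)
  b <- c(0, dt / 2 * (ca[-1L] + E * ca[-n]))
  as.numeric(stats::filter(b, E, method = "recursive"))
}

# Convolution of t e^(-alpha t) with a sampled curve, via the companion
# recursion z[i] = E (z[i-1] + dt y[i-1]) + dt^2/2 E ca[i-1], with y the
# plain exponential convolution.
.texpconv <- function(alpha, ca, dt) {
  n <- length(ca)
  E <- exp(-alpha * dt)
  y <- .expconv(alpha, ca, dt)
  b <- c(0, E * (dt * y[-n] + dt^2 / 2 * ca[-n]))
  as.numeric(stats::filter(b, E, method = "recursive"))
}

.cumtrapz <- function(y, dt) c(0, cumsum((y[-1L] + y[-length(y)]) / 2 * dt))

#' Instantaneous model tissue curve on an arbitrary time grid
#'
#' The continuous-time model prediction
#' \deqn{C(t) = (1-v_B)\,[h \otimes C_a](t) +
#'   v_B\left[C_{wb}(t) + K_b \int_0^t C_{wb}(s)\,ds\right]}
#' evaluated by exponential-convolution recursions on a fine uniform grid
#' and interpolated to `times`. Mostly a diagnostic / oracle-facing helper;
#' [model_tac()] returns frame averages.
#'
#' @param p a `kinetic_params`.
#' @param aif an `input_function`.
#' @param times output times in minutes.
#' @param dt internal uniform grid step in minutes.
#' @return numeric vector of model concentrations at `times`.
#' @export
model_curve <- function(p, aif, times, dt = 1 / 240) {
  fine <- .model_fine(p, aif, t_end = max(times), dt = dt)
  stats::approx(fine$t, fine$c, xout = times, rule = 2)$y
}

# Shared fine-grid evaluation; returns the grid, instantaneous curve and its
# cumulative integral.
.model_fine <- function(p, aif, t_end, dt) {
  nstep <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  tg <- seq_len(nstep + 1L) * dt - dt
  ca <- aif_value(aif, tg, "parent")
  cwb <- aif_value(aif, tg, "blood")
  s <- p$k2 + p$k3 + p$k4
  if (s <= 0) {
    conv <- p$K1 * .cumtrapz(ca, dt)        # pure-integrator limit
  } else {
    ir <- impulse_response(p)
    conv <- if (!ir$confluent) {
      ir$A1 * .expconv(ir$alpha1, ca, dt) + ir$A2 * .expconv(ir$alpha2, ca, dt)
    } else {
      ir$A1 * .expconv(ir$alpha1, ca, dt) + ir$A2 * .texpconv(ir$alpha1, ca, dt)
    }
  }
  ct <- (1 - p$vB) * conv + p$vB * (cwb + p$Kb * .cumtrapz(cwb, dt))
  list(t = tg, c = ct, cum = .cumtrapz(ct, dt))
}

#' Predict a frame-averaged time-activity curve
#'
#' Forward model for the two-tissue + vascular-trapping system: the
#' instantaneous curve is computed on a fine uniform grid (default step
#' 1/240 min = 0.25 s, so 5-s frames contain 20 steps and every frame
#' boundary of the default schedule falls on a grid node) and averaged over
#' each frame's duration — early frames are short and the input peak sharp,
#' so mid-point evaluation would bias them.
#'
#' @param p a `kinetic_params`.
#' @param aif an `input_function`.
#' @param schedule a `frame_schedule`.
#' @param dt convolution grid step in minutes.
#' @param subject_id,region labels for the returned curve.
#' @return a noiseless `tac` (tagged metabolite-corrected: the model predicts
#'   intact-tracer concentration).
#' @export
model_tac <- function(p, aif, schedule, dt = 1 / 240,
                      subject_id = "model", region = "whole brain") {
  stopifnot(inherits(schedule, "frame_schedule"))
  t_end <- max(schedule$end_min)
  if (t_end > 10 * max(aif$knot_min))
    warning("schedule extends beyond 10x the last AIF knot; ",
            "model output is dominated by tail extrapolation")
  fine <- .model_fine(p, aif, t_end, dt)
  cum_at <- stats::approx(fine$t, fine$cum, xout = c(schedule$start_min,
                                                     schedule$end_min))$y
  nf <- length(schedule$start_min)
  means <- (cum_at[nf + seq_len(nf)] - cum_at[seq_len(nf)]) /
    (schedule$end_min - schedule$start_min)
  tac(schedule, means, region = region, subject_id = subject_id,
      noisy = FALSE, corrected = TRUE)
}

#' Macroparameters of the kinetic model
#'
#' Total distribution volume \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)} and
#' non-displaceable binding potential \eqn{BP_{ND} = k_3/k_4}. The
#' irreversible vascular trapping term Kb has no equilibrium volume and is
#' excluded from VT by definition.
#'
#' @param p a `kinetic_params`.
#' @return list with `VT` (mL.cm^-3) and `BPND` (unitless).
#' @examples
#' macroparameters(kinetic_params(0.58, 0.35, 0.017, 0.05, 0.53))$VT
#' @export
macroparameters <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$k2 <= 0 || p$k4 <= 0)
    stop("macroparameters undefined: k2 and k4 must be positive")
  bp <- p$k3 / p$k4
  list(VT = (p$K1 / p$k2) * (1 + bp), BPND = bp)
}
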