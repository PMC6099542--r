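# Shared fixtures, built once per test run.

pf_pts <- default_pf_points()
pf_plasma <- pf_calibrate(pf_pts$plasma$time_min, pf_pts$plasma$fraction,
                          "plasma")
pf_brain <- pf_calibrate(pf_pts$brain$time_min, pf_pts$brain$fraction,
                         "brain")

default_sch <- default_frame_schedule()
default_samples <- generate_aif()
default_aif <- build_aif(default_samples, pf_plasma)

# Table-derived group mean parameter sets (k4 pinned at 0.05/min).
params_control <- kinetic_params(K1 = 0.58, k2 = 0.35, k3 = 0.34 * 0.05,
                                 k4 = 0.05, Kb = 0.53, vB = 0.05)
params_lps <- kinetic_params(K1 = 0.86, k2 = 0.36, k3 = 0.61 * 0.05,
                             k4 = 0.05, Kb = 0.68, vB = 0.05)

# A boxy three-knot input function handy for closed-form checks.
toy_aif <- function(tail_lambda = 0.1)
  input_function(c(0, 1, 10), c(0, 4, 2), c(0, 4, 2), tail_lambda)

# Random plausible parameter draw for property tests.
random_params <- function() {
  kinetic_params(K1 = stats::runif(1, 0.1, 1.5),
                 k2 = stats::runif(1, 0.05, 1),
                 k3 = stats::runif(1, 0, 0.3),
                 k4 = stats::runif(1, 0.01, 0.3),
                 Kb = stats::runif(1, 0, 1),
                 vB = stats::runif(1, 0, 0.1))
}

# Independent ODE oracle for the forward model: integrates the two-tissue
# system dC1/dt = K1 Ca - (k2+k3) C1 + k4 C2, dC2/dt = k3 C1 - k4 C2 plus
# the whole-blood integral with deSolve, then assembles
# C = (1-vB)(C1+C2) + vB (Cwb + Kb * int Cwb).
ode_oracle_curve <- function(p, aif, times) {
  deriv <- function(t, y, parms) {
    ca <- aif_value(aif, t, "parent")
    cwb <- aif_value(aif, t, "blood")
    list(c(p$K1 * ca - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2],
           cwb))
  }
  sol <- deSolve::lsoda(c(0, 0, 0), times = c(0, times), func = deriv,
                        rtol = 1e-10, atol = 1e-12)
  cwb <- aif_value(aif, times, "blood")
  idx <- seq_along(times) + 1L
  (1 - p$vB) * (sol[idx, 2] + sol[idx, 3]) +
    p$vB * (cwb + p$Kb * sol[idx, 4])
}
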