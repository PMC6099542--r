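#' Default parent-fraction calibration points
#'
#' The sparse parent-fraction measurements the study design provides:
#' plasma fractions 0.85, 0.60 and 0.35 at 15, 30 and 120 min; brain
#' fractions 0.96 and 0.77 at 15 and 120 min.
#'
#' @return list with data frames `plasma` and `brain` (`time_min`,
#'   `fraction`).
#' @export
default_pf_points <- function() {
  list(
    plasma = data.frame(time_min = c(15, 30, 120),
                        fraction = c(0.85, 0.60, 0.35)),
    brain = data.frame(time_min = c(15, 120), fraction = c(0.96, 0.77))
  )
}

#' Default synthetic arterial input parameters
#'
#' Tri-exponential total-plasma template
#' \deqn{C_{tot}(t) = S\,[w_f e^{-\lambda_f t} + w_s e^{-\lambda_s t}
#'   - (w_f + w_s) e^{-\lambda_r t}]}
#' which is zero at t = 0, rises at rate lambda_r to a peak near 0.5 min,
#' then decays bi-exponentially. The scale S (in %ID/g-equivalent
#' concentration units) is chosen so that the noiseless control whole-brain
#' TAC peaks in the low single digits of %ID/g, matching the tracer's low
#' brain extraction (2-4 %ID/g).
#'
#' @return named list of AIF shape parameters.
#' @export
default_aif_params <- function() {
  list(scale = 6, w_fast = 1, w_slow = 0.25,
       lambda_rise = 6, lambda_fast = 1, lambda_slow = 0.08)
}

.aif_total <- function(aif_params, t) {
  with(aif_params,
       scale * (w_fast * exp(-lambda_fast * t) +
                  w_slow * exp(-lambda_slow * t) -
                  (w_fast + w_slow) * exp(-lambda_rise * t)))
}

#' Generator configuration for a synthetic two-group cohort
#'
#' Group parameter distributions default to the study's whole-brain control
#' and LPS estimates: per-subject K1, k2, k3/k4 and Kb are drawn from
#' zero-truncated normals with those means and SDs; k4 is fixed (the study
#' reports only the k3/k4 ratio, so one positive k4 is pinned for
#' reproducibility) and k3 = ratio x k4.
#'
#' @param n_control,n_lps group sizes (scanned cohort: 8 and 7).
#' @param group_params list with `control` and `lps`, each a list of
#'   `mean` and `sd` vectors over (K1, k2, ratio, Kb).
#' @param k4_fixed fixed k4 in min^-1.
#' @param vB fixed blood volume fraction.
#' @param aif_params see [default_aif_params()].
#' @param sample_times_min plasma sampling grid (terminal samples at 5-120
#'   min plus early knots resolving the input peak).
#' @param noise_scale frame-noise scale; the default gives late 900-s
#'   frames a coefficient of variation near 5%.
#' @param base_seed integer seed; every subject's draws are deterministic
#'   given (base_seed, subject index).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    n_control = 8, n_lps = 7,
    group_params = list(
      control = list(mean = c(K1 = 0.58, k2 = 0.35, ratio = 0.34, Kb = 0.53),
                     sd = c(K1 = 0.15, k2 = 0.06, ratio = 0.13, Kb = 0.05)),
      lps = list(mean = c(K1 = 0.86, k2 = 0.36, ratio = 0.61, Kb = 0.68),
                 sd = c(K1 = 0.18, k2 = 0.13, ratio = 0.58, Kb = 0.23))),
    k4_fixed = 0.05, vB = 0.05,
    aif_params = default_aif_params(),
    sample_times_min = c(0.25, 0.5, 1, 2, 5, 15, 30, 45, 60, 75, 90, 120),
    noise_scale = 0.16, base_seed = 1L) {
  stopifnot(n_control > 0, n_lps > 0, k4_fixed > 0, noise_scale >= 0)
  for (g in group_params)
    stopifnot(all(g$mean > 0), all(g$sd >= 0))
  structure(list(n_control = n_control, n_lps = n_lps,
                 group_params = group_params, k4_fixed = k4_fixed, vB = vB,
                 aif_params = aif_params,
                 sample_times_min = sample_times_min,
                 noise_scale = noise_scale,
                 base_seed = as.integer(base_seed)),
            class = "generator_config")
}

.subject_seed <- function(base_seed, index, stream) {
  as.integer((as.numeric(base_seed) * 100003 + index * 1009 + stream) %%
               2147483647)
}

#' Generate synthetic plasma samples
#'
#' Evaluates the tri-exponential total-plasma template at the sampling
#' times and attaches observed parent fractions from the plasma
#' parent-fraction model (complement conservation: parent + metabolite
#' fractions sum to 1 by construction).
#'
#' @param aif_params AIF shape parameters, see [default_aif_params()].
#' @param times_min sampling times in minutes.
#' @param plasma_pf plasma `pf_model`; default calibrated to
#'   [default_pf_points()].
#' @return a `plasma_series`.
#' @export
generate_aif <- function(aif_params = default_aif_params(),
                         times_min = c(0.25, 0.5, 1, 2, 5, 15, 30, 45, 60,
                                       75, 90, 120),
                         plasma_pf = NULL) {
  if (any(unlist(aif_params[c("scale", "w_fast", "w_slow")]) <= 0))
    stop("AIF amplitudes must be positive")
  if (is.null(plasma_pf)) {
    pts <- default_pf_points()$plasma
    plasma_pf <- pf_calibrate(pts$time_min, pts$fraction, "plasma")
  }
  plasma_series(times_min, .aif_total(aif_params, times_min),
                pf_evaluate(plasma_pf, times_min))
}

#' Draw one subject's true kinetic parameters
#'
#' Zero-truncated normal draws of (K1, k2, k3/k4 ratio, Kb) at the group's
#' mean/SD; k3 = ratio x k4_fixed, k4 = k4_fixed. Deterministic given
#' (base_seed, subject index).
#'
#' @param group `"control"` or `"lps"`.
#' @param config a `generator_config`.
#' @param subject_index integer index within the cohort.
#' @return a `kinetic_params`.
#' @export
draw_subject_params <- function(group = c("control", "lps"), config,
                                subject_index = 1L) {
  group <- match.arg(group)
  gp <- config$group_params[[group]]
  set.seed(.subject_seed(config$base_seed, subject_index,
                         if (group == "control") 1L else 2L))
  draw_pos <- function(mean, sd) {
    if (sd == 0) return(mean)
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x > 0) return(x)
    }
  }
  v <- mapply(draw_pos, gp$mean, gp$sd)
  kinetic_params(K1 = v[["K1"]], k2 = v[["k2"]],
                 k3 = v[["ratio"]] * config$k4_fixed, k4 = config$k4_fixed,
                 Kb = v[["Kb"]], vB = config$vB)
}

#' Generate a complete synthetic cohort
#'
#' For each subject: true parameters are drawn, the noiseless intact-tracer
#' TAC is computed with [model_tac()] from the input function built from
#' the shared (population) plasma samples, brain metabolism is applied in
#' reverse (measured = intact / PF_brain at frame mid-time, so the measured
#' curve contains metabolite signal and the pipeline's correction step is
#' exercised non-trivially), and Gaussian frame noise with
#' sd_i = noise_scale x sqrt(C_i / dur_i_min) is added (count-statistics
#' approximation: longer frames are less noisy).
#'
#' @param config a `generator_config`.
#' @return list of class `synthetic_cohort`: `subjects` (each with
#'   `subject_id`, `group`, `true_params`, `plasma`, `tac_noisy`,
#'   `tac_measured_noiseless`, `tac_truth` (intact-tracer noiseless twin),
#'   `seed`), plus the shared `plasma`, `aif`, `plasma_pf`, `brain_pf`,
#'   `schedule` and the `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  pts <- default_pf_points()
  plasma_pf <- pf_calibrate(pts$plasma$time_min, pts$plasma$fraction, "plasma")
  brain_pf <- pf_calibrate(pts$brain$time_min, pts$brain$fraction, "brain")
  schedule <- default_frame_schedule()
  samples <- generate_aif(config$aif_params, config$sample_times_min,
                          plasma_pf)
  aif <- build_aif(samples, plasma_pf)
  pf_mid <- pf_evaluate(brain_pf, schedule$mid_min)
  dur_min <- schedule$duration_s / 60

  groups <- c(rep("control", config$n_control), rep("lps", config$n_lps))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    truth <- draw_subject_params(g, config, i)
    sid <- sprintf("%s_%02d", g, i)
    truth_tac <- model_tac(truth, aif, schedule, subject_id = sid)
    measured <- truth_tac$value / pf_mid
    noise_seed <- .subject_seed(config$base_seed, i, 3L)
    set.seed(noise_seed)
    noisy <- measured + stats::rnorm(
      length(measured), 0,
      config$noise_scale * sqrt(pmax(measured, 1e-6) / dur_min))
    subjects[[i]] <- list(
      subject_id = sid, group = g, true_params = truth, plasma = samples,
      tac_truth = truth_tac,
      tac_measured_noiseless = tac(schedule, measured, subject_id = sid,
                                   noisy = FALSE, corrected = FALSE),
      tac_noisy = tac(schedule, noisy, subject_id = sid, noisy = TRUE,
                      corrected = FALSE),
      seed = noise_seed)
  }
  structure(list(subjects = subjects, plasma = samples, aif = aif,
                 plasma_pf = plasma_pf, brain_pf = brain_pf,
                 schedule = schedule, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d control + %d LPS subjects, seed %d\n",
              x$config$n_control, x$config$n_lps, x$config$base_seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV tables
#'
#' Writes `tac.csv` (noisy measured curves), `plasma.csv` (shared plasma
#' samples) and `truth.csv` (per-subject generating parameters with their
#' VT) into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tac_table(lapply(cohort$subjects, `[[`, "tac_noisy"),
                  file.path(dir, "tac.csv"))
  write_plasma_table(cohort$plasma, file.path(dir, "plasma.csv"))
  truth <- do.call(rbind, lapply(cohort$subjects, function(s) {
    p <- s$true_params
    data.frame(subject_id = s$subject_id, group = s$group,
               K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, Kb = p$Kb,
               vB = p$vB, VT = macroparameters(p)$VT, seed = s$seed)
  }))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
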