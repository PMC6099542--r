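test_that("noiseless group-mean curves are recovered through the full loop", {
  # generate at group means -> divide by brain PF (measured curve) ->
  # correct -> fit from perturbed start; estimates must return to truth
  for (p in list(params_control, params_lps)) {
    truth_tac <- model_tac(p, default_aif, default_sch)
    measured <- tac(default_sch,
                    truth_tac$value / pf_evaluate(pf_brain,
                                                  default_sch$mid_min))
    corrected <- correct_tac_for_metabolites(measured, pf_brain)
    init <- kinetic_params(2 * p$K1, 2 * p$k2, 2 * p$k3, 2 * p$k4, 2 * p$Kb,
                           p$vB)
    fit <- fit_tac(corrected, default_aif, init = init)
    expect_true(fit$converged)
    expect_equal(fit$params$K1, p$K1, tolerance = 0.01)
    expect_equal(fit$params$k2, p$k2, tolerance = 0.01)
    expect_equal(fit$params$Kb, p$Kb, tolerance = 0.02)
    expect_equal(fit$macro$VT, macroparameters(p)$VT, tolerance = 0.01)
  }
})

test_that("noiseless self-fit recovers random parameter draws (property)", {
  set.seed(21)
  for (i in 1:8) {
    p <- kinetic_params(K1 = runif(1, 0.2, 1.2), k2 = runif(1, 0.1, 0.8),
                        k3 = runif(1, 0.005, 0.1), k4 = runif(1, 0.02, 0.2),
                        Kb = runif(1, 0.1, 1), vB = 0.05)
    y <- model_tac(p, default_aif, default_sch)
    init <- kinetic_params(1.5 * p$K1, 1.5 * p$k2, 1.5 * p$k3, 1.5 * p$k4,
                           1.5 * p$Kb, 0.05)
    fit <- fit_tac(y, default_aif, init = init)
    expect_equal(fit$params$K1, p$K1, tolerance = 0.01)
    expect_equal(fit$params$k2, p$k2, tolerance = 0.01)
    expect_equal(fit$params$Kb, p$Kb, tolerance = 0.01)
    expect_equal(fit$macro$VT, macroparameters(p)$VT, tolerance = 0.01)
  }
})

test_that("an all-zero TAC drives the uptake parameters to the boundary", {
  y <- tac(default_sch, rep(0, 25))
  fit <- fit_tac(y, default_aif)
  expect_true(fit$converged)
  expect_equal(fit$params$K1, 0, tolerance = 1e-6)
  expect_equal(fit$params$Kb, 0, tolerance = 1e-6)
  # only the fixed-vB blood signal remains in the residual
  w <- default_sch$duration_s / mean(default_sch$duration_s)
  blood <- model_tac(kinetic_params(0, 0.1, 0, 0, 0, vB = 0.05),
                     default_aif, default_sch)$value
  expect_equal(fit$wrss, sum(w * blood^2), tolerance = 1e-6)
})

test_that("estimates and %SE are invariant to rescaling all weights", {
  set.seed(33)
  p <- params_control
  y0 <- model_tac(p, default_aif, default_sch)$value
  noisy <- tac(default_sch, y0 + rnorm(25, 0, 0.03 * max(y0)), noisy = TRUE)
  w <- default_sch$duration_s
  f1 <- fit_tac(noisy, default_aif, init = p, weights = w)
  f2 <- fit_tac(noisy, default_aif, init = p, weights = 7.3 * w)
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-6)
  expect_equal(f1$percent_se, f2$percent_se, tolerance = 1e-4)
})

test_that("%SE matches the closed-form linear-regression SE when only K1 is free", {
  # with k2..Kb pinned the model is linear in K1: y = K1 * x(t), so the
  # weighted regression-through-origin SE is available in closed form
  set.seed(44)
  p <- params_control
  x <- model_tac(kinetic_params(1, p$k2, p$k3, p$k4, 0, vB = 0),
                 default_aif, default_sch)$value
  vb_term <- model_tac(kinetic_params(0, p$k2, p$k3, p$k4, 0, vB = 0),
                       default_aif, default_sch)$value
  stopifnot(all(vb_term == 0))
  y <- p$K1 * x + rnorm(25, 0, 0.02 * max(x))
  w <- default_sch$duration_s / mean(default_sch$duration_s)
  fit <- fit_tac(tac(default_sch, y, noisy = TRUE), default_aif,
                 init = kinetic_params(0.3, p$k2, p$k3, p$k4, 0, vB = 0),
                 vB = 0,
                 fixed = list(k2 = p$k2, k3 = p$k3, k4 = p$k4, Kb = 0))
  k1_hat <- sum(w * x * y) / sum(w * x^2)
  wrss <- sum(w * (y - k1_hat * x)^2)
  se_closed <- sqrt(wrss / (25 - 1) / sum(w * x^2))
  expect_equal(fit$params$K1, k1_hat, tolerance = 1e-6)
  expect_equal(fit$percent_se[["K1"]], 100 * se_closed / k1_hat,
               tolerance = 0.05)
})

test_that("the exclusion rule drops fits with any %SE above threshold", {
  mk <- function(pse, converged = TRUE) {
    f <- structure(list(params = params_control,
                        percent_se = c(K1 = pse[1], k2 = pse[2], k3 = pse[3],
                                       k4 = pse[4], Kb = pse[5]),
                        wrss = 1, converged = converged),
                   class = "kinetic_fit")
    f
  }
  fits <- list(mk(c(10, 60, 5, 5, 5)),        # k2 over threshold
               mk(c(10, 10, 10, 10, 10)),     # clean
               mk(c(5, 5, 5, 5, 5), converged = FALSE),
               mk(c(10, 10, Inf, 10, 10)))    # singular information
  res <- apply_exclusion(fits, threshold_percent = 50)
  expect_length(res$retained, 1L)
  expect_length(res$excluded, 3L)
  expect_match(res$reasons[1], "k2")
  expect_equal(res$reasons[2], "")
  expect_match(res$reasons[3], "not converged")
  expect_match(res$reasons[4], "k3")
})

test_that("multi-start is used when no init is given and the result converges", {
  y <- model_tac(params_control, default_aif, default_sch)
  fit <- fit_tac(y, default_aif)
  expect_equal(fit$n_starts_used, 3L)
  expect_true(fit$converged)
  expect_equal(fit$params$K1, 0.58, tolerance = 0.01)
})
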