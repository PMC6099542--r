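test_that("synthetic plasma samples have the right shape and parent fractions", {
  s <- generate_aif()
  expect_equal(petkin:::.aif_total(default_aif_params(), 0), 0)
  # peak of the continuous template lies in [0.3, 1] min
  tg <- seq(0, 3, by = 0.001)
  v <- petkin:::.aif_total(default_aif_params(), tg)
  expect_gt(tg[which.max(v)], 0.3)
  expect_lt(tg[which.max(v)], 1)
  # observed parent fraction at 30 min matches the plasma measurement
  expect_equal(s$parent_fraction_obs[s$time_min == 30], 0.60,
               tolerance = 0.02)
  # complement conservation at every sample
  expect_equal(s$parent_fraction_obs + (1 - s$parent_fraction_obs),
               rep(1, length(s$time_min)))
  expect_error(generate_aif(list(scale = -1, w_fast = 1, w_slow = 1,
                                 lambda_rise = 6, lambda_fast = 1,
                                 lambda_slow = 0.08)), "positive")
})

test_that("subject parameter draws are deterministic and unbiased", {
  cfg <- generator_config(base_seed = 5)
  p1 <- draw_subject_params("control", cfg, 3)
  p2 <- draw_subject_params("control", cfg, 3)
  expect_identical(unlist(p1), unlist(p2))
  expect_false(identical(unlist(p1),
                         unlist(draw_subject_params("control", cfg, 4))))
  # zero SDs pin every subject at the group means
  cfg0 <- generator_config(group_params = list(
    control = list(mean = c(K1 = 0.58, k2 = 0.35, ratio = 0.34, Kb = 0.53),
                   sd = c(K1 = 0, k2 = 0, ratio = 0, Kb = 0)),
    lps = list(mean = c(K1 = 0.86, k2 = 0.36, ratio = 0.61, Kb = 0.68),
               sd = c(K1 = 0, k2 = 0, ratio = 0, Kb = 0))))
  pc <- draw_subject_params("control", cfg0, 1)
  expect_equal(pc$K1, 0.58)
  expect_equal(pc$k3, 0.34 * 0.05)
  expect_equal(pc$k4, 0.05)
  # law of large numbers at the control K1 mean (mild truncation bias only)
  draws <- vapply(1:400, function(i)
    draw_subject_params("control", cfg, i)$K1, numeric(1))
  expect_equal(mean(draws), 0.58, tolerance = 0.58 * 0.05)
})

test_that("a generated cohort has the advertised structure", {
  cfg <- generator_config(n_control = 3, n_lps = 2, base_seed = 9)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 5L)
  expect_equal(vapply(coh$subjects, `[[`, "", "group"),
               c(rep("control", 3), rep("lps", 2)))
  for (s in coh$subjects) {
    expect_equal(n_frames(s$tac_noisy$schedule), 25L)
    # noiseless twin is exactly the forward model of the true parameters
    expect_equal(s$tac_truth$value,
                 model_tac(s$true_params, coh$aif, coh$schedule)$value)
    # reverse metabolism: measured = intact / PF_brain(mid)
    expect_equal(s$tac_measured_noiseless$value,
                 s$tac_truth$value /
                   pf_evaluate(coh$brain_pf, coh$schedule$mid_min))
  }
})

test_that("frame noise is unbiased and scales with sqrt(value/duration)", {
  cfg <- generator_config(n_control = 1, n_lps = 1, base_seed = 3)
  coh <- generate_cohort(cfg)
  s <- coh$subjects[[1]]
  frame <- 20                      # a 900-s frame
  truth <- s$tac_measured_noiseless$value[frame]
  sd_th <- cfg$noise_scale * sqrt(truth / (coh$schedule$duration_s[frame] / 60))
  set.seed(123)
  reps <- truth + rnorm(500, 0, sd_th)
  expect_lt(abs(mean(reps) - truth), 3 * sd_th / sqrt(500))
  # the one stored noisy draw lies within plausible range
  expect_lt(abs(s$tac_noisy$value[frame] - truth), 6 * sd_th)
})

test_that("identical base seeds give byte-identical cohort tables", {
  cfg <- generator_config(n_control = 2, n_lps = 2, base_seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("tac.csv", "plasma.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # and a different seed changes the noisy data
  write_cohort(generate_cohort(generator_config(n_control = 2, n_lps = 2,
                                                base_seed = 12)), d2)
  expect_false(identical(readLines(file.path(d1, "tac.csv")),
                         readLines(file.path(d2, "tac.csv"))))
})

test_that("late 900-s frames of a control-mean subject have ~5% noise CV", {
  cfg0 <- generator_config(
    n_control = 1, n_lps = 1,
    group_params = list(
      control = list(mean = c(K1 = 0.58, k2 = 0.35, ratio = 0.34, Kb = 0.53),
                     sd = c(K1 = 0, k2 = 0, ratio = 0, Kb = 0)),
      lps = list(mean = c(K1 = 0.86, k2 = 0.36, ratio = 0.61, Kb = 0.68),
                 sd = c(K1 = 0, k2 = 0, ratio = 0, Kb = 0))))
  coh <- generate_cohort(cfg0)
  s <- coh$subjects[[1]]
  v <- s$tac_measured_noiseless$value[25]
  cv <- cfg0$noise_scale * sqrt(v / 15) / v
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.08)
})
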