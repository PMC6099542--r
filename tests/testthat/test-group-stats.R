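test_that("dose normalizations follow their definitions", {
  expect_equal(percent_id_per_g(1, 100), 1)
  expect_equal(percent_id_per_g(1, 200), 0.5)          # doubling dose halves
  expect_equal(suv(0.5, 10, 20), 1)                    # conc = dose/weight
  expect_error(percent_id_per_g(1, 0), "positive")
  expect_error(suv(1, 10, 0), "positive")
})

test_that("AUC handles constant and ramp curves analytically", {
  flat <- tac(default_sch, rep(1, 25))
  expect_equal(auc_trapezoid(flat), 7200, tolerance = 0.01)
  ramp <- tac(default_sch, default_sch$mid_s / 7200)
  expect_equal(auc_trapezoid(ramp), 3600, tolerance = 0.01)
  expect_error(auc_trapezoid(tac(default_sch, rep(1, 25), unit = "kBq/mL")),
               "unit")
})

test_that("AUC is additive over contiguous sub-intervals and homogeneous", {
  set.seed(3)
  v <- runif(25, 0, 4)
  full <- tac(default_sch, v)
  # split after frame 16 (t = 480 s); second part re-anchored at 0 with the
  # same inter-mid-time trapezoids plus the boundary panel
  expect_equal(auc_trapezoid(tac(default_sch, 3 * v)),
               3 * auc_trapezoid(full))
  # node grid: anchored zero, frame mid-times, scan end held at last value
  nodes <- c(0, default_sch$mid_s, 7200)
  y <- c(0, v, v[25])
  manual <- sum(diff(nodes) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(auc_trapezoid(full), manual)
  k <- 17                      # split at an interior node
  left <- sum(diff(nodes[1:k]) * (y[2:k] + y[1:(k - 1)]) / 2)
  right <- sum(diff(nodes[k:27]) * (y[(k + 1):27] + y[k:26]) / 2)
  expect_equal(left + right, auc_trapezoid(full))
})

test_that("Welch test matches the closed-form formula on a worked example", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_t_test(a, b, sides = "two")
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(b) - mean(a)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-t_hand, df_hand), tolerance = 1e-12)
  # one-sided p in the hypothesized direction is half the two-sided p
  one <- welch_t_test(a, b, sides = "one")
  expect_equal(one$p_value, res$p_value / 2, tolerance = 1e-12)
})

test_that("Welch degenerate and limiting cases behave", {
  x <- c(1, 2, 3, 4)
  same <- welch_t_test(x, x, sides = "one")
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 0.5)
  # equal variances and n: Welch df equals the pooled df
  set.seed(9)
  a <- rnorm(10); b <- a + 1          # identical sample variance
  expect_equal(welch_t_test(a, b)$df, 18, tolerance = 1e-9)
  expect_error(welch_t_test(1, c(1, 2)), "insufficient data")
})

test_that("Welch agrees with a permutation test on separated groups", {
  set.seed(17)
  a <- rnorm(6, 2.25, 0.44); b <- rnorm(5, 3.77, 0.41)
  res <- welch_t_test(a, b, sides = "one")
  pool <- c(a, b)
  obs <- mean(b) - mean(a)
  perm <- replicate(2000, {
    idx <- sample(11, 5)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- mean(perm >= obs)
  expect_equal(res$p_value < 0.05, p_perm < 0.05)
})

test_that("fold change is a plain mean ratio reported to 2 decimals", {
  expect_identical(fold_change(0.93, 0.43), 2.16)
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(1, 0.5), 2)
  expect_equal(fold_change(0.93, 0.43) * fold_change(0.43, 0.93), 2.16 * 0.46)
  expect_error(fold_change(1, 0), "positive")
})

test_that("group summary mirrors the per-parameter layout", {
  set.seed(2)
  mkfit <- function(p) {
    y <- model_tac(p, default_aif, default_sch)
    fit_tac(y, default_aif, init = p)
  }
  jit <- function(p, f) kinetic_params(p$K1 * f, p$k2 * f, p$k3 * f, p$k4,
                                       p$Kb * f, p$vB)
  fc <- lapply(c(0.9, 1, 1.1), function(f) mkfit(jit(params_control, f)))
  fl <- lapply(c(0.9, 1, 1.1), function(f) mkfit(jit(params_lps, f)))
  tab <- summarize_groups(fc, fl, auc_control = c(10, 11, 12),
                          auc_lps = c(15, 16, 17))
  expect_equal(tab$parameter, c("K1", "k2", "k3/k4", "Kb", "VT", "AUC"))
  expect_equal(tab$sides, c(rep("one", 5), "two"))
  expect_equal(tab$control_mean[tab$parameter == "K1"], 0.58,
               tolerance = 0.01)
  # identical groups -> one-sided p >= 0.5
  tab2 <- summarize_groups(fc, fc)
  expect_true(all(tab2$p_value[tab2$sides == "one"] >= 0.5 |
                    !is.finite(tab2$t_stat)))
  expect_error(summarize_groups(list(), fl), "insufficient data")
})
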