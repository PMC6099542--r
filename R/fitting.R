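#' Fit the two-tissue + vascular-trapping model to a time-activity curve
#'
#' Weighted nonlinear least squares over (K1, k2, k3, k4, Kb) with box
#' bounds, Levenberg-Marquardt minimization (minpack.lm), and a
#' deterministic multi-start strategy: three starts with all rates at 0.01,
#' 0.1 and 1 (log-spaced over [0.01, 1]), preceded by `init` when one is
#' given; the lowest weighted residual sum of squares wins, ties broken by
#' lowest K1. vB is held fixed. Default weights are proportional to frame duration
#' (longer frames accumulate more counts, so their values are more precise).
#'
#' Per-parameter standard errors come from the Gauss-Newton approximation
#' \eqn{\widehat{cov} = (J^T W J)^{-1} \, WRSS/(N-p)} with the Jacobian
#' evaluated by central finite differences at the solution; `percent_se` is
#' 100 x se / estimate (infinite where the information matrix is singular or
#' the estimate is zero).
#'
#' @param x a `tac` (metabolite-corrected for brain regions).
#' @param aif an `input_function` covering the same time span.
#' @param init optional `kinetic_params` tried as the first start.
#' @param weights `"duration"` (default) or `"uniform"`, or a numeric vector
#'   of per-frame weights.
#' @param lower,upper bounds applied to each of the five rates (min^-1 /
#'   K1 units); defaults 0 and 10.
#' @param vB fixed blood volume fraction.
#' @param fixed optional named list pinning a subset of `K1,k2,k3,k4,Kb` to
#'   given values (they are removed from the free parameter set).
#' @param dt convolution grid step passed to [model_tac()].
#' @return an object of class `kinetic_fit`: `params`, `se`, `percent_se`,
#'   `wrss`, `converged`, `n_starts_used`, `macro` (NULL when undefined),
#'   and `diagnostics` (residuals, runs-test z and p).
#' @export
fit_tac <- function(x, aif, init = NULL, weights = "duration",
                    lower = 0, upper = 10, vB = 0.05, fixed = NULL,
                    dt = 1 / 240) {
  stopifnot(inherits(x, "tac"), inherits(aif, "input_function"))
  sch <- x$schedule
  y <- x$value
  nf <- length(y)

  w <- if (is.numeric(weights)) {
    if (length(weights) != nf) stop("weights must have one entry per frame")
    weights
  } else {
    switch(match.arg(weights, c("duration", "uniform")),
           duration = sch$duration_s,
           uniform = rep(1, nf))
  }
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0, not all zero")
  w <- w / mean(w)                          # normalization: no effect on
  sw <- sqrt(w)                             # estimates or %SE, keeps wrss O(N)

  par_names <- c("K1", "k2", "k3", "k4", "Kb")
  fixed_vals <- rep(NA_real_, 5L); names(fixed_vals) <- par_names
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% par_names)) stop("unknown fixed parameter")
    fixed_vals[names(fixed)] <- as.numeric(fixed)
  }
  free <- is.na(fixed_vals)
  if (!any(free)) stop("at least one parameter must be free")

  full_theta <- function(theta_free) {
    th <- fixed_vals
    th[free] <- theta_free
    th
  }
  predict_theta <- function(th) {
    p <- kinetic_params(th[["K1"]], th[["k2"]], th[["k3"]], th[["k4"]],
                        th[["Kb"]], vB = vB)
    model_tac(p, aif, sch, dt = dt)$value
  }
  resid_fn <- function(theta_free) sw * (y - predict_theta(full_theta(theta_free)))

  starts <- lapply(c(0.01, 0.1, 1), function(s) rep(s, sum(free)))
  if (!is.null(init)) {
    stopifnot(inherits(init, "kinetic_params"))
    # the user start is tried first; the deterministic log-spaced starts
    # remain as a safeguard against local minima, best WRSS still wins
    starts <- c(list(unlist(init[par_names])[free]), starts)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(st, lower), upper), fn = resid_fn,
        lower = rep(lower, sum(free)), upper = rep(upper, sum(free)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = fit$par, wrss = fit$deviance,
                 converged = fit$info >= 1 && fit$info <= 4)
    if (is.null(best) ||
        cand$wrss < best$wrss - 1e-12 * max(best$wrss, 1) ||
        (abs(cand$wrss - best$wrss) <= 1e-12 * max(best$wrss, 1) &&
         full_theta(cand$par)[["K1"]] < full_theta(best$par)[["K1"]]))
      best <- cand
  }

  if (is.null(best)) {
    th <- fixed_vals; th[free] <- 0
    p <- kinetic_params(th[["K1"]], th[["k2"]], th[["k3"]], th[["k4"]],
                        th[["Kb"]], vB = vB)
    return(.kinetic_fit(p, se = rep(Inf, 5L), wrss = Inf, converged = FALSE,
                        n_starts = length(starts), residuals = rep(NA_real_, nf),
                        par_names = par_names))
  }

  th <- full_theta(best$par)
  p_hat <- kinetic_params(th[["K1"]], th[["k2"]], th[["k3"]], th[["k4"]],
                          th[["Kb"]], vB = vB)
  resid <- y - predict_theta(th)
  wrss <- sum(w * resid^2)

  # central-difference Jacobian of the weighted model wrt free parameters
  J <- matrix(0, nf, sum(free))
  theta_free <- best$par
  for (j in seq_along(theta_free)) {
    h <- max(1e-6, 1e-4 * abs(theta_free[j]))
    up <- theta_free; up[j] <- up[j] + h
    dn <- theta_free; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- sw * (predict_theta(full_theta(up)) -
                      predict_theta(full_theta(dn))) / (up[j] - dn[j])
  }
  se <- rep(NA_real_, 5L); names(se) <- par_names
  se[!free] <- 0
  dof <- nf - sum(free)
  cov_free <- tryCatch(solve(crossprod(J)) * wrss / dof,
                       error = function(e) NULL)
  se[free] <- if (is.null(cov_free)) Inf else {
    d <- diag(cov_free)
    ifelse(d >= 0 & is.finite(d), sqrt(d), Inf)
  }

  .kinetic_fit(p_hat, se = se, wrss = wrss, converged = best$converged,
               n_starts = length(starts), residuals = resid,
               par_names = par_names)
}

.kinetic_fit <- function(p, se, wrss, converged, n_starts, residuals,
                         par_names) {
  est <- unlist(p[par_names])
  percent_se <- ifelse(est > 0, 100 * se / est, ifelse(se == 0, 0, Inf))
  names(se) <- names(percent_se) <- par_names
  macro <- if (p$k2 > 0 && p$k4 > 0) macroparameters(p) else NULL
  rt <- .runs_test(residuals)
  structure(
    list(params = p, se = se, percent_se = percent_se, wrss = wrss,
         converged = converged, n_starts_used = n_starts, macro = macro,
         diagnostics = list(residuals = residuals, runs_z = rt$z,
                            runs_p = rt$p)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf(" wrss = %.4g\n", x$wrss))
  est <- unlist(x$params[c("K1", "k2", "k3", "k4", "Kb")])
  tab <- rbind(estimate = est, percent_se = x$percent_se)
  print(round(tab, 4))
  if (!is.null(x$macro))
    cat(sprintf("VT = %.3f mL.cm-3, BPND = %.3f\n",
                x$macro$VT, x$macro$BPND))
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation);
# low p flags systematic lack of fit.
.runs_test <- function(resid) {
  s <- sign(resid[is.finite(resid) & resid != 0])
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 3)
    return(list(z = NA_real_, p = NA_real_))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Apply the percent-SE exclusion rule to a set of fits
#'
#' A subject's fit is excluded when any of the five estimated rate
#' parameters has a percent standard error above the threshold (default
#' 50%), or when the fit did not converge.
#'
#' @param fits non-empty list of `kinetic_fit` objects.
#' @param threshold_percent exclusion threshold on %SE; default 50.
#' @return list with `retained` and `excluded` (sublists of `fits`) and
#'   `reasons` (character vector, one entry per input fit; "" if retained).
#' @export
apply_exclusion <- function(fits, threshold_percent = 50) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("fits must be non-empty")
  reasons <- vapply(fits, function(f) {
    if (!f$converged) return("not converged")
    bad <- names(f$percent_se)[!is.finite(f$percent_se) |
                                 f$percent_se > threshold_percent]
    if (length(bad)) paste0("%SE > ", threshold_percent, "%: ",
                            paste(bad, collapse = ", ")) else ""
  }, character(1L))
  keep <- reasons == ""
  list(retained = fits[keep], excluded = fits[!keep], reasons = reasons)
}

#' Write per-subject fit results to CSV
#'
#' @param fits list of `kinetic_fit` objects.
#' @param subject_ids,regions label vectors recycled over fits.
#' @param path output CSV path.
#' @param exclusion optional result of [apply_exclusion()] for the same fits.
#' @return the data frame written, invisibly.
#' @export
write_fit_table <- function(fits, subject_ids, regions = "whole brain",
                            path, exclusion = NULL) {
  n <- length(fits)
  subject_ids <- rep_len(subject_ids, n)
  regions <- rep_len(regions, n)
  rows <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]
    p <- f$params
    data.frame(
      subject_id = subject_ids[i], region = regions[i],
      K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, Kb = p$Kb,
      VT = if (is.null(f$macro)) NA_real_ else f$macro$VT,
      BPND = if (is.null(f$macro)) NA_real_ else f$macro$BPND,
      percent_se_K1 = f$percent_se[["K1"]],
      percent_se_k2 = f$percent_se[["k2"]],
      percent_se_k3 = f$percent_se[["k3"]],
      percent_se_k4 = f$percent_se[["k4"]],
      percent_se_Kb = f$percent_se[["Kb"]],
      wrss = f$wrss, converged = f$converged,
      excluded = if (is.null(exclusion)) NA else exclusion$reasons[i] != "",
      exclusion_reason = if (is.null(exclusion)) "" else exclusion$reasons[i])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
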