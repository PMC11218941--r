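# Catch-conditioned estimator: Baranov solver, likelihood fitting,
# projection.

test_that("Baranov solver inverts the catch equation", {
  expect_equal(solve_baranov_f(0, 1000, 1, 1, 0.2)$f, 0)
  # forward Baranov at F = 0.2, single age, N*w = 1000, M = 0.2:
  # 0.5 * (1 - exp(-0.4)) * 1000 = 164.84
  sol <- solve_baranov_f(164.84, 1000, 1, 1, 0.2)
  expect_true(sol$attainable)
  expect_equal(sol$f, 0.2, tolerance = 1e-3)
  # doubling numbers at fixed catch strictly decreases F
  sol2 <- solve_baranov_f(164.84, 2000, 1, 1, 0.2)
  expect_lt(sol2$f, sol$f)
  # unattainable catch is flagged
  expect_false(solve_baranov_f(1e9, 1000, 1, 1, 0.2)$attainable)
  expect_error(solve_baranov_f(-1, 1000, 1, 1, 0.2), ">= 0")
})

test_that("noise-free self-test recovers the true trajectory", {
  sim <- det_sim()
  fit <- det_fit()
  T_ <- length(sim$traj$years)
  expect_true(fit$converged)
  expect_equal(unname(fit$ssb_hat[T_]), sim$traj$ssb[T_], tolerance = 0.05)
  expect_equal(exp(fit$log_r0_hat), det_params()$r0, tolerance = 0.01)
  # whole trajectory, not just the endpoint
  expect_equal(unname(fit$ssb_hat), sim$traj$ssb, tolerance = 0.02)
  # selectivity parameters recovered
  expect_equal(unname(fit$sel_hat$params[["L50"]]), 80, tolerance = 0.02)
})

test_that("index residual mean vanishes at the conditional MLE of q", {
  expect_lt(abs(mean(residuals(det_fit()))), 1e-6)
  expect_lt(abs(mean(residuals(noisy_fit()))), 1e-6)
})

test_that("refits are bit-identical and warm starts never degrade the fit", {
  sim <- det_sim()
  cfg <- matching_config(det_params())
  f1 <- fit_assessment(sim$data, cfg)
  f2 <- fit_assessment(sim$data, cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$nll, f2$nll)
  # warm start from the solution cannot increase the objective
  f3 <- fit_assessment(sim$data, cfg, control = list(start = f1$par))
  expect_lte(f3$nll, f1$nll + 1e-8)
})

test_that("fit refuses degenerate inputs", {
  d <- det_sim()$data
  short <- truncate_data(d, 5)
  expect_error(fit_assessment(short, matching_config(det_params())),
               ">= 10 years")
})

test_that("projection handles the degenerate and the no-catch cases", {
  fit <- det_fit()
  expect_equal(nrow(project(fit, numeric(0), 0)), 0)
  pr <- project(fit, rep(0, 10), 10)
  expect_equal(nrow(pr), 10)
  # no removals: the predicted index cannot fall
  expect_true(all(diff(pr$index_pred) >= -1e-9))
})

test_that("one-step-ahead prediction matches the noise-free truth", {
  sim <- det_sim()
  T_ <- max(sim$data$catch$year)
  cfg <- matching_config(det_params())
  fit <- fit_assessment(truncate_data(sim$data, T_ - 1), cfg)
  pr <- project(fit, sim$data$catch$catch[T_], 1)
  truth <- sim$data$index$index[sim$data$index$year == T_]
  expect_equal(pr$index_pred, truth, tolerance = 0.02)
})

test_that("down-weighting the index loosens the fit to it", {
  d <- noisy_sim()$data
  p <- ref_params()
  tight <- fit_assessment(d, matching_config(p))
  cfg_loose <- matching_config(p)
  cfg_loose$index_cv_assumed <- 0.6
  cfg_loose$label <- "loose"
  loose <- fit_assessment(d, cfg_loose)
  r_tight <- cor(log(d$index$index), log(tight$exploitable_b_hat))
  r_loose <- cor(log(d$index$index), log(loose$exploitable_b_hat))
  expect_lte(r_loose, r_tight + 1e-6)
})

test_that("fit methods expose the standard modelling interface", {
  fit <- det_fit()
  expect_s3_class(fit, "assessment_fit")
  expect_named(coef(fit), c("log_r0", "sel_L50", "sel_L95", "q"))
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  expect_output(print(fit), "Catch-conditioned")
  s <- summary(fit)
  expect_true(s$ssb_ratio > 0 && s$f_ratio > 0)
  expect_output(print(s), "Kobe")
  # parametric bootstrap replicates are valid data sets
  reps <- simulate(fit, nsim = 2, seed = 5)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "assessment_data")
  expect_false(identical(reps[[1]]$index$index, reps[[2]]$index$index))
  # plot methods draw without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
  expect_silent(plot(ref_refpts()))
})
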