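# Validation toolbox: surplus production, process error, runs test,
# retrospective peels / Mohn's rho, hindcast / MASE, Diebold-Mariano.

test_that("surplus production is the biomass balance identity", {
  sp <- surplus_production(c(100, 110), c(5, 0))
  expect_equal(sp$production, 15)
  # constant biomass without catch produces nothing
  sp0 <- surplus_production(rep(50, 6), rep(0, 6))
  expect_equal(sp0$production, rep(0, 5))
  # reconstructing biomass from B_0, C and P is exact
  set.seed(3)
  b <- cumsum(runif(12, 50, 100))
  cc <- runif(12, 0, 10)
  sp2 <- surplus_production(b, cc)
  b_rec <- Reduce(function(bt, i) bt - sp2$catch[i] + sp2$production[i],
                  seq_len(11), accumulate = TRUE, init = b[1])
  expect_equal(b_rec, b, tolerance = 1e-12)
  expect_error(surplus_production(b, cc[1:4]), "misaligned")
  expect_error(surplus_production(b[1], numeric(0)), ">= 2")
})

test_that("process error vanishes when the expectation is the realised production", {
  p <- make_reference_case(sigma_r = 0)
  traj <- simulate_population(p, seed = 1)
  sp <- surplus_production(traj$exploitable_biomass, traj$catch_biomass)
  own <- approxfun(sp$biomass, sp$production, rule = 2)
  eps <- process_error(traj$exploitable_biomass, traj$catch_biomass, own)
  expect_lt(max(abs(eps$epsilon)), 1e-6)
  # fewer than 3 years: defined as empty
  expect_equal(nrow(process_error(c(1, 2), 1, own)), 0)
})

test_that("an injected biomass shock appears as log(1.1) process error", {
  b <- c(100, 100, 100, 100)
  cc <- rep(10, 4)
  pexp <- function(bb) rep(10, length(bb))   # expectation keeps B constant
  b_shocked <- b
  b_shocked[3] <- 110
  eps <- process_error(b_shocked, cc, pexp)
  expect_equal(eps$epsilon[2], log(1.1), tolerance = 1e-12)
})

test_that("process-error dispersion tracks recruitment variability", {
  sd_at <- function(sigma_r) {
    p <- make_reference_case(sigma_r = sigma_r)
    pexp <- production_expectation(p)
    vapply(1:20, function(s) {
      traj <- simulate_population(p, seed = s)
      eps <- process_error(traj$exploitable_biomass, traj$catch_biomass,
                           pexp)
      sd(eps$epsilon, na.rm = TRUE)
    }, numeric(1))
  }
  expect_gt(median(sd_at(0.6)), median(sd_at(0.4)))
})

test_that("runs test reproduces the Wald-Wolfowitz normal approximation", {
  # 12 strictly alternating signs: R = 12, mu = 7, z ~ 3.03
  r <- runs_test(rep(c(1, -1), 6))
  expect_equal(r$n_runs, 12L)
  expect_equal(r$z, 3.028, tolerance = 1e-3)
  expect_equal(r$p_value, 0.00246, tolerance = 1e-2)
  expect_false(r$pass)
  # one-sided residuals are degenerate and fail
  d <- runs_test(c(1, 2, 3, 4))
  expect_false(d$pass)
  expect_equal(d$reason, "degenerate")
})

test_that("runs test holds its nominal size under white noise", {
  set.seed(11)
  rej <- mean(vapply(1:2000, function(i)
    !runs_test(rnorm(30))$pass, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Mohn's rho is the mean relative terminal drift", {
  mk <- function(vals, T_) stats::setNames(vals, seq_len(T_))
  full <- mk(rep(100, 10), 10)
  same <- list(full, mk(rep(100, 9), 9), mk(rep(100, 8), 8))
  expect_equal(mohn_rho(same)$rho, 0)
  expect_true(mohn_rho(same)$pass)
  up10 <- list(full, mk(rep(110, 9), 9), mk(rep(110, 8), 8))
  r10 <- mohn_rho(up10)
  expect_equal(r10$rho, 0.1)
  expect_true(r10$pass)
  up25 <- list(full, mk(rep(125, 9), 9), mk(rep(125, 8), 8))
  r25 <- mohn_rho(up25)
  expect_equal(r25$rho, 0.25)
  expect_false(r25$pass)
  # rescaling every trajectory by a common factor changes nothing
  scaled <- lapply(up10, function(s) s * 3.7)
  expect_equal(mohn_rho(scaled)$rho, 0.1, tolerance = 1e-12)
})

test_that("retrospective peels of consistent data overlap the full fit", {
  sim <- det_sim()
  cfg <- matching_config(det_params())
  peels <- retro_peels(sim$data, cfg, n_peels = 3, fit0 = det_fit())
  expect_length(peels, 4)
  T_ <- max(sim$data$catch$year)
  for (p in 1:3) {
    fit_p <- peels[[p + 1]]
    expect_equal(max(fit_p$years), T_ - p)
    shared <- as.character(fit_p$years)
    expect_equal(unname(fit_p$ssb_hat[shared]),
                 unname(peels[[1]]$ssb_hat[shared]), tolerance = 0.01)
  }
  rho <- mohn_rho(peels, "ssb")
  expect_lt(abs(rho$rho), 0.01)
  expect_error(retro_peels(sim$data, cfg, n_peels = 35), "fewer than 10")
})

test_that("MASE has its defining fixed points and scale freedom", {
  obs <- exp(c(1, 2, 3))
  expect_equal(mase(obs, obs, exp(c(0, 0, 0))), 0)
  naive <- exp(c(0.5, 1.5, 2.5))
  expect_equal(mase(obs, naive, naive), 1)
  # log-error arithmetic: model errors {1,1,1}, naive errors {1,3,2}
  pred <- exp(c(0, 1, 2))
  nv <- exp(c(0, -1, 1))
  expect_equal(mase(obs, pred, nv), 0.5)
  # scale-free on the natural scale
  expect_equal(mase(10 * obs, 10 * pred, 10 * nv), 0.5, tolerance = 1e-12)
  expect_error(mase(obs, obs, obs), "benchmark")
})

test_that("Diebold-Mariano is antisymmetric with exact degenerate cases", {
  e <- c(0.5, -0.2, 0.3, -0.1, 0.4)
  same <- diebold_mariano(e, e)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(2)
  e2 <- rnorm(5)
  a <- diebold_mariano(e, e2)
  b <- diebold_mariano(e2, e)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(diebold_mariano(e[1:2], e2[1:2]), "n >= 3")
})

test_that("Diebold-Mariano holds its size for equal-skill forecasts", {
  set.seed(12)
  rej <- mean(vapply(1:2000, function(i) {
    d <- diebold_mariano(rnorm(50), rnorm(50))
    d$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("hindcast builds one prediction row per peel at horizon one", {
  sim <- det_sim()
  cfg <- matching_config(det_params())
  hc <- hindcast(sim$data, cfg, n_peels = 3, horizon = 1)
  T_ <- max(sim$data$catch$year)
  expect_equal(nrow(hc), 3)
  expect_setequal(hc$year, c(T_, T_ - 1, T_ - 2))
  expect_true(all(hc$horizon == 1))
  # predictions copied from the naive column give MASE exactly 1
  hc2 <- hc
  hc2$predicted <- hc2$naive
  expect_equal(hindcast_mase(hc2)$mase, 1)
})

test_that("hindcast predictions never touch withheld observations", {
  sim <- det_sim()
  cfg <- matching_config(det_params())
  T_ <- max(sim$data$catch$year)
  hc1 <- hindcast(sim$data, cfg, n_peels = 2, horizon = 1)
  # the final year is withheld from every peel at these settings
  poked <- sim$data
  wh <- poked$index$year == T_
  poked$index$index[wh] <- poked$index$index[wh] * 5
  hc2 <- hindcast(poked, cfg, n_peels = 2, horizon = 1)
  expect_equal(hc1$predicted, hc2$predicted, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(hc1$observed, hc2$observed)))
})

test_that("the assembled diagnostic report is internally consistent", {
  sim <- det_sim()
  cfg <- matching_config(det_params())
  dg <- diagnose(sim$data, cfg, n_peels = 2, hind_peels = 3, horizon = 1,
                 fit = det_fit())
  expect_s3_class(dg, "diagnostic_report")
  expect_true(all(dg$mase$mase >= 0))
  expect_true(dg$rho_ssb$pass)     # self-consistent data: no retro drift
  expect_equal(unname(dg$pass["rho"]), dg$rho_ssb$pass)
  expect_equal(unname(dg$pass["mase"]),
               is.finite(dg$mase_h1) && dg$mase_h1 < 1)
  expect_output(print(dg), "Mohn")
})
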