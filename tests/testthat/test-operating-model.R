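# Operating model: parameters, selectivity, population dynamics and
# observation generation.

test_that("reference case carries the central grid levels", {
  p <- make_reference_case()
  expect_equal(p$m_juvenile, 0.3)
  expect_equal(p$m_adult, 0.3)
  expect_equal(p$steepness_h, 0.7)
  expect_equal(p$sigma_r, 0.4)
  expect_equal(p$ess, 50)
  expect_equal(p$index_cv, 0.3)
  expect_equal(p$q_trend, 0)
  expect_equal(p$selectivity$form, "logistic")
  # constructor contract: invariants hold
  expect_silent(validate_om_parameters(p))
})

test_that("parameter invariants are enforced", {
  expect_error(om_parameters(m_adult = -0.1), "m_adult")
  expect_error(om_parameters(steepness_h = 0.1), "steepness")
  expect_error(om_parameters(length_bins = c(10, 5)), "increasing")
  expect_error(om_parameters(ess = 0), "ess")
})

test_that("selectivity forms evaluate to their closed forms", {
  logi <- selectivity_spec("logistic", c(L50 = 80, L95 = 95))
  expect_equal(selectivity_at_length(logi, 80), 0.5)
  expect_equal(selectivity_at_length(logi, 95), 0.95)
  dn <- selectivity_spec("double_normal", c(peak = 90, asc = 10, desc = 15))
  expect_equal(selectivity_at_length(dn, 90), 1.0)
  # descending limb: exp(-(120-90)^2 / (2*15^2)) = exp(-2)
  expect_equal(selectivity_at_length(dn, 120), exp(-2), tolerance = 1e-12)
  # bounded in [0, 1] across lengths for both forms
  L <- seq(0, 200, by = 0.5)
  for (s in list(logi, dn)) {
    v <- selectivity_at_length(s, L)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(selectivity_spec("gauss"), "arg")
  expect_error(selectivity_spec("logistic", c(L50 = 90, L95 = 80)), "L95")
})

test_that("unfished deterministic population sits at equilibrium", {
  p <- make_reference_case(sigma_r = 0)
  traj <- simulate_population(p, f_series = rep(0, p$years), seed = 1)
  expect_equal(max(abs(traj$ssb / traj$ssb0 - 1)), 0, tolerance = 1e-10)
  # SSB never exceeds total biomass
  bio <- build_biology(p)
  total_b <- as.numeric(traj$numbers_at_age %*% bio$waa)
  expect_true(all(traj$ssb <= total_b + 1e-9))
})

test_that("steepness near 1 decouples recruitment from spawning biomass", {
  p <- make_reference_case(sigma_r = 0, steepness_h = 0.999)
  traj <- simulate_population(p, f_series = rep(0.4, p$years), seed = 1)
  expect_equal(max(abs(traj$recruitment / p$r0 - 1)), 0, tolerance = 0.01)
})

test_that("fishing at F_MSY converges to B_MSY", {
  p <- make_reference_case(sigma_r = 0, years = 200)
  rp <- ref_refpts()
  traj <- simulate_population(p, f_series = rep(rp$f_msy, 200), seed = 1)
  expect_equal(traj$ssb[200], rp$b_msy, tolerance = 0.01)
})

test_that("noise-free observations obey the catchability trend exactly", {
  p <- make_reference_case(sigma_r = 0, index_cv = 1e-12, q_trend = 0.01)
  traj <- simulate_population(p, seed = 1)
  obs <- generate_observations(traj, p, seed = 1, exact = TRUE)
  ratio <- obs$index$index / (p$q0 * traj$exploitable_biomass)
  expect_equal(ratio, 1.01^(traj$years - 1), tolerance = 1e-10)
  # without a trend the index is exactly proportional to exploitable biomass
  p0 <- make_reference_case(sigma_r = 0, q_trend = 0)
  obs0 <- generate_observations(traj, p0, seed = 1, exact = TRUE)
  expect_equal(obs0$index$index / traj$exploitable_biomass,
               rep(p0$q0, p0$years), tolerance = 1e-12)
})

test_that("huge effective sample sizes recover the expected compositions", {
  p <- make_reference_case(sigma_r = 0, ess = 1e6)
  traj <- simulate_population(p, seed = 1)
  obs <- generate_observations(traj, p, seed = 7)
  exact <- generate_observations(traj, p, seed = 7, exact = TRUE)
  dev <- abs(obs$lencomp$proportion - exact$lencomp$proportion)
  expect_lt(max(dev), 0.01)
})

test_that("a fixed seed reproduces observations bit for bit", {
  p <- ref_params()
  a <- simulate_assessment_data(p, seed = 42)
  b <- simulate_assessment_data(p, seed = 42)
  expect_identical(a$data, b$data)
  c_ <- simulate_assessment_data(p, seed = 43)
  expect_false(identical(a$data$index$index, c_$data$index$index))
})

test_that("catch-at-age never exceeds total deaths", {
  traj <- noisy_sim()$traj
  bio <- traj$biology
  for (t in seq_along(traj$years)) {
    z <- bio$m + traj$f_apical[t] * bio$sel_a
    deaths <- traj$numbers_at_age[t, ] * (1 - exp(-z))
    expect_true(all(traj$catch_n[t, ] <= deaths + 1e-9))
  }
})

test_that("lognormal observation errors are mean-unbiased", {
  sigma <- sqrt(log(1 + 0.3^2))
  set.seed(99)
  draws <- exp(rnorm(1e5, 0, sigma) - sigma^2 / 2)
  expect_equal(mean(draws), 1, tolerance = 0.01)
})

test_that("higher adult natural mortality lowers unfished spawning biomass", {
  ssb0 <- vapply(c(0.2, 0.3, 0.4), function(m) {
    p <- make_reference_case(m_adult = m, sigma_r = 0)
    bio <- build_biology(p)
    sum(unfished_numbers(bio, p$r0)[-1] * bio$waa[-1] * bio$mat[-1])
  }, numeric(1))
  expect_true(all(diff(ssb0) < 0))
})

test_that("length-composition rows are proper distributions", {
  d <- noisy_sim()$data
  sums <- tapply(d$lencomp$proportion, d$lencomp$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(d$catch$catch >= 0))
  expect_true(all(d$index$index > 0))
})
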