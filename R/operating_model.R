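#' Operating-model parameters
#'
#' Full biological, fishery and observation specification of the simulated
#' "true" population: an age-structured, single-area, single-fleet stock with
#' tuna-like life history. Ages run from 0 to a plus group; natural mortality
#' has separate juvenile (ages 0-4) and adult (ages 5+) stanzas; growth is
#' von Bertalanffy with a Normal length-at-age distribution; recruitment is
#' Beverton-Holt with lognormal, mean-bias-corrected deviates.
#'
#' @param a_plus plus-group age (default 15).
#' @param m_juvenile,m_adult instantaneous natural mortality (per year) for
#'   ages 0-4 and 5+.
#' @param linf,k,t0 von Bertalanffy asymptotic length (cm), growth rate
#'   (per year) and theoretical age at length zero (year).
#' @param w_a,w_b allometric length (cm) to weight (kg) coefficients.
#' @param mat_a50,mat_a95 logistic age at 50% and 95% maturity.
#' @param steepness_h Beverton-Holt steepness, in (0.2, 1].
#' @param r0 unfished recruitment (numbers of age-0 fish).
#' @param sigma_r SD of lognormal recruitment deviates.
#' @param selectivity a [selectivity_spec()].
#' @param q0 index catchability in the first year.
#' @param q_trend proportional yearly increase in catchability (0.01 = 1%).
#' @param index_cv lognormal CV of index observations (> 0).
#' @param ess effective (multinomial) sample size of annual length samples.
#' @param length_bins strictly increasing length-bin edges (cm).
#' @param len_cv CV of the Normal length-at-age distribution.
#' @param years number of simulated years.
#' @return An object of class `om_parameters`.
#' @seealso [make_reference_case()], [simulate_population()]
#' @export
om_parameters <- function(a_plus = 15,
                          m_juvenile = 0.3, m_adult = 0.3,
                          linf = 120, k = 0.2, t0 = -0.5,
                          w_a = 1.34e-5, w_b = 3.05,
                          mat_a50 = 5, mat_a95 = 6.5,
                          steepness_h = 0.7,
                          r0 = 1e7,
                          sigma_r = 0.4,
                          selectivity = selectivity_spec("logistic"),
                          q0 = 1e-5, q_trend = 0,
                          index_cv = 0.3,
                          ess = 50,
                          length_bins = seq(5, 165, by = 5),
                          len_cv = 0.1,
                          years = 40) {
  p <- list(a_plus = a_plus, m_juvenile = m_juvenile, m_adult = m_adult,
            linf = linf, k = k, t0 = t0, w_a = w_a, w_b = w_b,
            mat_a50 = mat_a50, mat_a95 = mat_a95,
            steepness_h = steepness_h, r0 = r0, sigma_r = sigma_r,
            selectivity = selectivity, q0 = q0, q_trend = q_trend,
            index_cv = index_cv, ess = ess, length_bins = length_bins,
            len_cv = len_cv, years = years)
  validate_om_parameters(p)
  structure(p, class = "om_parameters")
}

validate_om_parameters <- function(p) {
  stopifnot(
    "m_juvenile must be > 0" = p$m_juvenile > 0,
    "m_adult must be > 0" = p$m_adult > 0,
    "steepness must be in (0.2, 1]" =
      p$steepness_h > 0.2 && p$steepness_h <= 1,
    "sigma_r must be >= 0" = p$sigma_r >= 0,
    "index_cv must be > 0" = p$index_cv > 0 || p$index_cv == 0,
    "ess must be >= 1" = p$ess >= 1,
    "length_bins must be strictly increasing" =
      all(diff(p$length_bins) > 0),
    "years must be >= 2" = p$years >= 2
  )
  if (!inherits(p$selectivity, "selectivity_spec"))
    stop("selectivity must be a selectivity_spec")
  invisible(p)
}

#' Reference-case operating model
#'
#' The most plausible single configuration at the centre of the uncertainty
#' grid: M = 0.3 for both juvenile and adult stanzas, steepness 0.7,
#' recruitment variability 0.4, length-composition effective sample size 50,
#' index CV 0.3, no catchability trend, logistic selectivity. All other
#' biology is set to the documented tuna-like defaults of
#' [om_parameters()].
#'
#' @param ... overrides passed to [om_parameters()].
#' @return An `om_parameters` object.
#' @export
#' @examples
#' ref <- make_reference_case()
#' ref$steepness_h  # 0.7
make_reference_case <- function(...) {
  om_parameters(...)
}

#' @export
print.om_parameters <- function(x, ...) {
  cat("Operating model (ages 0-", x$a_plus, "+, ", x$years, " years)\n",
      sep = "")
  cat(sprintf("  M juvenile/adult: %.3g/%.3g  h: %.3g  sigmaR: %.3g  R0: %.3g\n",
              x$m_juvenile, x$m_adult, x$steepness_h, x$sigma_r, x$r0))
  cat(sprintf("  index CV: %.3g  q trend: %.3g  ESS: %g\n",
              x$index_cv, x$q_trend, x$ess))
  print(x$selectivity)
  invisible(x)
}

# internal: deterministic age-structured biology derived from parameters.
# ALK rows are exact Normal bin masses with the tails folded into the end
# bins, so each row sums to one.
build_biology <- function(params, selectivity = params$selectivity) {
  ages <- 0:params$a_plus
  A <- length(ages)
  m <- ifelse(ages <= 4, params$m_juvenile, params$m_adult)
  len_mu <- params$linf * (1 - exp(-params$k * (ages + 0.5 - params$t0)))
  len_sd <- pmax(params$len_cv * len_mu, 0.5)
  edges <- params$length_bins
  L <- length(edges) - 1
  mids <- (edges[-1] + edges[-(L + 1)]) / 2
  alk <- matrix(0, A, L)
  for (a in seq_len(A)) {
    cdf <- stats::pnorm(edges, len_mu[a], len_sd[a])
    p <- diff(cdf)
    p[1] <- p[1] + cdf[1]
    p[L] <- p[L] + 1 - cdf[L + 1]
    alk[a, ] <- p
  }
  waa <- as.numeric(alk %*% (params$w_a * mids^params$w_b) / 1000) # tonnes
  mat <- 1 / (1 + exp(-log(19) * (ages - params$mat_a50) /
                        (params$mat_a95 - params$mat_a50)))
  sel_l <- selectivity_at_length(selectivity, mids)
  sel_a <- as.numeric(alk %*% sel_l)
  list(ages = ages, n_ages = A, m = m, waa = waa, mat = mat,
       len_mu = len_mu, len_sd = len_sd, edges = edges, mids = mids,
       n_len = L, alk = alk, sel_l = sel_l, sel_a = sel_a)
}

# internal: unfished equilibrium numbers-at-age for recruitment r0
unfished_numbers <- function(bio, r0) {
  A <- bio$n_ages
  n <- numeric(A)
  n[1] <- r0
  for (a in 2:A) n[a] <- n[a - 1] * exp(-bio$m[a - 1])
  n[A] <- n[A] / (1 - exp(-bio$m[A]))
  n
}

# internal: spawning biomass over ages 1+ (spawning precedes recruitment)
ssb_of <- function(n, bio) sum(n[-1] * bio$waa[-1] * bio$mat[-1])

# internal: Beverton-Holt recruitment
bh_rec <- function(ssb, h, r0, ssb0) {
  4 * h * r0 * ssb / (ssb0 * (1 - h) + (5 * h - 1) * ssb)
}

#' Default fishing-mortality history
#'
#' A 40-year (or `params$years`-year) one-way effort ramp: apical F rising
#' linearly from 10% of F_MSY to F_MSY, the contrast typical of longline
#' CPUE series for tunas.
#'
#' @param params an `om_parameters` object.
#' @param f_terminal terminal F as a multiple of F_MSY (default 1).
#' @return numeric vector of apical F, length `params$years`.
#' @export
default_f_series <- function(params, f_terminal = 1) {
  rp <- compute_refpts(params)
  seq(0.1 * rp$f_msy, f_terminal * rp$f_msy, length.out = params$years)
}

#' Simulate the true population
#'
#' Runs the age-structured operating model forward from the unfished
#' equilibrium under a given apical fishing-mortality series. Within each
#' year: spawning biomass is computed over ages 1+, Beverton-Holt recruitment
#' (times a mean-bias-corrected lognormal deviate
#' \eqn{\exp(d - \sigma_R^2/2)}, \eqn{d \sim N(0, \sigma_R^2)}) enters at
#' age 0, the Baranov catch is taken, and survivors advance one age with
#' plus-group accumulation.
#'
#' @param params an `om_parameters` object.
#' @param f_series apical F per year (length `params$years`); defaults to
#'   [default_f_series()].
#' @param seed integer seed for the recruitment deviates.
#' @return An object of class `pop_trajectory` with year vectors `ssb`,
#'   `exploitable_biomass`, `f_apical`, `recruitment`, `rec_devs`,
#'   `catch_biomass`, the `numbers_at_age` matrix (year x age, start of
#'   year) and the catch-at-age matrix `catch_n`.
#' @export
simulate_population <- function(params, f_series = NULL, seed = 1) {
  if (is.null(f_series)) f_series <- default_f_series(params)
  if (length(f_series) != params$years)
    stop("f_series must cover params$years years")
  if (any(f_series < 0)) stop("F must be >= 0")
  bio <- build_biology(params)
  A <- bio$n_ages
  T_ <- params$years
  set.seed(seed)
  devs <- if (params$sigma_r > 0) stats::rnorm(T_, 0, params$sigma_r)
          else numeric(T_)

  n <- unfished_numbers(bio, params$r0)
  ssb0 <- ssb_of(n, bio)
  N <- matrix(0, T_ + 1, A)
  ssb <- eb <- rec <- cb <- numeric(T_)
  CN <- matrix(0, T_, A)

  for (t in seq_len(T_)) {
    ssb[t] <- ssb_of(n, bio)
    r <- bh_rec(ssb[t], params$steepness_h, params$r0, ssb0)
    n[1] <- r * exp(devs[t] - params$sigma_r^2 / 2)
    rec[t] <- n[1]
    eb[t] <- sum(n * bio$waa * bio$sel_a)
    N[t, ] <- n
    f <- f_series[t]
    z <- bio$m + f * bio$sel_a
    CN[t, ] <- n * (f * bio$sel_a / z) * (1 - exp(-z))
    cb[t] <- sum(CN[t, ] * bio$waa)
    n_new <- numeric(A)
    n_new[2:A] <- n[1:(A - 1)] * exp(-z[1:(A - 1)])
    n_new[A] <- n_new[A] + n[A] * exp(-z[A])
    n <- n_new
  }
  N[T_ + 1, ] <- n

  structure(list(
    years = seq_len(T_), numbers_at_age = N[seq_len(T_), , drop = FALSE],
    terminal_n = n, ssb = ssb, exploitable_biomass = eb,
    f_apical = as.numeric(f_series), recruitment = rec, rec_devs = devs,
    catch_biomass = cb, catch_n = CN, ssb0 = ssb0, params = params,
    biology = bio, seed = seed
  ), class = "pop_trajectory")
}

#' @export
print.pop_trajectory <- function(x, ...) {
  T_ <- length(x$years)
  cat(sprintf(
    "Population trajectory: %d years, SSB0 = %.1f t, terminal SSB = %.1f t (%.0f%% of SSB0)\n",
    T_, x$ssb0, x$ssb[T_], 100 * x$ssb[T_] / x$ssb0))
  invisible(x)
}

#' Generate assessment observations
#'
#' Converts a true trajectory into the data an assessment sees: exact annual
#' catch biomass (Baranov), a relative-abundance index
#' \eqn{I_t = q_0 (1+\lambda)^{t-1} B_t e^{\eta_t - \sigma^2/2}} with
#' \eqn{\eta \sim N(0, \sigma^2)}, \eqn{\sigma = \sqrt{\log(1+cv^2)}}, on
#' exploitable biomass \eqn{B_t}, and annual length compositions drawn
#' Multinomial(ess) from the expected catch-at-length proportions.
#'
#' @param traj a `pop_trajectory` from [simulate_population()].
#' @param params the `om_parameters` used to build `traj`.
#' @param seed integer seed for observation noise.
#' @param exact if `TRUE`, return noise-free observations: the index without
#'   lognormal error and the expected (not sampled) length proportions.
#' @return An `assessment_data` object: data frames `catch` (year, catch),
#'   `index` (year, index, cv) and `lencomp` (year, bin_lower, proportion, n).
#' @export
generate_observations <- function(traj, params, seed = 1, exact = FALSE) {
  bio <- traj$biology
  T_ <- length(traj$years)
  set.seed(seed)
  sigma <- sqrt(log(1 + params$index_cv^2))
  trend <- (1 + params$q_trend)^(traj$years - traj$years[1])
  noise <- if (!exact && sigma > 0)
    exp(stats::rnorm(T_, 0, sigma) - sigma^2 / 2) else 1
  index <- params$q0 * trend * traj$exploitable_biomass * noise

  # expected catch-at-length, weighting within-age length masses by
  # length-based selectivity (renormalised within age)
  lc <- matrix(0, T_, bio$n_len)
  alkc <- bio$alk * rep(bio$sel_l, each = bio$n_ages)
  rs <- rowSums(alkc)
  alkc[rs > 1e-12, ] <- alkc[rs > 1e-12, ] / rs[rs > 1e-12]
  expected <- traj$catch_n %*% alkc
  zero <- rowSums(expected) <= 0
  if (any(zero)) {
    # no catch that year: fall back to the selected population composition
    popc <- traj$numbers_at_age %*% alkc
    expected[zero, ] <- popc[zero, , drop = FALSE]
  }
  expected <- expected / rowSums(expected)
  if (exact) {
    lc <- expected
    n_samp <- rep(params$ess, T_)
  } else {
    for (t in seq_len(T_))
      lc[t, ] <- as.numeric(stats::rmultinom(1, params$ess, expected[t, ])) /
        params$ess
    n_samp <- rep(params$ess, T_)
  }

  assessment_data(
    catch = data.frame(year = traj$years, catch = traj$catch_biomass),
    index = data.frame(year = traj$years, index = index,
                       cv = params$index_cv),
    lencomp = data.frame(
      year = rep(traj$years, each = bio$n_len),
      bin_lower = rep(bio$edges[-length(bio$edges)], T_),
      proportion = as.numeric(t(lc)),
      n = rep(n_samp, each = bio$n_len))
  )
}

#' Assessment data set
#'
#' Container for the three observation streams consumed by the estimator.
#'
#' @param catch data frame with columns `year`, `catch` (biomass, t).
#' @param index data frame with columns `year`, `index`, `cv`.
#' @param lencomp data frame with columns `year`, `bin_lower`, `proportion`,
#'   `n`; proportions must sum to 1 within each year.
#' @return An object of class `assessment_data`.
#' @export
assessment_data <- function(catch, index, lencomp) {
  stopifnot(
    all(c("year", "catch") %in% names(catch)),
    all(c("year", "index", "cv") %in% names(index)),
    all(c("year", "bin_lower", "proportion", "n") %in% names(lencomp))
  )
  if (any(catch$catch < 0)) stop("catch must be >= 0")
  if (any(index$index <= 0)) stop("index must be > 0 where present")
  sums <- tapply(lencomp$proportion, lencomp$year, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("length-composition proportions must sum to 1 within year")
  structure(list(catch = catch, index = index, lencomp = lencomp),
            class = "assessment_data")
}

#' @export
print.assessment_data <- function(x, ...) {
  cat(sprintf(
    "Assessment data: %d catch years (%d-%d), %d index obs, %d length-comp years\n",
    nrow(x$catch), min(x$catch$year), max(x$catch$year), nrow(x$index),
    length(unique(x$lencomp$year))))
  invisible(x)
}

#' Simulate a complete assessment data set
#'
#' Convenience wrapper chaining [simulate_population()] and
#' [generate_observations()] with per-purpose seed substreams derived from
#' one global seed.
#'
#' @param params an `om_parameters` object.
#' @param seed global integer seed.
#' @param f_series optional apical F series.
#' @param exact passed to [generate_observations()].
#' @return list with elements `traj` and `data`.
#' @export
simulate_assessment_data <- function(params, seed = 1, f_series = NULL,
                                     exact = FALSE) {
  traj <- simulate_population(params, f_series,
                              seed = substream_seed(seed, "population"))
  data <- generate_observations(traj, params,
                                seed = substream_seed(seed, "observations"),
                                exact = exact)
  list(traj = traj, data = data)
}

# internal: truncate all observation streams at last_year
truncate_data <- function(data, last_year) {
  assessment_data(
    catch = data$catch[data$catch$year <= last_year, , drop = FALSE],
    index = data$index[data$index$year <= last_year, , drop = FALSE],
    lencomp = data$lencomp[data$lencomp$year <= last_year, , drop = FALSE]
  )
}
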