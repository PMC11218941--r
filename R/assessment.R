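#' Scenario configuration
#'
#' One cell of the factorial uncertainty grid: the fixed-parameter and
#' data-weighting choices under which the estimator is run. Natural
#' mortality may differ between the juvenile (ages 0-4) and adult (5+)
#' stanzas; the assumed index CV and effective sample size are the data
#' weighting levers; the assumed catchability trend and selectivity form are
#' structural choices.
#'
#' @param m_juvenile,m_adult assumed natural mortality per year.
#' @param steepness_h assumed Beverton-Holt steepness.
#' @param sigma_r assumed SD of recruitment deviates (penalty scale); 0
#'   fixes all deviates at zero.
#' @param ess_assumed effective sample size given to length data in the
#'   multinomial likelihood.
#' @param index_cv_assumed lognormal CV given to the index likelihood.
#' @param q_trend_assumed assumed proportional yearly catchability increase.
#' @param selectivity_form `"logistic"` or `"double_normal"`.
#' @param label scenario key; autogenerated if missing.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(m_juvenile = 0.3, m_adult = 0.3,
                            steepness_h = 0.7, sigma_r = 0.4,
                            ess_assumed = 50, index_cv_assumed = 0.3,
                            q_trend_assumed = 0,
                            selectivity_form = c("logistic", "double_normal"),
                            label = NULL) {
  selectivity_form <- match.arg(selectivity_form)
  stopifnot(m_juvenile > 0, m_adult > 0,
            steepness_h > 0.2, steepness_h <= 1,
            sigma_r >= 0, ess_assumed >= 1, index_cv_assumed > 0)
  if (is.null(label)) {
    mlab <- if (m_juvenile == m_adult) format(m_adult)
            else paste0(format(m_juvenile), "/", format(m_adult))
    label <- paste0("M", mlab, "_h", format(steepness_h),
                    "_sR", format(sigma_r), "_E", format(ess_assumed),
                    "_CV", format(index_cv_assumed),
                    "_q", format(q_trend_assumed),
                    "_sel", if (selectivity_form == "logistic") "Log"
                            else "DoNorm")
  }
  structure(list(m_juvenile = m_juvenile, m_adult = m_adult,
                 steepness_h = steepness_h, sigma_r = sigma_r,
                 ess_assumed = ess_assumed,
                 index_cv_assumed = index_cv_assumed,
                 q_trend_assumed = q_trend_assumed,
                 selectivity_form = selectivity_form, label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  invisible(x)
}

#' Matching scenario configuration for an operating model
#'
#' The configuration whose assumptions equal the operating model's true
#' values: the self-test (correctly specified estimator) case.
#'
#' @param params an `om_parameters` object.
#' @return a `scenario_config`.
#' @export
matching_config <- function(params) {
  scenario_config(
    m_juvenile = params$m_juvenile, m_adult = params$m_adult,
    steepness_h = params$steepness_h, sigma_r = params$sigma_r,
    ess_assumed = params$ess, index_cv_assumed = max(params$index_cv, 0.05),
    q_trend_assumed = params$q_trend,
    selectivity_form = params$selectivity$form)
}

# internal: om_parameters with a scenario's factors substituted
scenario_params <- function(config, base = make_reference_case()) {
  sel <- if (config$selectivity_form == base$selectivity$form)
    base$selectivity else selectivity_spec(config$selectivity_form)
  om_parameters(
    a_plus = base$a_plus,
    m_juvenile = config$m_juvenile, m_adult = config$m_adult,
    linf = base$linf, k = base$k, t0 = base$t0,
    w_a = base$w_a, w_b = base$w_b,
    mat_a50 = base$mat_a50, mat_a95 = base$mat_a95,
    steepness_h = config$steepness_h, r0 = base$r0,
    sigma_r = config$sigma_r, selectivity = sel,
    q0 = base$q0, q_trend = config$q_trend_assumed,
    index_cv = config$index_cv_assumed, ess = config$ess_assumed,
    length_bins = base$length_bins, len_cv = base$len_cv,
    years = base$years)
}

#' Solve the Baranov catch equation for F
#'
#' Finds the apical fishing mortality whose Baranov-predicted catch biomass
#' \eqn{\sum_a w_a N_a \frac{F s_a}{F s_a + M_a}(1 - e^{-F s_a - M_a})}
#' equals an observed catch, by fixed-count bisection on \[0, f_max\]
#' (accurate to better than 1e-8 relative in catch).
#'
#' @param catch_biomass observed catch (t), `>= 0`.
#' @param numbers_at_age,weights_at_age,sel_at_age,m_at_age age vectors of
#'   start-of-year numbers, weights (t), selectivity and natural mortality.
#' @param f_max upper bracket for F (default 5).
#' @return list with `f` (apical F) and `attainable` (`FALSE` when the
#'   catch exceeds the predicted catch at `f_max`, in which case `f = f_max`).
#' @export
#' @examples
#' # single age, N*w = 1000, M = 0.2: catch at F = 0.2 is 164.84 t
#' solve_baranov_f(164.84, 1000, 1, 1, 0.2)$f
solve_baranov_f <- function(catch_biomass, numbers_at_age, weights_at_age,
                            sel_at_age, m_at_age, f_max = 5) {
  if (catch_biomass < 0) stop("catch must be >= 0")
  pred <- function(f) {
    fa <- f * sel_at_age
    z <- fa + m_at_age
    sum(weights_at_age * numbers_at_age * (fa / z) * (1 - exp(-z)))
  }
  if (catch_biomass == 0) return(list(f = 0, attainable = TRUE))
  if (pred(f_max) < catch_biomass)
    return(list(f = f_max, attainable = FALSE))
  lo <- 0; hi <- f_max
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pred(mid) < catch_biomass) lo <- mid else hi <- mid
  }
  list(f = (lo + hi) / 2, attainable = TRUE)
}

# internal: assemble the data list consumed by the C++ kernel
prep_asm_data <- function(data, config, base = make_reference_case(),
                          f_max = 5) {
  params <- scenario_params(config, base)
  sel0 <- if (config$selectivity_form == "logistic")
    selectivity_spec("logistic") else selectivity_spec("double_normal")
  bio <- build_biology(params, selectivity = sel0)
  years <- data$catch$year
  if (any(diff(years) != 1)) stop("catch years must be contiguous")
  T_ <- length(years)
  ipos <- match(data$index$year, years) - 1L
  if (anyNA(ipos)) stop("index years outside catch years")
  sigma <- sqrt(log(1 + config$index_cv_assumed^2))

  lc_years <- sort(unique(data$lencomp$year))
  lpos <- match(lc_years, years) - 1L
  if (anyNA(lpos)) stop("length-comp years outside catch years")
  L <- bio$n_len
  lobs <- matrix(0, length(lc_years), L)
  binmatch <- match(data$lencomp$bin_lower, bio$edges[-length(bio$edges)])
  if (anyNA(binmatch)) stop("length-comp bins do not match configured bins")
  for (i in seq_along(lc_years)) {
    sub <- data$lencomp[data$lencomp$year == lc_years[i], ]
    row <- numeric(L)
    row[match(sub$bin_lower, bio$edges[-length(bio$edges)])] <- sub$proportion
    lobs[i, ] <- row
  }

  dev_pos <- if (config$sigma_r > 0) lpos else integer(0)

  list(dat = list(
    n_ages = bio$n_ages, n_len = L, n_years = T_,
    m = bio$m, waa = bio$waa, mat = bio$mat, alk = bio$alk,
    mids = bio$mids, h = config$steepness_h, sigma_r = config$sigma_r,
    catch_obs = data$catch$catch, idx_pos = as.integer(ipos),
    idx_obs = data$index$index, idx_sigma = rep(sigma, length(ipos)),
    lc_pos = as.integer(lpos), lc_obs = lobs, ess = config$ess_assumed,
    q_trend = config$q_trend_assumed, dev_pos = as.integer(dev_pos),
    sel_form = if (config$selectivity_form == "logistic") 0L else 1L,
    n_sel = if (config$selectivity_form == "logistic") 2L else 3L,
    f_max = f_max),
    bio = bio, params = params, years = years, sel0 = sel0,
    lc_years = lc_years)
}

# internal: deterministic starting value for log R0 from a crude
# equilibrium-yield heuristic: assume the mean catch was taken at a
# moderate exploitation rate (F = 0.2 apical) from a stock near its
# deterministic equilibrium.
start_log_r0 <- function(prep, data) {
  ypr <- per_recruit(prep$bio, 0.2)$ypr
  log(max(mean(data$catch$catch), 1e-6) / max(ypr, 1e-12)) + log(2)
}

#' Fit the catch-conditioned assessment model
#'
#' Fits the simplified integrated, age-structured estimator to an
#' [assessment_data] set under one [scenario_config()] by penalised maximum
#' likelihood. Catches are treated as exact and annual apical F is solved
#' from the Baranov equation inside the objective; estimated parameters are
#' log unfished recruitment, the selectivity parameters of the configured
#' form, and annual recruitment deviates (for years with length-composition
#' data, penalised \eqn{N(0, \sigma_R^2)}). Index catchability is set to its
#' conditional analytic maximum-likelihood estimate. The objective is the
#' lognormal index negative log-likelihood at the configured CV, plus the
#' multinomial length negative log-likelihood at the configured effective
#' sample size, plus the deviate penalty. Optimisation is quasi-Newton
#' (`nlminb` with central-difference gradients) from a fixed deterministic
#' start, so refits are bit-identical.
#'
#' @param data an `assessment_data` object (>= 10 catch years, >= 5 index
#'   observations).
#' @param config a `scenario_config`.
#' @param base baseline `om_parameters` supplying the biology assumed known
#'   (growth, weight, maturity, bins); grid factors come from `config`.
#' @param control optional list: `rel.tol` (default 1e-8), `iter.max`
#'   (default 600), `eval.max` (default 2000), `start` (warm-start parameter
#'   vector).
#' @return An object of class `assessment_fit`.
#' @export
fit_assessment <- function(data, config, base = make_reference_case(),
                           control = list()) {
  if (nrow(data$catch) < 10) stop("need >= 10 years of catch")
  if (nrow(data$index) < 5) stop("need >= 5 index observations")
  prep <- prep_asm_data(data, config, base)
  dat <- prep$dat

  start <- control$start
  if (is.null(start)) {
    start <- c(start_log_r0(prep, data), sel_par_raw(prep$sel0),
               rep(0, length(dat$dev_pos)))
  }
  obj <- function(p) asm_kernel(p, dat, FALSE)$nll
  grad <- function(p) asm_nll_grad(p, dat)$grad
  ctl <- list(rel.tol = control$rel.tol %||% 1e-8,
              iter.max = control$iter.max %||% 600,
              eval.max = control$eval.max %||% 2000)
  opt <- stats::nlminb(start, obj, gradient = grad, control = ctl)
  rep_ <- asm_kernel(opt$par, dat, TRUE)

  years <- prep$years
  nsel <- dat$n_sel
  devs_hat <- stats::setNames(rep(0, dat$n_years), years)
  if (length(dat$dev_pos))
    devs_hat[dat$dev_pos + 1] <- opt$par[(2 + nsel):(1 + nsel +
                                                       length(dat$dev_pos))]
  converged <- opt$convergence == 0 && is.finite(opt$objective) &&
    rep_$all_attainable

  structure(list(
    config = config, base = base,
    par = opt$par,
    log_r0_hat = opt$par[1],
    sel_hat = sel_par_unraw(config$selectivity_form, opt$par[2:(1 + nsel)]),
    q_hat = exp(rep_$logq),
    ssb_hat = stats::setNames(rep_$ssb, years),
    f_hat = stats::setNames(rep_$f, years),
    rec_hat = stats::setNames(rep_$rec, years),
    rec_devs_hat = devs_hat,
    exploitable_b_hat = stats::setNames(rep_$eb, years),
    index_pred = stats::setNames(rep_$index_pred, years),
    index_residuals = stats::setNames(rep_$index_resid, data$index$year),
    lencomp_pred = rep_$lencomp_pred,
    lc_years = prep$lc_years,
    loglik_components = c(index = -rep_$nll_index,
                          length = -rep_$nll_length,
                          penalty = -rep_$nll_penalty),
    nll = opt$objective,
    converged = converged,
    n_params = length(opt$par),
    terminal_n = rep_$terminal_n,
    numbers = rep_$numbers,
    sel_age = rep_$sel_age,
    ssb0_hat = rep_$ssb0,
    years = years,
    data = data,
    opt = opt[c("convergence", "iterations", "evaluations", "message")]
  ), class = "assessment_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assessment_fit <- function(x, ...) {
  T_ <- length(x$years)
  cat("Catch-conditioned assessment fit —", x$config$label, "\n")
  cat(sprintf("  %d years (%d-%d), %d parameters, converged: %s\n",
              T_, x$years[1], x$years[T_], x$n_params, x$converged))
  cat(sprintf("  R0 = %.4g, q = %.4g, terminal SSB = %.1f t, terminal F = %.4f\n",
              exp(x$log_r0_hat), x$q_hat, x$ssb_hat[T_], x$f_hat[T_]))
  cat(sprintf("  negative log-likelihood: %.4f (index %.3f, length %.3f, penalty %.3f)\n",
              x$nll, -x$loglik_components["index"],
              -x$loglik_components["length"], -x$loglik_components["penalty"]))
  invisible(x)
}

#' @export
summary.assessment_fit <- function(object, ...) {
  rp <- compute_refpts(object)
  T_ <- length(object$years)
  out <- list(
    label = object$config$label,
    converged = object$converged,
    n_params = object$n_params,
    nll = object$nll,
    r0_hat = exp(object$log_r0_hat),
    q_hat = object$q_hat,
    ssb0_hat = object$ssb0_hat,
    terminal_ssb = unname(object$ssb_hat[T_]),
    terminal_f = unname(object$f_hat[T_]),
    depletion = unname(object$ssb_hat[T_] / object$ssb0_hat),
    msy = rp$msy, f_msy = rp$f_msy, b_msy = rp$b_msy,
    ssb_ratio = unname(object$ssb_hat[T_] / rp$b_msy),
    f_ratio = unname(object$f_hat[T_] / rp$f_msy)
  )
  out$kobe <- as.character(kobe_classify(out$ssb_ratio, out$f_ratio))
  class(out) <- "summary.assessment_fit"
  out
}

#' @export
print.summary.assessment_fit <- function(x, ...) {
  cat("Assessment summary —", x$label, "\n")
  cat(sprintf("  terminal SSB %.1f t (depletion %.2f), terminal F %.4f\n",
              x$terminal_ssb, x$depletion, x$terminal_f))
  cat(sprintf("  MSY %.1f t/yr, F_MSY %.4f, B_MSY %.1f t\n",
              x$msy, x$f_msy, x$b_msy))
  cat(sprintf("  SSB/B_MSY = %.2f, F/F_MSY = %.2f -> Kobe %s\n",
              x$ssb_ratio, x$f_ratio, x$kobe))
  invisible(x)
}

#' @export
coef.assessment_fit <- function(object, ...) {
  sp <- object$sel_hat$params
  c(log_r0 = object$log_r0_hat,
    stats::setNames(sp, paste0("sel_", names(sp))),
    q = object$q_hat)
}

#' @export
logLik.assessment_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, class = "logLik")
}

#' @export
residuals.assessment_fit <- function(object, ...) {
  object$index_residuals
}

#' @export
plot.assessment_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$years, x$ssb_hat, type = "l", xlab = "Year",
                 ylab = "SSB (t)", main = "Spawning biomass")
  graphics::plot(x$years, x$f_hat, type = "l", xlab = "Year",
                 ylab = "Apical F", main = "Fishing mortality")
  iy <- as.integer(names(x$index_residuals))
  graphics::plot(x$data$index$year, x$data$index$index, xlab = "Year",
                 ylab = "Index", main = "Index fit")
  graphics::lines(x$years, x$index_pred)
  graphics::plot(iy, x$index_residuals, xlab = "Year",
                 ylab = "log residual", main = "Index residuals")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Project a fitted assessment forward
#'
#' Rolls the population forward from the fit's terminal state under a given
#' future catch stream: recruitment at the deterministic stock-recruit
#' expectation (deviates zero), annual F solved from the catch, and the
#' predicted index including the fitted catchability and its assumed trend.
#'
#' @param fit an `assessment_fit`.
#' @param future_catch catch biomass (t) per future year, length >= horizon.
#' @param horizon number of years to project (`>= 0`).
#' @return data frame `year`, `index_pred`, `ssb`, `exploitable_b`, `f`
#'   (zero rows when `horizon = 0`).
#' @export
project <- function(fit, future_catch, horizon = length(future_catch)) {
  if (horizon < 0) stop("horizon must be >= 0")
  empty <- data.frame(year = integer(), index_pred = numeric(),
                      ssb = numeric(), exploitable_b = numeric(),
                      f = numeric())
  if (horizon == 0) return(empty)
  if (length(future_catch) < horizon)
    stop("future_catch must cover the horizon")
  bio <- build_biology(fit$base, selectivity = fit$sel_hat)
  # numbers from the fit (fitted selectivity governs dynamics and index)
  n <- fit$terminal_n
  sel_a <- fit$sel_age
  r0 <- exp(fit$log_r0_hat)
  ssb0 <- fit$ssb0_hat
  h <- fit$config$steepness_h
  T_ <- length(fit$years)
  first <- fit$years[1]
  out <- empty
  for (s in seq_len(horizon)) {
    yr <- fit$years[T_] + s
    ssb <- sum(n[-1] * bio$waa[-1] * bio$mat[-1])
    n[1] <- bh_rec(ssb, h, r0, ssb0)
    eb <- sum(n * bio$waa * sel_a)
    sol <- solve_baranov_f(future_catch[s], n, bio$waa, sel_a, bio$m)
    if (!sol$attainable)
      stop("projected catch unattainable in year ", yr)
    f <- sol$f
    trend <- (1 + fit$config$q_trend_assumed)^(yr - first)
    out <- rbind(out, data.frame(year = yr, index_pred = fit$q_hat * trend * eb,
                                 ssb = ssb, exploitable_b = eb, f = f))
    z <- bio$m + f * sel_a
    n_new <- numeric(length(n))
    n_new[-1] <- n[-length(n)] * exp(-z[-length(z)])
    n_new[length(n)] <- n_new[length(n)] + n[length(n)] * exp(-z[length(z)])
    n <- n_new
  }
  rownames(out) <- NULL
  out
}

#' @export
#' @rdname project
#' @param object an `assessment_fit` (predict method).
#' @param ... unused.
predict.assessment_fit <- function(object, future_catch = NULL,
                                   horizon = NULL, ...) {
  if (is.null(future_catch))
    return(object$index_pred)
  project(object, future_catch, horizon %||% length(future_catch))
}

#' Parametric-bootstrap replicate data from a fit
#'
#' Simulates new index observations (lognormal at the configured CV) and
#' length compositions (multinomial at the configured effective sample
#' size) around the fitted trajectory, keeping catches fixed. This is the
#' parametric-bootstrap device for approximating estimation uncertainty.
#'
#' @param object an `assessment_fit`.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `assessment_data` objects, length `nsim`.
#' @export
simulate.assessment_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  cv <- object$config$index_cv_assumed
  sigma <- sqrt(log(1 + cv^2))
  ess <- object$config$ess_assumed
  iy <- object$data$index$year
  ipred <- object$index_pred[as.character(iy)]
  lc <- object$lencomp_pred
  edges <- build_biology(object$base)$edges
  lapply(seq_len(nsim), function(i) {
    idx <- ipred * exp(stats::rnorm(length(ipred), 0, sigma) - sigma^2 / 2)
    props <- t(apply(lc, 1, function(p)
      as.numeric(stats::rmultinom(1, ess, p)) / ess))
    assessment_data(
      catch = object$data$catch,
      index = data.frame(year = iy, index = as.numeric(idx), cv = cv),
      lencomp = data.frame(
        year = rep(object$lc_years, each = ncol(lc)),
        bin_lower = rep(edges[-length(edges)], length(object$lc_years)),
        proportion = as.numeric(t(props)),
        n = ess))
  })
}

#' @export
compute_refpts.assessment_fit <- function(x, base = x$base) {
  params <- scenario_params(x$config, base)
  params$r0 <- exp(x$log_r0_hat)
  params$selectivity <- x$sel_hat
  compute_refpts(params)
}
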