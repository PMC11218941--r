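# Equilibrium analysis: per-recruit quantities, production functions and
# MSY reference points. All quantities are deterministic (no recruitment
# bias correction at equilibrium) and are defined on the apical F of the
# configured selectivity, so each grid scenario carries its own benchmarks.

# internal: coerce om_parameters / scenario_config to om_parameters
as_om_parameters <- function(x, base = make_reference_case()) {
  if (inherits(x, "om_parameters")) return(x)
  if (inherits(x, "scenario_config")) return(scenario_params(x, base))
  stop("expected om_parameters or scenario_config")
}

# internal: per-recruit spawners / yield / exploitable biomass at apical F.
# Vectorised over f.
per_recruit <- function(bio, f) {
  A <- bio$n_ages
  nf <- length(f)
  Z <- outer(f, bio$sel_a) + rep(bio$m, each = nf)       # nf x A
  n <- matrix(0, nf, A)
  n[, 1] <- 1
  for (a in 2:A) n[, a] <- n[, a - 1] * exp(-Z[, a - 1])
  n[, A] <- n[, A] / (1 - exp(-Z[, A]))
  spr <- n[, -1, drop = FALSE] %*% (bio$waa[-1] * bio$mat[-1])
  fm <- outer(f, bio$sel_a)
  ypr <- rowSums(n * (fm / Z) * (1 - exp(-Z)) *
                   rep(bio$waa, each = nf))
  ebpr <- n %*% (bio$waa * bio$sel_a)
  list(spr = as.numeric(spr), ypr = as.numeric(ypr),
       ebpr = as.numeric(ebpr))
}

#' Equilibrium state at a fishing mortality
#'
#' Computes spawners-per-recruit and yield-per-recruit over the age
#' structure at apical fishing mortality `f`, solves the Beverton-Holt
#' equilibrium recruitment
#' \eqn{R(F) = \max(0, R_0 (4h\,s(F) - s_0(1-h)) / ((5h-1)\,s(F)))}
#' (with \eqn{s} spawning biomass per recruit), and returns the equilibrium
#' yield, spawning biomass and selectivity-weighted exploitable biomass.
#'
#' @param x an `om_parameters` or `scenario_config` object.
#' @param f apical fishing mortality (vectorised, `>= 0`).
#' @param base baseline `om_parameters` used when `x` is a scenario.
#' @return data frame with columns `f`, `yield`, `ssb`, `exploitable_b`,
#'   `recruits`.
#' @export
#' @examples
#' eq <- equilibrium_state(make_reference_case(), c(0, 0.1, 0.2))
#' eq$yield[1]  # 0 at F = 0
equilibrium_state <- function(x, f, base = make_reference_case()) {
  if (any(f < 0)) stop("f must be >= 0")
  params <- as_om_parameters(x, base)
  eq_state_bio(build_biology(params), params, f)
}

# internal: equilibrium state with a prebuilt biology (avoids rebuilding
# the age-length machinery inside optimisation loops)
eq_state_bio <- function(bio, params, f) {
  pr <- per_recruit(bio, f)
  s0 <- per_recruit(bio, 0)$spr
  h <- params$steepness_h
  r <- pmax(0, params$r0 * (4 * h * pr$spr - s0 * (1 - h)) /
              ((5 * h - 1) * pr$spr))
  data.frame(f = f, yield = r * pr$ypr, ssb = r * pr$spr,
             exploitable_b = r * pr$ebpr, recruits = r)
}

# internal: F at which equilibrium recruitment reaches zero (crash F),
# capped at f_max when the stock cannot be crashed by apical F alone.
crash_f <- function(params, f_max = 5, bio = build_biology(params)) {
  s0 <- per_recruit(bio, 0)$spr
  h <- params$steepness_h
  thresh <- s0 * (1 - h) / (4 * h)
  if (per_recruit(bio, f_max)$spr > thresh) return(f_max)
  lo <- 0; hi <- f_max
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (per_recruit(bio, mid)$spr > thresh) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Production function
#'
#' Samples the equilibrium (spawning biomass, yield) curve on an F grid from
#' 0 to the crash F, the classic dome whose peak is MSY.
#'
#' @param x an `om_parameters` or `scenario_config`.
#' @param n_points number of F grid points (>= 3).
#' @param base baseline parameters for scenario configs.
#' @return data frame `f`, `ssb`, `exploitable_b`, `yield`, ordered by
#'   increasing F (decreasing biomass), passing through (ssb0, 0) at F = 0.
#' @export
production_function <- function(x, n_points = 200,
                                base = make_reference_case()) {
  if (n_points < 3) stop("n_points must be >= 3")
  params <- as_om_parameters(x, base)
  fgrid <- seq(0, crash_f(params), length.out = n_points)
  eq <- equilibrium_state(params, fgrid)
  eq[, c("f", "ssb", "exploitable_b", "yield")]
}

#' MSY reference points
#'
#' Locates F_MSY by golden-section search on the equilibrium yield curve
#' over \[0, crash F\] (assumed unimodal; falls back to a brute-force F grid
#' with a warning if the bracket degenerates) and fills MSY, B_MSY, unfished
#' spawning biomass and carrying capacity from [equilibrium_state()].
#'
#' @param x an `om_parameters`, `scenario_config`, or `assessment_fit` (for
#'   a fit, the estimated R0 and selectivity are used so the benchmarks are
#'   scenario-specific).
#' @param base baseline parameters for scenario configs.
#' @return An object of class `ref_points`: list with `msy`, `f_msy`,
#'   `b_msy`, `ssb0`, `k_carrying` (unfished exploitable biomass), `eb_msy`
#'   and the sampled `production_curve`.
#' @export
compute_refpts <- function(x, base = make_reference_case()) {
  UseMethod("compute_refpts")
}

#' @export
compute_refpts.default <- function(x, base = make_reference_case()) {
  params <- as_om_parameters(x, base)
  bio <- build_biology(params)
  fc <- crash_f(params, bio = bio)
  yield_at <- function(f) eq_state_bio(bio, params, f)$yield

  # golden-section search for the maximum
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- fc
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  yc <- yield_at(c_); yd <- yield_at(d_)
  for (i in 1:80) {
    if (yc > yd) { b <- d_; d_ <- c_; yd <- yc
      c_ <- b - gr * (b - a); yc <- yield_at(c_)
    } else { a <- c_; c_ <- d_; yc <- yd
      d_ <- a + gr * (b - a); yd <- yield_at(d_)
    }
  }
  f_msy <- (a + b) / 2
  msy <- yield_at(f_msy)
  if (!is.finite(msy) || msy <= 0) {
    warning("golden-section bracket failed; using brute-force F grid")
    fg <- seq(0, fc, by = max(fc / 5000, 1e-4))
    yg <- eq_state_bio(bio, params, fg)$yield
    f_msy <- fg[which.max(yg)]
    msy <- max(yg)
  }
  eq_msy <- eq_state_bio(bio, params, f_msy)
  eq0 <- eq_state_bio(bio, params, 0)
  structure(list(
    msy = msy, f_msy = f_msy, b_msy = eq_msy$ssb,
    eb_msy = eq_msy$exploitable_b,
    ssb0 = eq0$ssb, k_carrying = eq0$exploitable_b,
    crash_f = fc,
    production_curve = production_function(params, n_points = 101),
    params = params
  ), class = "ref_points")
}

#' @export
print.ref_points <- function(x, ...) {
  cat(sprintf(
    "MSY reference points:\n  MSY = %.1f t/yr  F_MSY = %.4f  B_MSY = %.1f t\n  SSB0 = %.1f t  K (exploitable) = %.1f t  B_MSY/SSB0 = %.3f\n",
    x$msy, x$f_msy, x$b_msy, x$ssb0, x$k_carrying, x$b_msy / x$ssb0))
  invisible(x)
}

#' @export
plot.ref_points <- function(x, ...) {
  pc <- x$production_curve
  graphics::plot(pc$ssb, pc$yield, type = "l", xlab = "Equilibrium SSB (t)",
                 ylab = "Equilibrium yield (t/yr)", ...)
  graphics::points(x$b_msy, x$msy, pch = 19)
  graphics::abline(v = x$b_msy, lty = 3)
  invisible(x)
}

#' Equilibrium production expectation
#'
#' Returns the deterministic expectation of annual surplus production as a
#' function of exploitable biomass, interpolated from the equilibrium
#' production curve. Used by [process_error()] to contrast realised biomass
#' against the deterministic expectation.
#'
#' @param x an `om_parameters` or `scenario_config`.
#' @param base baseline parameters for scenario configs.
#' @return a function mapping exploitable biomass (t) to expected surplus
#'   production (t/yr); clamped to 0 outside the sampled biomass range.
#' @export
production_expectation <- function(x, base = make_reference_case()) {
  params <- as_om_parameters(x, base)
  fgrid <- seq(0, crash_f(params), length.out = 400)
  eq <- equilibrium_state(params, fgrid)
  ok <- is.finite(eq$exploitable_b) & is.finite(eq$yield)
  stats::approxfun(eq$exploitable_b[ok], eq$yield[ok], rule = 2)
}
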