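# The validation toolbox: surplus production and process error, residual
# runs test, retrospective peels with Mohn's rho, tail-cutting hindcast
# with MASE and the Diebold-Mariano test.

#' Surplus production series
#'
#' Annual surplus production \eqn{P_t = B_{t+1} - B_t + C_t}: the net
#' addition to biomass (recruitment plus growth minus natural deaths) that
#' would have occurred absent catch. By construction the identity
#' \eqn{B_{t+1} = B_t - C_t + P_t} holds exactly.
#'
#' @param biomass named (by year) or plain biomass series (t), length >= 2.
#' @param catch catch series (t) aligned with `biomass` (same years; the
#'   final catch value is unused and may be omitted).
#' @param years optional years; defaults to names or seq_along.
#' @return data frame `year`, `biomass`, `catch`, `production` (production
#'   defined for all but the final year, which is dropped).
#' @export
#' @examples
#' surplus_production(c(100, 110), c(5, 0))$production  # 15
surplus_production <- function(biomass, catch, years = NULL) {
  n <- length(biomass)
  if (n < 2) stop("need >= 2 years of biomass")
  if (!length(catch) %in% c(n - 1, n))
    stop("biomass and catch years misaligned")
  if (is.null(years))
    years <- if (!is.null(names(biomass))) as.numeric(names(biomass))
             else seq_len(n)
  catch <- catch[seq_len(n - 1)]
  p <- biomass[-1] - biomass[-n] + catch
  data.frame(year = years[seq_len(n - 1)],
             biomass = as.numeric(biomass[seq_len(n - 1)]),
             catch = as.numeric(catch), production = as.numeric(p))
}

#' Process error series
#'
#' Log-scale deviation of realised biomass from its deterministic
#' expectation:
#' \eqn{\epsilon_t = \log(B_{t+1}) - \log(B_t - C_t + \hat P(B_t))}, where
#' \eqn{\hat P} is the deterministic surplus-production expectation (e.g.
#' the equilibrium mapping from [production_expectation()]).
#'
#' @param biomass biomass series (t), length >= 3.
#' @param catch aligned catch series (t).
#' @param expectation function mapping biomass to expected production.
#' @param years optional years.
#' @return data frame `year`, `epsilon`; years where the log argument is
#'   non-positive are recorded as `NA` with a warning.
#' @export
process_error <- function(biomass, catch, expectation, years = NULL) {
  n <- length(biomass)
  if (n < 3) {
    return(data.frame(year = numeric(0), epsilon = numeric(0)))
  }
  if (!length(catch) %in% c(n - 1, n))
    stop("biomass and catch years misaligned")
  if (is.null(years))
    years <- if (!is.null(names(biomass))) as.numeric(names(biomass))
             else seq_len(n)
  b <- as.numeric(biomass)
  arg <- b[-n] - catch[seq_len(n - 1)] + expectation(b[-n])
  eps <- ifelse(arg > 0, log(b[-1]) - log(arg), NA_real_)
  if (anyNA(eps))
    warning("non-positive expected biomass; recorded as NA")
  data.frame(year = years[seq_len(n - 1)], epsilon = eps)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether the sequence of residual signs is random. With \eqn{n^+}
#' positive, \eqn{n^-} negative residuals and \eqn{R} observed runs, the
#' normal approximation uses \eqn{\mu = 2n^+n^-/n + 1} and
#' \eqn{\sigma^2 = 2n^+n^-(2n^+n^- - n)/(n^2(n-1))};
#' \eqn{z = (R-\mu)/\sigma} with a two-sided p-value. Passing (no evidence
#' of autocorrelated or one-sided misfit) requires `p >= alpha`.
#'
#' @param residuals signed residual series; zeros are dropped.
#' @param alpha significance level (default 0.05).
#' @return list `n_runs`, `z`, `p_value`, `pass`, and `reason`
#'   (`"degenerate"` when all residuals share one sign, which fails).
#' @export
runs_test <- function(residuals, alpha = 0.05) {
  s <- sign(residuals)
  s <- s[s != 0]
  np <- sum(s > 0); nn <- sum(s < 0); n <- np + nn
  if (np == 0 || nn == 0 || n < 2) {
    return(list(n_runs = if (n) 1L else 0L, z = NA_real_,
                p_value = NA_real_, pass = FALSE, reason = "degenerate"))
  }
  r <- 1L + sum(diff(s) != 0)
  mu <- 2 * np * nn / n + 1
  sig2 <- 2 * np * nn * (2 * np * nn - n) / (n^2 * (n - 1))
  z <- (r - mu) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(n_runs = r, z = z, p_value = p, pass = p >= alpha, reason = "ok")
}

#' Retrospective peels
#'
#' Refits the model on successively truncated data: peel `p` uses all data
#' (catch, index and length compositions) through year `T - p`; peel 0 is
#' the full fit.
#'
#' @param data an `assessment_data`.
#' @param config a `scenario_config`.
#' @param n_peels number of peels (>= 1; the truncated series must keep at
#'   least 10 years).
#' @param base baseline `om_parameters`.
#' @param fit0 optional pre-computed full fit to reuse as peel 0.
#' @return list of `assessment_fit` (length `n_peels + 1`), class
#'   `retro_fits`; non-convergent peels are kept but flagged.
#' @export
retro_peels <- function(data, config, n_peels = 3,
                        base = make_reference_case(), fit0 = NULL) {
  T_ <- max(data$catch$year)
  if (n_peels < 1) stop("n_peels must be >= 1")
  if (nrow(data$catch) - n_peels < 10)
    stop("peeling would leave fewer than 10 years")
  fits <- vector("list", n_peels + 1)
  fits[[1]] <- fit0 %||% fit_assessment(data, config, base)
  for (p in seq_len(n_peels)) {
    fits[[p + 1]] <- fit_assessment(truncate_data(data, T_ - p), config, base)
  }
  structure(fits, class = "retro_fits")
}

#' Mohn's rho
#'
#' Retrospective bias statistic:
#' \eqn{\rho = \frac{1}{P}\sum_{p=1}^{P}
#'   (\hat X^{(p)}_{T-p} - \hat X^{(0)}_{T-p}) / \hat X^{(0)}_{T-p}},
#' the mean relative difference between each peel's terminal estimate and
#' the full fit's estimate for that year. The conventional pass band is
#' \eqn{-0.15 < \rho < 0.2}.
#'
#' @param peel_fits a `retro_fits` list (full fit first) from
#'   [retro_peels()], or a plain list of numeric year-named series (full
#'   first).
#' @param quantity `"ssb"` or `"f"`.
#' @param band pass band, default `c(-0.15, 0.2)`.
#' @return list `rho`, `pass`, `peels_used`.
#' @export
mohn_rho <- function(peel_fits, quantity = c("ssb", "f"),
                     band = c(-0.15, 0.2)) {
  quantity <- match.arg(quantity)
  series <- lapply(peel_fits, function(f) {
    if (inherits(f, "assessment_fit")) {
      if (!isTRUE(f$converged)) return(NULL)
      if (quantity == "ssb") f$ssb_hat else f$f_hat
    } else f
  })
  full <- series[[1]]
  if (is.null(full)) stop("full fit did not converge")
  terms <- numeric(0)
  dropped <- 0L
  for (p in seq_along(series)[-1]) {
    s <- series[[p]]
    if (is.null(s)) { dropped <- dropped + 1L; next }
    yr <- names(s)[length(s)]
    denom <- full[yr]
    if (!is.finite(denom) || denom == 0) stop("zero denominator in Mohn's rho")
    terms <- c(terms, (s[[length(s)]] - denom) / denom)
  }
  if (dropped > 0)
    warning(dropped, " non-convergent peel(s) excluded from Mohn's rho")
  if (!length(terms)) stop("no valid peels")
  rho <- unname(mean(terms))
  list(rho = rho, pass = rho > band[1] && rho < band[2],
       peels_used = length(terms))
}

#' Mean absolute scaled error
#'
#' \eqn{MASE = \mathrm{mean}(|o - \hat o|) / \mathrm{mean}(|o - o^{naive}|)},
#' computed on the log scale by default (abundance indices are lognormal).
#' Values below 1 indicate more skill than the naive (random-walk
#' persistence) forecast.
#'
#' @param observed,predicted,naive aligned non-empty series.
#' @param log_scale compute on log values (default `TRUE`).
#' @return MASE, `>= 0`.
#' @export
mase <- function(observed, predicted, naive, log_scale = TRUE) {
  n <- length(observed)
  if (n == 0 || length(predicted) != n || length(naive) != n)
    stop("observed, predicted and naive must be aligned and non-empty")
  if (log_scale) {
    observed <- log(observed); predicted <- log(predicted)
    naive <- log(naive)
  }
  denom <- mean(abs(observed - naive))
  if (denom == 0) stop("no-information benchmark: naive errors are all zero")
  mean(abs(observed - predicted)) / denom
}

#' Diebold-Mariano test of predictive accuracy
#'
#' Compares two forecast-error series via the loss differential
#' \eqn{d_t = |e^{model}_t| - |e^{naive}_t|}. The statistic is
#' \eqn{\bar d / \sqrt{\mathrm{var}(d)/n}} multiplied by the Harvey
#' small-sample correction \eqn{\sqrt{(n + 1 - 2h + h(h-1)/n)/n}} for
#' forecast horizon `h`, referred to a t distribution with `n - 1` degrees
#' of freedom (two-sided).
#'
#' @param errors_model,errors_naive aligned error series, n >= 3.
#' @param h forecast horizon (default 1).
#' @return list `statistic`, `p_value`.
#' @export
diebold_mariano <- function(errors_model, errors_naive, h = 1) {
  n <- length(errors_model)
  if (n < 3 || length(errors_naive) != n)
    stop("need aligned error series with n >= 3")
  d <- abs(errors_model) - abs(errors_naive)
  v <- stats::var(d)
  if (v == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p_value = 1))
    warning("degenerate loss differential with non-zero mean")
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0))
  }
  dm <- mean(d) / sqrt(v / n)
  corr <- sqrt((n + 1 - 2 * h + h * (h - 1) / n) / n)
  stat <- dm * corr
  list(statistic = stat, p_value = 2 * stats::pt(-abs(stat), df = n - 1))
}

#' Hindcast cross-validation (tail cutting)
#'
#' For each peel `p = 1..n_peels`, the model is refitted on data through
#' year `T - p` and projected forward with the retained actual catches
#' (catches are data under catch-conditioning); the projected index is
#' compared with the withheld index observations up to `horizon` steps
#' ahead. The naive benchmark persists the last retained index observation.
#'
#' @param data an `assessment_data`.
#' @param config a `scenario_config`.
#' @param n_peels number of peels.
#' @param horizon forecast horizon (years ahead).
#' @param base baseline `om_parameters`.
#' @return data frame `peel`, `year`, `horizon`, `observed`, `predicted`,
#'   `naive`, class `hindcast`; peels without withheld observations are
#'   skipped with a warning, non-convergent peels with a warning.
#' @export
hindcast <- function(data, config, n_peels = 5, horizon = 1,
                     base = make_reference_case()) {
  T_ <- max(data$catch$year)
  out <- NULL
  for (p in seq_len(n_peels)) {
    cut <- T_ - p
    wh <- data$index[data$index$year > cut &
                       data$index$year <= cut + horizon, , drop = FALSE]
    if (nrow(wh) == 0) {
      warning("peel ", p, ": no withheld index observation; skipped")
      next
    }
    retained <- data$index[data$index$year <= cut, , drop = FALSE]
    if (nrow(retained) == 0) {
      warning("peel ", p, ": no retained index observation; skipped")
      next
    }
    fit <- fit_assessment(truncate_data(data, cut), config, base)
    if (!isTRUE(fit$converged)) {
      warning("peel ", p, ": fit did not converge; skipped")
      next
    }
    fc <- data$catch$catch[data$catch$year > cut]
    hmax <- min(horizon, length(fc))
    proj <- project(fit, fc, hmax)
    naive <- retained$index[nrow(retained)]
    m <- match(wh$year, proj$year)
    keep <- !is.na(m)
    if (!any(keep)) next
    out <- rbind(out, data.frame(
      peel = p, year = wh$year[keep], horizon = wh$year[keep] - cut,
      observed = wh$index[keep], predicted = proj$index_pred[m[keep]],
      naive = naive))
  }
  if (is.null(out))
    out <- data.frame(peel = integer(), year = integer(),
                      horizon = integer(), observed = numeric(),
                      predicted = numeric(), naive = numeric())
  rownames(out) <- NULL
  class(out) <- c("hindcast", "data.frame")
  out
}

#' MASE per horizon from a hindcast table
#'
#' Pools absolute (log-scale) errors across peels within each horizon, so
#' the naive denominator is stable even with one observation per peel.
#'
#' @param hc a [hindcast()] table.
#' @param log_scale compute on log values (default `TRUE`).
#' @return data frame `horizon`, `mase`, `n`.
#' @export
hindcast_mase <- function(hc, log_scale = TRUE) {
  if (nrow(hc) == 0)
    return(data.frame(horizon = integer(), mase = numeric(), n = integer()))
  hs <- sort(unique(hc$horizon))
  data.frame(
    horizon = hs,
    mase = vapply(hs, function(h) {
      sub <- hc[hc$horizon == h, ]
      mase(sub$observed, sub$predicted, sub$naive, log_scale)
    }, numeric(1)),
    n = vapply(hs, function(h) sum(hc$horizon == h), integer(1)))
}

#' Full diagnostic report for one scenario
#'
#' Runs the complete validation battery on one configuration: the full fit
#' with a runs test on its log index residuals, retrospective peels with
#' Mohn's rho on SSB and F, and a tail-cutting hindcast with pooled MASE
#' per horizon and a Diebold-Mariano comparison against the naive forecast
#' at horizon 1.
#'
#' @param data an `assessment_data`.
#' @param config a `scenario_config`.
#' @param n_peels retrospective peels (default 3).
#' @param hind_peels hindcast peels (default 5).
#' @param horizon hindcast horizon (default 1).
#' @param alpha runs-test level (default 0.05).
#' @param rho_band Mohn's rho pass band (default `c(-0.15, 0.2)`).
#' @param mase_threshold MASE pass threshold (default 1).
#' @param base baseline `om_parameters`.
#' @param fit optional pre-computed full fit.
#' @return An object of class `diagnostic_report`: lists `runs`, `rho_ssb`,
#'   `rho_f`, `mase` (per horizon), `dm`, `pass` (named logical vector
#'   `runs`, `rho`, `mase`), `fit`, `peels_used`.
#' @export
diagnose <- function(data, config, n_peels = 3, hind_peels = 5, horizon = 1,
                     alpha = 0.05, rho_band = c(-0.15, 0.2),
                     mase_threshold = 1, base = make_reference_case(),
                     fit = NULL) {
  fit <- fit %||% fit_assessment(data, config, base)
  runs <- runs_test(residuals(fit), alpha)
  peels <- retro_peels(data, config, n_peels, base, fit0 = fit)
  rho_ssb <- mohn_rho(peels, "ssb", rho_band)
  rho_f <- mohn_rho(peels, "f", rho_band)
  hc <- hindcast(data, config, hind_peels, horizon, base)
  mtab <- hindcast_mase(hc)
  mase_h1 <- if (nrow(mtab)) mtab$mase[mtab$horizon == min(mtab$horizon)]
             else NA_real_
  dm <- if (nrow(hc) >= 3) {
    sub <- hc[hc$horizon == min(hc$horizon), ]
    if (nrow(sub) >= 3)
      diebold_mariano(log(sub$observed) - log(sub$predicted),
                      log(sub$observed) - log(sub$naive),
                      h = min(hc$horizon))
    else list(statistic = NA_real_, p_value = NA_real_)
  } else list(statistic = NA_real_, p_value = NA_real_)

  structure(list(
    label = config$label,
    runs = runs, rho_ssb = rho_ssb, rho_f = rho_f,
    mase = mtab, mase_h1 = mase_h1, dm = dm, hindcast = hc,
    pass = c(runs = isTRUE(runs$pass), rho = isTRUE(rho_ssb$pass),
             mase = isTRUE(is.finite(mase_h1) && mase_h1 < mase_threshold)),
    fit = fit, peels_used = rho_ssb$peels_used
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report —", x$label, "\n")
  cat(sprintf("  runs test: p = %.4f (%s)\n", x$runs$p_value,
              if (x$pass["runs"]) "pass" else "fail"))
  cat(sprintf("  Mohn's rho: SSB %.4f, F %.4f (%s)\n", x$rho_ssb$rho,
              x$rho_f$rho, if (x$pass["rho"]) "pass" else "fail"))
  cat(sprintf("  MASE (h=1): %.4f (%s)\n", x$mase_h1,
              if (x$pass["mase"]) "pass" else "fail"))
  if (is.finite(x$dm$statistic))
    cat(sprintf("  Diebold-Mariano: %.3f (p = %.4f)\n", x$dm$statistic,
                x$dm$p_value))
  invisible(x)
}
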