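#' Fishery selectivity specification
#'
#' Describes length-based selectivity of the fleet. Two functional forms are
#' supported: `"logistic"`, which rises to and stays at the maximum for large
#' fish, and `"double_normal"`, which declines again for fish larger than the
#' peak (dome-shaped).
#'
#' @param form `"logistic"` or `"double_normal"`.
#' @param params named numeric vector: `c(L50=, L95=)` for the logistic
#'   (lengths in cm at 50% and 95% selection), or `c(peak=, asc=, desc=)`
#'   for the double normal (peak length and the ascending/descending
#'   Gaussian widths, cm).
#' @return An object of class `selectivity_spec`.
#' @seealso [selectivity_at_length()]
#' @export
#' @examples
#' sel <- selectivity_spec("logistic", c(L50 = 80, L95 = 95))
#' selectivity_at_length(sel, 80)  # 0.5 at L50
selectivity_spec <- function(form = c("logistic", "double_normal"),
                             params = NULL) {
  form <- match.arg(form)
  if (is.null(params)) {
    params <- switch(form,
      logistic = c(L50 = 80, L95 = 95),
      double_normal = c(peak = 90, asc = 15, desc = 20)
    )
  }
  if (form == "logistic") {
    if (!all(c("L50", "L95") %in% names(params)))
      stop("logistic selectivity needs params L50 and L95")
    if (params[["L95"]] <= params[["L50"]])
      stop("selectivity requires L95 > L50")
  } else {
    if (!all(c("peak", "asc", "desc") %in% names(params)))
      stop("double_normal selectivity needs params peak, asc and desc")
    if (params[["asc"]] <= 0 || params[["desc"]] <= 0)
      stop("double_normal widths must be > 0")
  }
  structure(list(form = form, params = params), class = "selectivity_spec")
}

#' Selectivity at length
#'
#' Evaluates a [selectivity_spec()] at one or more lengths. The logistic form
#' is \eqn{1/(1+\exp(-\log(19)(L-L_{50})/(L_{95}-L_{50})))}; the double
#' normal is a Gaussian kernel with separate ascending and descending widths
#' around the peak, so selection is 1 at the peak and falls off on both
#' sides.
#'
#' @param spec a `selectivity_spec`.
#' @param length numeric vector of lengths (cm), `>= 0`.
#' @return numeric vector of selection fractions in \[0, 1\].
#' @export
selectivity_at_length <- function(spec, length) {
  if (!inherits(spec, "selectivity_spec"))
    stop("`spec` must be a selectivity_spec")
  if (any(length < 0)) stop("length must be >= 0")
  p <- spec$params
  if (spec$form == "logistic") {
    1 / (1 + exp(-log(19) * (length - p[["L50"]]) / (p[["L95"]] - p[["L50"]])))
  } else {
    w <- ifelse(length < p[["peak"]], p[["asc"]], p[["desc"]])
    exp(-(length - p[["peak"]])^2 / (2 * w^2))
  }
}

#' @export
print.selectivity_spec <- function(x, ...) {
  cat("Selectivity:", x$form, "(",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

# internal: raw parameter vector used by the estimator
sel_par_raw <- function(spec) {
  p <- spec$params
  if (spec$form == "logistic") {
    c(p[["L50"]], log(p[["L95"]] - p[["L50"]]))
  } else {
    c(p[["peak"]], log(p[["asc"]]), log(p[["desc"]]))
  }
}

sel_par_unraw <- function(form, raw) {
  if (form == "logistic") {
    selectivity_spec("logistic", c(L50 = raw[1], L95 = raw[1] + exp(raw[2])))
  } else {
    selectivity_spec("double_normal",
                     c(peak = raw[1], asc = exp(raw[2]), desc = exp(raw[3])))
  }
}
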