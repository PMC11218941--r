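# Factorial grid construction, scenario evaluation, diagnostic weighting,
# Kobe classification and the regression-tree factor analysis.

#' Standard uncertainty-grid factors
#'
#' The full seven-factor design used for Indian Ocean albacore-style
#' assessments: natural mortality (five juvenile/adult combinations),
#' steepness (3), recruitment variability (2), length-composition effective
#' sample size (3), index CV (4), catchability trend (2) and selectivity
#' form (2) — 1,440 cells in all. The reference level of each factor is the
#' [make_reference_case()] value.
#'
#' @return list with `factors` (ordered named list of level vectors) and
#'   `reference` (named character vector of reference levels).
#' @export
default_grid_factors <- function() {
  list(
    factors = list(
      M = c("0.2", "0.3", "0.4", "0.4/0.3", "0.4/0.2"),
      h = c("0.7", "0.8", "0.9"),
      sR = c("0.4", "0.6"),
      E = c("20", "50", "100"),
      CV = c("0.2", "0.3", "0.4", "0.5"),
      q = c("0", "0.01"),
      sel = c("Log", "DoNorm")
    ),
    reference = c(M = "0.3", h = "0.7", sR = "0.4", E = "50", CV = "0.3",
                  q = "0", sel = "Log")
  )
}

#' Build a factorial scenario grid
#'
#' Full Cartesian product of the factor levels in deterministic
#' (lexicographic by declared factor order, first factor varying slowest)
#' order, with labels that encode the levels.
#'
#' @param factors ordered named list: factor name -> character/numeric level
#'   vector (each with >= 1 unique level).
#' @param reference named vector of reference levels (one per factor); all
#'   must appear in their factor's levels.
#' @return An object of class `scenario_grid`: list with `factors`,
#'   `levels` (data frame, one row per scenario), `labels`,
#'   `reference_label`, and `n`.
#' @export
#' @examples
#' g <- build_grid(list(a = 1:2, b = c("x", "y", "z")),
#'                 reference = c(a = "1", b = "x"))
#' g$n  # 6
build_grid <- function(factors, reference = NULL) {
  if (!length(factors) || is.null(names(factors)))
    stop("factors must be a named list")
  factors <- lapply(factors, as.character)
  for (nm in names(factors)) {
    if (!length(factors[[nm]])) stop("factor ", nm, " has no levels")
    if (anyDuplicated(factors[[nm]]))
      stop("duplicate levels within factor ", nm)
  }
  if (is.null(reference))
    reference <- vapply(factors, `[`, character(1), 1)
  reference <- as.character(reference)[match(names(factors),
                                             names(reference) %||%
                                               names(factors))]
  names(reference) <- names(factors)
  for (nm in names(factors))
    if (!reference[[nm]] %in% factors[[nm]])
      stop("reference level for ", nm, " not among its levels")

  # first declared factor varies slowest (lexicographic by declared order)
  lv <- expand.grid(rev(factors), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  lv <- lv[, rev(seq_along(factors)), drop = FALSE]
  names(lv) <- names(factors)
  labels <- apply(lv, 1, function(r)
    paste0(names(factors), r, collapse = "_"))
  rownames(lv) <- NULL
  structure(list(factors = factors, levels = lv, labels = unname(labels),
                 reference_label = paste0(names(factors), reference,
                                          collapse = "_"),
                 n = nrow(lv)),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("Scenario grid:", x$n, "cells over",
      length(x$factors), "factors (",
      paste(names(x$factors), vapply(x$factors, length, integer(1)),
            sep = ":", collapse = ", "), ")\n")
  cat("  reference:", x$reference_label, "\n")
  invisible(x)
}

# internal: one grid row (canonical 7 factors) -> scenario_config
row_to_config <- function(row, label) {
  m <- strsplit(as.character(row[["M"]]), "/", fixed = TRUE)[[1]]
  mj <- as.numeric(m[1])
  ma <- if (length(m) > 1) as.numeric(m[2]) else mj
  scenario_config(
    m_juvenile = mj, m_adult = ma,
    steepness_h = as.numeric(row[["h"]]),
    sigma_r = as.numeric(row[["sR"]]),
    ess_assumed = as.numeric(row[["E"]]),
    index_cv_assumed = as.numeric(row[["CV"]]),
    q_trend_assumed = as.numeric(row[["q"]]),
    selectivity_form = if (row[["sel"]] == "Log") "logistic"
                       else "double_normal",
    label = label)
}

#' Scenario configurations of a grid
#'
#' Converts a canonical seven-factor grid (factors `M`, `h`, `sR`, `E`,
#' `CV`, `q`, `sel`) into a list of [scenario_config()] objects.
#'
#' @param grid a `scenario_grid` built from the canonical factors.
#' @return list of `scenario_config`, one per cell, named by label.
#' @export
grid_configs <- function(grid) {
  need <- c("M", "h", "sR", "E", "CV", "q", "sel")
  if (!all(need %in% names(grid$factors)))
    stop("grid must carry the canonical factors ",
         paste(need, collapse = ", "))
  out <- lapply(seq_len(grid$n), function(i)
    row_to_config(grid$levels[i, , drop = FALSE], grid$labels[i]))
  names(out) <- grid$labels
  out
}

#' Evaluate every scenario of a grid against one data set
#'
#' Runs the full battery per cell — [fit_assessment()],
#' [compute_refpts()] on the fit, and [diagnose()] (retrospective,
#' hindcast, runs test) — and collects one summary row per scenario.
#' Failures are recorded per cell, never fatal. Cells are cached by
#' scenario label plus a hash of the data and settings, so re-running with
#' unchanged inputs refits nothing.
#'
#' @param data an `assessment_data`.
#' @param grid a canonical `scenario_grid` (see [grid_configs()]).
#' @param settings list of diagnostic settings: `n_peels` (3), `hind_peels`
#'   (5), `horizon` (1), `alpha` (0.05), `rho_band` (c(-0.15, 0.2)),
#'   `mase_threshold` (1).
#' @param base baseline `om_parameters`.
#' @param cache optional environment (or `NULL`) used as the cell cache;
#'   pass the same environment across calls to reuse results.
#' @param verbose print progress.
#' @return data frame of class `grid_result`, one row per scenario with the
#'   factor levels, convergence flag, estimates (`ssb0`, `terminal_ssb`,
#'   `terminal_f`), reference points (`msy`, `f_msy`, `b_msy`, `k`), Kobe
#'   ratios and quadrant, and diagnostics (`rho_ssb`, `rho_f`, `rho_pass`,
#'   `mase_h1`, `mase_pass`, `runs_p`, `runs_pass`, `dm_stat`, `dm_p`).
#' @export
evaluate_grid <- function(data, grid, settings = list(),
                          base = make_reference_case(), cache = NULL,
                          verbose = FALSE) {
  st <- list(n_peels = settings$n_peels %||% 3,
             hind_peels = settings$hind_peels %||% 5,
             horizon = settings$horizon %||% 1,
             alpha = settings$alpha %||% 0.05,
             rho_band = settings$rho_band %||% c(-0.15, 0.2),
             mase_threshold = settings$mase_threshold %||% 1)
  configs <- grid_configs(grid)
  key_base <- object_hash(list(data, st, base))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    key <- paste0(cfg$label, "_", key_base)
    if (!is.null(cache) && !is.null(cache[[key]])) {
      rows[[i]] <- cache[[key]]
      next
    }
    row <- evaluate_one(data, cfg, st, base)
    row <- cbind(grid$levels[i, , drop = FALSE], row)
    rows[[i]] <- row
    if (!is.null(cache)) cache[[key]] <- row
    if (verbose) message(i, "/", length(configs), " ", cfg$label)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_label") <- grid$reference_label
  class(out) <- c("grid_result", "data.frame")
  out
}

# internal: one scenario -> one summary row; errors trapped into flags
evaluate_one <- function(data, cfg, st, base) {
  empty <- data.frame(
    label = cfg$label, converged = FALSE, error = NA_character_,
    ssb0 = NA_real_, terminal_ssb = NA_real_, terminal_f = NA_real_,
    msy = NA_real_, f_msy = NA_real_, b_msy = NA_real_, k = NA_real_,
    ssb_ratio = NA_real_, f_ratio = NA_real_, kobe = NA_character_,
    rho_ssb = NA_real_, rho_f = NA_real_, rho_pass = NA,
    mase_h1 = NA_real_, mase_pass = NA, runs_p = NA_real_, runs_pass = NA,
    dm_stat = NA_real_, dm_p = NA_real_, nll = NA_real_,
    stringsAsFactors = FALSE)
  res <- tryCatch({
    dg <- suppressWarnings(diagnose(
      data, cfg, n_peels = st$n_peels, hind_peels = st$hind_peels,
      horizon = st$horizon, alpha = st$alpha, rho_band = st$rho_band,
      mase_threshold = st$mase_threshold, base = base))
    fit <- dg$fit
    rp <- compute_refpts(fit)
    T_ <- length(fit$years)
    sr <- unname(fit$ssb_hat[T_] / rp$b_msy)
    fr <- unname(fit$f_hat[T_] / rp$f_msy)
    data.frame(
      label = cfg$label, converged = fit$converged, error = NA_character_,
      ssb0 = fit$ssb0_hat, terminal_ssb = unname(fit$ssb_hat[T_]),
      terminal_f = unname(fit$f_hat[T_]),
      msy = rp$msy, f_msy = rp$f_msy, b_msy = rp$b_msy, k = rp$k_carrying,
      ssb_ratio = sr, f_ratio = fr,
      kobe = as.character(kobe_classify(sr, fr)),
      rho_ssb = dg$rho_ssb$rho, rho_f = dg$rho_f$rho,
      rho_pass = unname(dg$pass["rho"]),
      mase_h1 = dg$mase_h1, mase_pass = unname(dg$pass["mase"]),
      runs_p = dg$runs$p_value, runs_pass = unname(dg$pass["runs"]),
      dm_stat = dg$dm$statistic, dm_p = dg$dm$p_value, nll = fit$nll,
      stringsAsFactors = FALSE)
  }, error = function(e) {
    empty$error <- conditionMessage(e)
    empty
  })
  res
}

#' Diagnostic-score ensemble weights
#'
#' Discrete plausibility weights from binary diagnostic outcomes: each
#' scenario's raw score is the (diagnostic-weighted) sum of its pass
#' indicators, normalised to sum to one across scenarios.
#'
#' @param pass_matrix logical (or 0/1) matrix, scenarios x diagnostics;
#'   rownames are scenario labels. `NA` counts as a fail.
#' @param diag_weights non-negative per-diagnostic weights (default equal).
#' @return An object of class `ensemble_weights`: data frame `label`,
#'   `score`, `weight`. If every score is zero the weights are uniform,
#'   with a warning.
#' @export
weight_scenarios <- function(pass_matrix,
                             diag_weights = rep(1, ncol(pass_matrix))) {
  pm <- as.matrix(pass_matrix)
  if (ncol(pm) < 1) stop("need >= 1 diagnostic column")
  if (length(diag_weights) != ncol(pm))
    stop("diag_weights must match the diagnostic columns")
  if (any(diag_weights < 0)) stop("diagnostic weights must be >= 0")
  pm[is.na(pm)] <- 0
  score <- as.numeric(pm %*% diag_weights)
  if (sum(score) > 0) {
    w <- score / sum(score)
  } else {
    warning("all scenarios score zero; using uniform weights")
    w <- rep(1 / nrow(pm), nrow(pm))
  }
  out <- data.frame(label = rownames(pm) %||% as.character(seq_len(nrow(pm))),
                    score = score, weight = w, stringsAsFactors = FALSE)
  class(out) <- c("ensemble_weights", "data.frame")
  out
}

#' Kobe quadrant classification
#'
#' Classifies stock status from \eqn{SSB/B_{MSY}} and \eqn{F/F_{MSY}}:
#' green (healthy: SSB ratio > 1 and F ratio < 1), yellow (not overfished
#' but overfishing), orange (overfished, no overfishing), red (overfished
#' and overfishing). Boundary values (ratio exactly 1) are assigned to the
#' non-green quadrant (precautionary convention).
#'
#' @param ssb_ratio,f_ratio positive ratio vectors (recycled).
#' @return factor with levels `green`, `yellow`, `orange`, `red`.
#' @export
#' @examples
#' kobe_classify(1.5, 0.5)  # green
#' kobe_classify(0.5, 1.5)  # red
kobe_classify <- function(ssb_ratio, f_ratio) {
  if (any(ssb_ratio <= 0) || any(f_ratio <= 0))
    stop("ratios must be > 0")
  q <- ifelse(ssb_ratio > 1 & f_ratio < 1, "green",
       ifelse(ssb_ratio > 1, "yellow",
       ifelse(f_ratio > 1, "red", "orange")))
  factor(q, levels = c("green", "yellow", "orange", "red"))
}

#' Weighted Kobe quadrant probabilities
#'
#' Ensemble probability of each Kobe quadrant: the sum of scenario weights
#' falling in the quadrant.
#'
#' @param records data frame with columns `label` and `quadrant` (or
#'   `kobe`).
#' @param weights an [weight_scenarios()] table (columns `label`,
#'   `weight`).
#' @return named numeric vector over the four quadrants, summing to 1.
#' @export
kobe_probabilities <- function(records, weights) {
  qcol <- if ("quadrant" %in% names(records)) "quadrant" else "kobe"
  m <- match(records$label, weights$label)
  if (anyNA(m)) stop("scenario labels do not match the weights table")
  q <- factor(as.character(records[[qcol]]),
              levels = c("green", "yellow", "orange", "red"))
  w <- weights$weight[m]
  p <- tapply(w, q, sum, default = 0)
  p <- p / sum(p)
  stats::setNames(as.numeric(p), levels(q))
}

#' Regression tree over grid factors
#'
#' Recursive binary partitioning of scenarios over categorical factor-level
#' subsets, choosing at each node the split that maximises the reduction in
#' within-node sum of squared errors of the response. A split is accepted
#' only if it reduces total SSE; ties break deterministically by factor
#' declaration order, then by level-subset enumeration order. Built for the
#' small categorical designs of uncertainty grids (every subset of each
#' factor's levels is enumerated exactly).
#'
#' @param grid_factors data frame of factor levels, scenarios x factors.
#' @param response finite numeric response per scenario (e.g. Mohn's rho).
#' @param max_depth maximum depth (root = depth 0; default 3).
#' @param min_leaf minimum scenarios per leaf (default 2).
#' @return An object of class `grid_tree`: nested node lists with fields
#'   `n`, `mean`, `sse`, and for internal nodes `split_factor`,
#'   `left_levels`, `right_levels`, `left`, `right`.
#' @export
regression_tree <- function(grid_factors, response, max_depth = 3,
                            min_leaf = 2) {
  gf <- as.data.frame(grid_factors, stringsAsFactors = FALSE)
  gf[] <- lapply(gf, as.character)
  if (nrow(gf) < 2) stop("need >= 2 scenarios")
  if (length(response) != nrow(gf) || any(!is.finite(response)))
    stop("response must be finite and match the scenarios")
  grow_node(gf, response, depth = 0, max_depth = max_depth,
            min_leaf = min_leaf) |>
    structure(class = "grid_tree")
}

node_sse <- function(y) sum((y - mean(y))^2)

grow_node <- function(gf, y, depth, max_depth, min_leaf) {
  node <- list(n = length(y), mean = mean(y), sse = node_sse(y))
  if (depth >= max_depth || length(y) < 2 * min_leaf) return(node)

  best <- NULL
  for (fac in names(gf)) {
    lev <- unique(gf[[fac]])        # appearance order: deterministic
    k <- length(lev)
    if (k < 2) next
    # enumerate proper non-empty subsets; fix the first level on the left
    # to avoid mirrored duplicates
    for (mask in seq_len(2^(k - 1)) - 1L) {
      left <- lev[c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1) - 1))))]
      if (length(left) == k) next
      inl <- gf[[fac]] %in% left
      if (sum(inl) < min_leaf || sum(!inl) < min_leaf) next
      sse <- node_sse(y[inl]) + node_sse(y[!inl])
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(factor = fac, left = left, right = setdiff(lev, left),
                     inl = inl, sse = sse)
      }
    }
  }
  if (is.null(best) || best$sse >= node$sse - 1e-12) return(node)
  node$split_factor <- best$factor
  node$left_levels <- best$left
  node$right_levels <- best$right
  node$left <- grow_node(gf[best$inl, , drop = FALSE], y[best$inl],
                         depth + 1, max_depth, min_leaf)
  node$right <- grow_node(gf[!best$inl, , drop = FALSE], y[!best$inl],
                          depth + 1, max_depth, min_leaf)
  node
}

#' @export
print.grid_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split_factor)) {
      cat(sprintf("%sleaf: n = %d, mean = %.4g\n", pad, node$n, node$mean))
    } else {
      cat(sprintf("%s%s in {%s} (n = %d, mean = %.4g)\n", pad,
                  node$split_factor,
                  paste(node$left_levels, collapse = ","), node$n,
                  node$mean))
      show(node$left, indent + 1)
      cat(sprintf("%s%s in {%s}\n", pad, node$split_factor,
                  paste(node$right_levels, collapse = ",")))
      show(node$right, indent + 1)
    }
  }
  cat("Regression tree over grid factors\n")
  show(unclass(x), 0)
  invisible(x)
}

#' @export
predict.grid_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  newdata[] <- lapply(newdata, as.character)
  one <- function(node, row) {
    if (is.null(node$split_factor)) return(node$mean)
    if (row[[node$split_factor]] %in% node$left_levels)
      one(node$left, row) else one(node$right, row)
  }
  vapply(seq_len(nrow(newdata)), function(i)
    one(unclass(object), newdata[i, , drop = FALSE]), numeric(1))
}

#' Total SSE of a tree's leaves
#'
#' @param tree a `grid_tree`.
#' @return sum of within-leaf SSE over all leaves.
#' @export
tree_sse <- function(tree) {
  walk <- function(node) {
    if (is.null(node$split_factor)) return(node$sse)
    walk(node$left) + walk(node$right)
  }
  walk(unclass(tree))
}
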