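# Configuration, CSV/JSON/YAML I/O and the end-to-end pipeline:
# simulate -> grid -> evaluate -> weight -> report.

# ---- schema-checked table I/O -------------------------------------------

asm_schemas <- list(
  catch = c("year", "catch"),
  index = c("year", "index", "cv"),
  lencomp = c("year", "bin_lower", "proportion", "n")
)

#' Write a data frame as a CSV payload
#'
#' Numeric columns are serialised with 15 significant digits; no row names,
#' no timestamps, so identical data give byte-identical files.
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  out[] <- lapply(out, fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schema-checked CSV table
#'
#' Validates the header against the expected columns and enforces
#' locale-independent numeric parsing (decimal point only): a value such as
#' `"1,5"` is rejected with a message naming the file, line and column.
#'
#' @param path CSV file.
#' @param columns required column names.
#' @param numeric_cols columns that must parse as numbers (default: all
#'   required columns).
#' @return data frame.
#' @export
read_table <- function(path, columns, numeric_cols = columns) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column '",
         missing_cols[1], "'")
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !raw[[cl]] %in% c("NA", ""))
    if (length(bad))
      stop("schema error in ", path, ", line ", bad[1] + 1L,
           ", column '", cl, "': cannot parse \"", raw[[cl]][bad[1]],
           "\" as a number (decimal point required)")
    raw[[cl]] <- v
  }
  raw
}

#' Write an assessment data set to CSV files
#'
#' Emits `catch.csv`, `index.csv` and `lencomp.csv` under `dir`; the
#' writers round-trip losslessly with [read_assessment_data()].
#'
#' @param data an `assessment_data`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assessment_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(data$catch, file.path(dir, "catch.csv"))
  write_table(data$index, file.path(dir, "index.csv"))
  write_table(data$lencomp, file.path(dir, "lencomp.csv"))
  invisible(dir)
}

#' Read an assessment data set from CSV files
#'
#' @param dir directory containing `catch.csv`, `index.csv`,
#'   `lencomp.csv`.
#' @return an `assessment_data`.
#' @export
read_assessment_data <- function(dir) {
  assessment_data(
    catch = read_table(file.path(dir, "catch.csv"), asm_schemas$catch),
    index = read_table(file.path(dir, "index.csv"), asm_schemas$index),
    lencomp = read_table(file.path(dir, "lencomp.csv"), asm_schemas$lencomp)
  )
}

# ---- operating-model parameter serialisation ----------------------------

#' Write operating-model parameters to JSON
#'
#' @param params an `om_parameters`.
#' @param path output file (.json).
#' @return `path`, invisibly.
#' @export
write_om_parameters <- function(params, path) {
  x <- unclass(params)
  x$selectivity <- list(form = params$selectivity$form,
                        params = as.list(params$selectivity$params))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read operating-model parameters from JSON
#'
#' @param path a file written by [write_om_parameters()].
#' @return an `om_parameters`.
#' @export
read_om_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- selectivity_spec(x$selectivity$form,
                          unlist(x$selectivity$params))
  x$selectivity <- NULL
  do.call(om_parameters, c(x, list(selectivity = sel)))
}

# ---- run configuration --------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles everything one experiment needs: the operating-model parameters
#' (inline or a JSON file path), the grid factor specification, diagnostic
#' settings, the global seed and the output directory.
#'
#' @param om an `om_parameters`, or path to a JSON parameter file
#'   (default: [make_reference_case()]).
#' @param factors named list of factor levels (default:
#'   [default_grid_factors()]`$factors`).
#' @param reference named reference levels.
#' @param n_peels,hind_peels,horizon,alpha,rho_band,mase_threshold
#'   diagnostic settings (see [diagnose()]).
#' @param diag_weights named weights for the default pass diagnostics
#'   (`rho`, `mase`, `runs`).
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(om = NULL, factors = NULL, reference = NULL,
                       n_peels = 3, hind_peels = 5, horizon = 1,
                       alpha = 0.05, rho_band = c(-0.15, 0.2),
                       mase_threshold = 1,
                       diag_weights = c(rho = 1, mase = 1, runs = 1),
                       seed = 1, out_dir = "stockgrid-run") {
  dflt <- default_grid_factors()
  structure(list(
    om = om, factors = factors %||% dflt$factors,
    reference = reference %||%
      (if (is.null(factors)) dflt$reference else NULL),
    n_peels = n_peels, hind_peels = hind_peels, horizon = horizon,
    alpha = alpha, rho_band = rho_band, mase_threshold = mase_threshold,
    diag_weights = diag_weights, seed = seed, out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose fields mirror
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
       else stop("config must be .yaml, .yml or .json")
  x$rho_band <- as.numeric(unlist(x$rho_band %||% c(-0.15, 0.2)))
  if (!is.null(x$diag_weights)) x$diag_weights <- unlist(x$diag_weights)
  if (!is.null(x$factors)) x$factors <- lapply(x$factors, as.character)
  if (!is.null(x$reference)) x$reference <- unlist(x$reference)
  do.call(run_config, x)
}

#' Write a run configuration to JSON
#'
#' @param config a `run_config`; an inline `om_parameters` is embedded.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$diag_weights <- as.list(x$diag_weights)
  if (inherits(x$om, "om_parameters")) {
    om <- unclass(x$om)
    om$selectivity <- list(form = x$om$selectivity$form,
                           params = as.list(x$om$selectivity$params))
    x$om <- om
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# internal: resolve the om field of a config
resolve_om <- function(om) {
  if (is.null(om)) return(make_reference_case())
  if (inherits(om, "om_parameters")) return(om)
  if (is.character(om)) return(read_om_parameters(om))
  if (is.list(om)) {
    sel <- selectivity_spec(om$selectivity$form,
                            unlist(om$selectivity$params))
    om$selectivity <- NULL
    return(do.call(om_parameters, c(om, list(selectivity = sel))))
  }
  stop("cannot interpret the om field of the configuration")
}

# ---- the pipeline -------------------------------------------------------

#' Run the end-to-end validation pipeline
#'
#' Chains the whole experiment: simulate data from the operating model,
#' build the factorial grid, evaluate every scenario (fit, reference
#' points, diagnostics), weight scenarios by their diagnostic passes,
#' classify Kobe status with weighted quadrant probabilities, and grow the
#' factor-importance regression tree on Mohn's rho. Writes `catch.csv`,
#' `index.csv`, `lencomp.csv`, `om.json`, `grid.csv`, `diagnostics.csv`,
#' `refpts.csv`, `weights.csv`, `kobe.csv`, `tree.json` and `manifest.json`
#' to the output directory. Identical configuration and seed give
#' byte-identical payload files.
#'
#' @param config a `run_config`, or path to a YAML/JSON configuration.
#' @param out_dir optional override of `config$out_dir`.
#' @param cache optional environment reused across calls (see
#'   [evaluate_grid()]).
#' @param verbose print progress.
#' @return invisibly, a list with `data`, `grid`, `results`, `weights`,
#'   `kobe`, `tree`, `out_dir`, `n_failed`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cache = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("invalid configuration")
  out <- out_dir %||% config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  params <- resolve_om(config$om)
  sim <- simulate_assessment_data(params, seed = config$seed)
  write_assessment_data(sim$data, out)
  write_om_parameters(params, file.path(out, "om.json"))

  grid <- build_grid(config$factors, config$reference)
  st <- config[c("n_peels", "hind_peels", "horizon", "alpha", "rho_band",
                 "mase_threshold")]
  results <- evaluate_grid(sim$data, grid, settings = st, base = params,
                           cache = cache, verbose = verbose)

  conv <- results[results$converged %in% TRUE, , drop = FALSE]
  pm <- cbind(rho = conv$rho_pass, mase = conv$mase_pass,
              runs = conv$runs_pass)
  rownames(pm) <- conv$label
  dw <- config$diag_weights[colnames(pm)]
  weights <- if (nrow(conv)) weight_scenarios(pm, dw) else
    data.frame(label = character(), score = numeric(), weight = numeric())

  kobe <- conv[, c("label", "ssb_ratio", "f_ratio", "kobe")]
  names(kobe)[4] <- "quadrant"
  kobe_p <- if (nrow(kobe)) kobe_probabilities(kobe, weights) else
    stats::setNames(rep(NA_real_, 4), c("green", "yellow", "orange", "red"))

  tree <- if (nrow(conv) >= 2)
    regression_tree(conv[, names(grid$factors), drop = FALSE],
                    conv$rho_ssb) else NULL

  fac_cols <- names(grid$factors)
  write_table(results[, c("label", fac_cols, "converged", "error", "ssb0",
                          "terminal_ssb", "terminal_f", "ssb_ratio",
                          "f_ratio", "kobe", "nll")],
              file.path(out, "grid.csv"))
  write_table(results[, c("label", "rho_ssb", "rho_f", "rho_pass",
                          "mase_h1", "mase_pass", "runs_p", "runs_pass",
                          "dm_stat", "dm_p")],
              file.path(out, "diagnostics.csv"))
  write_table(results[, c("label", "msy", "f_msy", "b_msy", "ssb0", "k")],
              file.path(out, "refpts.csv"))
  write_table(weights, file.path(out, "weights.csv"))
  kobe_out <- rbind(
    cbind(kobe, weight = weights$weight[match(kobe$label, weights$label)]))
  write_table(kobe_out, file.path(out, "kobe.csv"))
  jsonlite::write_json(
    list(response = "rho_ssb", probabilities = as.list(kobe_p),
         tree = tree_to_list(tree)),
    file.path(out, "tree.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest <- unclass(config)
  manifest$diag_weights <- as.list(config$diag_weights)
  manifest$om <- unclass(params)
  manifest$om$selectivity <- list(form = params$selectivity$form,
                                  params = as.list(params$selectivity$params))
  manifest$package_version <- as.character(utils::packageVersion("stockgrid"))
  manifest$n_scenarios <- grid$n
  manifest$n_failed <- sum(!results$converged %in% TRUE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = sim$data, grid = grid, results = results,
                 weights = weights, kobe = kobe, kobe_probabilities = kobe_p,
                 tree = tree, out_dir = out,
                 n_failed = manifest$n_failed))
}

# internal: tree -> plain nested list for JSON
tree_to_list <- function(node) {
  if (is.null(node)) return(NULL)
  node <- unclass(node)
  out <- list(n = node$n, mean = node$mean, sse = node$sse)
  if (!is.null(node$split_factor)) {
    out$split_factor <- node$split_factor
    out$left_levels <- as.list(node$left_levels)
    out$right_levels <- as.list(node$right_levels)
    out$left <- tree_to_list(node$left)
    out$right <- tree_to_list(node$right)
  }
  out
}

#' Replay a pipeline run from its manifest
#'
#' Re-runs [run_pipeline()] from the machine-readable manifest written by a
#' previous run; with the recorded seed this reproduces the payload files
#' byte for byte.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the replay.
#' @return as [run_pipeline()].
#' @export
replay_pipeline <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- run_config(
    om = m$om, factors = lapply(m$factors, as.character),
    reference = unlist(m$reference), n_peels = m$n_peels,
    hind_peels = m$hind_peels, horizon = m$horizon, alpha = m$alpha,
    rho_band = as.numeric(m$rho_band),
    mase_threshold = m$mase_threshold,
    diag_weights = unlist(m$diag_weights), seed = m$seed,
    out_dir = out_dir)
  run_pipeline(cfg)
}
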