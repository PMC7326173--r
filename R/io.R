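#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON file describing a complete run: the economic
#' parameters, the Moran-process settings, and the simulation settings.
#' Keys may be given flat or nested under `econ`, `moran` and `simulate`
#' sections; unspecified settings are filled with documented defaults and
#' the names of defaulted fields are recorded so every run can state its
#' full provenance. Validation is performed up front and names the
#' offending field.
#'
#' Recognised keys: the [econ_params()] fields (`T` is accepted as an alias
#' for `T_incentive`); `u`, `fitness_map`, `fitness_floor` (Moran);
#' `mutation_rate`, `replicates`, `max_steps`, `start`, `thin`, `seed`
#' (simulation).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `scenario`: `econ` (an `econ_params`), `moran`
#'   and `simulate` setting lists, `defaulted` (character vector of filled
#'   fields) and `source`.
#' @examples
#' sc <- load_scenario(scenario_preset())
#' sc$econ$N
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !is.list(raw) || !length(raw))
    stop("config file is empty or not a mapping: ", path, call. = FALSE)

  flat <- raw
  for (sect in c("econ", "moran", "simulate"))
    if (!is.null(raw[[sect]]) && is.list(raw[[sect]])) {
      flat <- c(flat[setdiff(names(flat), sect)], raw[[sect]])
    }
  if (!is.null(flat$T) && is.null(flat$T_incentive)) flat$T_incentive <- flat$T
  # YAML 1.1 resolves an unquoted key `N` to a boolean; recover it
  if (is.null(flat$N) && !is.null(flat[["FALSE"]])) flat$N <- flat[["FALSE"]]

  econ_fields <- c("N", "C1", "a", "b", "R", "R_star", "C", "P_success",
                   "T_incentive", "mu", "r", "t1", "t2")
  missing_fields <- setdiff(setdiff(econ_fields, "mu"), names(flat))
  if (length(missing_fields))
    stop("config missing required field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  econ <- do.call(econ_params, flat[intersect(econ_fields, names(flat))])

  defaults <- list(u = 0.5, fitness_map = "linear", fitness_floor = 1e-9,
                   mutation_rate = 0.01, replicates = 1000, max_steps = 1e6,
                   start = 1, thin = econ$N, seed = NULL)
  defaulted <- character(0)
  take <- function(key) {
    if (!is.null(flat[[key]])) flat[[key]]
    else {
      defaulted <<- c(defaulted, key)
      defaults[[key]]
    }
  }
  moran <- list(u = take("u"), fitness_map = take("fitness_map"),
                fitness_floor = take("fitness_floor"))
  if (!is.numeric(moran$u) || moran$u < 0 || moran$u >= 1)
    stop("invalid parameter `u`: must satisfy 0 <= u < 1", call. = FALSE)
  if (!moran$fitness_map %in% c("linear", "exponential"))
    stop("invalid parameter `fitness_map`: must be \"linear\" or \"exponential\"",
         call. = FALSE)
  sim <- list(mutation_rate = take("mutation_rate"),
              replicates = take("replicates"), max_steps = take("max_steps"),
              start = take("start"), thin = take("thin"))
  sim$seed <- if (!is.null(flat$seed)) flat$seed else {
    defaulted <- c(defaulted, "seed"); NULL
  }
  if (sim$mutation_rate < 0 || sim$mutation_rate >= 1)
    stop("invalid parameter `mutation_rate`: must be in [0, 1)", call. = FALSE)

  structure(list(econ = econ, moran = moran, simulate = sim,
                 defaulted = defaulted, source = normalizePath(path)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$source, "\n")
  print(x$econ)
  cat(sprintf("  Moran: u = %g, %s fitness (floor %g); mutation %g\n",
              x$moran$u, x$moran$fitness_map, x$moran$fitness_floor,
              x$simulate$mutation_rate))
  if (length(x$defaulted))
    cat("  defaulted fields:", paste(x$defaulted, collapse = ", "), "\n")
  invisible(x)
}

#' Path to the bundled baseline scenario
#'
#' The published simulation scenario of the model (`N = 100`, `C1 = 2`,
#' `a = 0.4`, `b = 0.7`, `R = 1000`, `C = 100`, `P(C) = 0.4`, `r = 0.015`,
#' `t1 = 100`, `t2 = 300`, `R* = 100`, mutation rate 0.01). Note this
#' scenario itself violates the `R = N * R_star` identity the model text
#' posits, so loading it emits exactly one warning.
#'
#' @return File path of the bundled YAML preset.
#' @export
scenario_preset <- function() {
  system.file("extdata", "baseline_scenario.yaml", package = "greengame",
              mustWork = TRUE)
}

#' Serialize a result object
#'
#' JSON output (via jsonlite, full numeric precision so numeric fields
#' round-trip losslessly) for any result object; CSV output for tabular
#' results (sweep grids, ensemble outcomes, fixation vectors).
#'
#' @param x a result object (`fixation_result`, `sweep_result`,
#'   `trajectory_ensemble`, `reward_breakdown`, or any list/data frame).
#' @param path output file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    df <- if (inherits(x, "sweep_result")) x$grid
      else if (inherits(x, "trajectory_ensemble")) x$outcomes
      else if (inherits(x, "fixation_result"))
        data.frame(i = seq_along(x$F) - 1L, F = x$F)
      else if (is.data.frame(x)) x
      else stop("no CSV representation for class ",
                paste(class(x), collapse = "/"), call. = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    payload <- if (inherits(x, "trajectory_ensemble")) {
      x$paths <- NULL
      unclass(x)
    } else if (is.list(x)) unclass(x) else x
    # 17 significant digits guarantee a lossless double round-trip
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", force = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
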