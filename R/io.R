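#' Write a trajectory to CSV
#'
#' Fixed column order \code{t,S,P,B,C,z}, full float precision (17
#' significant digits), so the file parses back to the in-memory trajectory
#' within float round-trip precision.
#'
#' @param traj a \code{"bmu_trajectory"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV file with columns \code{t,S,P,B,C,z}.
#' @return \code{data.frame} with those columns.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "S", "P", "B", "C", "z")
  if (!identical(names(df), need))
    stop_validation("trajectory CSV must have columns %s",
                    paste(need, collapse = ","))
  df
}

#' Write a remodeling summary to JSON
#'
#' @param summary a \code{"bmu_summary"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(summary, path) {
  x <- list(zbar = summary$zbar,
            duration_days = summary$duration_days,
            peaks = summary$peaks,
            classification = summary$classification,
            converged = summary$converged,
            solver_meta = summary$solver_meta[c("method", "rtol", "atol",
                                                "dt_out", "horizon",
                                                "termination")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- configuration -------------------------------------------------------

.solver_keys <- c("horizon", "rtol", "atol", "dt_out")
.init_keys <- c("sigma", "z0")

#' Default run configuration
#'
#' The configuration equivalent of an empty config file: baseline
#' parameters, the default initial osteocyte deficit, and default solver
#' settings.
#'
#' @return A \code{"run_config"}: list with \code{params}, \code{init},
#'   \code{solver} (horizon, rtol, atol, dt_out), \code{schedule} and
#'   \code{sweep} (both \code{NULL} unless configured).
#' @export
default_config <- function() {
  structure(list(
    params = remodeling_params(),
    init = initial_condition(),
    solver = list(horizon = 300, rtol = 1e-8, atol = 1e-10, dt_out = 0.1),
    schedule = NULL,
    sweep = NULL
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' The config is flat YAML: any model parameter by its symbol
#' (\code{alpha1} ... \code{epsilon}), the initial condition
#' (\code{sigma}, \code{z0}) and solver settings (\code{horizon},
#' \code{rtol}, \code{atol}, \code{dt_out}) at top level, plus optional
#' blocks \code{disease} (name: value map), \code{schedule} (list of
#' \code{{parameter, start, end, value}}) and \code{sweep}
#' (\code{param_x}, \code{values_x}, optionally \code{param_y},
#' \code{values_y}). Unknown keys are rejected by name; every omitted key
#' falls back to the baseline default. An empty file yields
#' [default_config()].
#'
#' @param path YAML file path.
#' @return A validated \code{"run_config"} (see [default_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_validation("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop_validation("config must be a YAML mapping")
  known <- c(names(.param_defaults), .init_keys, .solver_keys,
             "disease", "schedule", "sweep")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  scalar_keys <- intersect(names(raw),
                           c(names(.param_defaults), .init_keys, .solver_keys))
  for (k in scalar_keys)
    if (!is.numeric(raw[[k]]) || length(raw[[k]]) != 1L)
      stop_validation("config key %s must be a single number", k)
  cfg <- default_config()
  pov <- raw[intersect(names(raw), names(.param_defaults))]
  if (length(pov))
    cfg$params <- do.call(remodeling_params, c(lapply(pov, as.numeric)))
  cfg$init <- initial_condition(
    sigma = if (!is.null(raw$sigma)) raw$sigma else 20,
    z0 = if (!is.null(raw$z0)) raw$z0 else 100)
  for (k in intersect(names(raw), .solver_keys))
    cfg$solver[[k]] <- as.numeric(raw[[k]])
  if (cfg$solver$horizon <= 0 || cfg$solver$rtol <= 0 ||
      cfg$solver$atol <= 0 || cfg$solver$dt_out <= 0)
    stop_validation("solver settings must be positive (horizon, rtol, atol, dt_out)")
  windows <- lapply(raw$schedule, function(w) {
    need <- c("parameter", "start", "end", "value")
    if (!is.list(w) || !all(need %in% names(w)))
      stop_validation("each schedule entry needs keys: %s",
                      paste(need, collapse = ", "))
    dose_window(w$parameter, w$start, w$end, w$value)
  })
  disease <- raw$disease
  if (length(windows) || length(disease))
    cfg$schedule <- treatment_schedule(windows = windows,
                                       disease = as.list(disease))
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    if (!is.list(sw) || is.null(sw$param_x) || is.null(sw$values_x))
      stop_validation("sweep block needs param_x and values_x")
    for (nm in c(sw$param_x, sw$param_y))
      if (!nm %in% names(.param_defaults))
        stop_validation("unknown parameter in sweep block: %s", nm)
    cfg$sweep <- list(param_x = sw$param_x,
                      values_x = as.numeric(unlist(sw$values_x)),
                      param_y = sw$param_y,
                      values_y = if (is.null(sw$values_y)) NULL
                                 else as.numeric(unlist(sw$values_y)))
  }
  cfg
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: \code{load_config(write_config(cfg, f))}
#' reproduces an identical validated object.
#'
#' @param config a \code{"run_config"}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  out <- as.list(unclass(config$params))
  out$sigma <- config$init$sigma
  out$z0 <- config$init$z0
  out <- c(out, config$solver)
  if (!is.null(config$schedule)) {
    if (length(config$schedule$disease))
      out$disease <- config$schedule$disease
    if (length(config$schedule$windows))
      out$schedule <- lapply(config$schedule$windows, function(w)
        list(parameter = w$parameter, start = w$start, end = w$end,
             value = w$value))
  }
  if (!is.null(config$sweep))
    out$sweep <- config$sweep[!vapply(config$sweep, is.null, TRUE)]
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

# Short deterministic fingerprint of a config, for audit logging.
config_fingerprint <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2L))
  acc <- 0
  for (b in bytes) acc <- (acc * 31 + b) %% 2147483647
  sprintf("%08x", acc)
}
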