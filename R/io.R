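# Configuration loading and trajectory serialization.

#' Write a trajectory to a CSV file
#'
#' One row per saved time point, header
#' `time,csc,ctac,mtc,helper,killer,regulator`, values at full double
#' precision (17 significant digits, round-trip exact). A YAML sidecar
#' `<path>.yaml` stores the parameter snapshot and simulation settings so
#' the run can be replayed exactly.
#'
#' @param traj An `hl_trajectory` (non-empty).
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar?
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  if (!is.data.frame(traj) || nrow(traj) == 0)
    stop("empty trajectory", call. = FALSE)
  cols <- c("time", "csc", "ctac", "mtc", "helper", "killer", "regulator")
  stopifnot(all(cols %in% names(traj)))
  body <- do.call(paste, c(lapply(traj[cols], function(x)
    sprintf("%.17g", x)), sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path)
  if (sidecar) {
    params <- attr(traj, "params")
    settings <- attr(traj, "settings")
    meta <- list(
      parameters = if (!is.null(params)) as.list(unclass(params)),
      settings = if (!is.null(settings)) unclass(settings)
    )
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' If the metadata sidecar is present the parameter snapshot and settings
#' are restored as attributes.
#'
#' @param path CSV path.
#' @return An `hl_trajectory`.
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path, colClasses = "numeric")
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$parameters)) {
      p <- unlist(meta$parameters)
      class(p) <- "hl_params"
      validate_parameters(p)
      attr(traj, "params") <- p
    }
    if (!is.null(meta$settings))
      attr(traj, "settings") <- do.call(sim_settings, meta$settings)
  }
  class(traj) <- c("hl_trajectory", "data.frame")
  traj
}

#' Load a run configuration
#'
#' The configuration is a YAML mapping with optional fields:
#' * `scenario` — a registered scenario name;
#' * `overrides` — named parameter overrides (canonical keys or display
#'   names), applied after the scenario's own overrides;
#' * `settings` — any of `final_time` (alias `horizon`), `dt`, `saveper`,
#'   `initial_time`;
#' * `output` — default output path for the trajectory.
#'
#' Supplying both a scenario and a complete inline parameter set is
#' rejected as contradictory; unknown parameter names are rejected with a
#' nearest-match suggestion.
#'
#' @param path YAML file path.
#' @return A list of class `hl_config`: `params`, `settings`, `scenario`,
#'   `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("scenario", "overrides", "settings", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         "; expected ", paste(known, collapse = ", "), call. = FALSE)
  ov <- cfg$overrides
  n_all <- nrow(param_table())
  if (!is.null(cfg$scenario) && length(ov) >= n_all)
    stop("config gives both a scenario and a full inline parameter set; ",
         "use one or the other", call. = FALSE)

  set <- cfg$settings
  if (!is.null(set$horizon)) { set$final_time <- set$horizon; set$horizon <- NULL }
  bad <- setdiff(names(set),
                 c("final_time", "dt", "saveper", "initial_time"))
  if (length(bad))
    stop("unknown settings field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  if (!is.null(cfg$scenario)) {
    sc <- do.call(get_scenario, c(list(cfg$scenario), as.list(ov)))
    params <- sc$params
    settings <- sc$settings
    if (length(set)) settings <- do.call(sim_settings, modifyList(
      unclass(settings), set))
  } else {
    params <- default_parameters(overrides = ov)
    settings <- do.call(sim_settings, if (length(set)) set else list())
  }
  structure(list(params = params, settings = settings,
                 scenario = cfg$scenario, output = cfg$output),
            class = "hl_config")
}
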