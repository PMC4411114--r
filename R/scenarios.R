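# Scenario registry: named presets reproducing the published experiments.
# The registry itself is data (inst/extdata/scenarios.yaml), kept in the
# display-name spelling so presets can be diffed against figure legends.

.scenario_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "scenarios.yaml", package = "hlsim")
      if (path == "") stop("scenario manifest not found", call. = FALSE)
      man <- yaml::read_yaml(path)$scenarios
      names(man) <- vapply(man, `[[`, "", "name")
      cache <<- man
    }
    cache
  }
})

#' List registered scenarios
#'
#' @return Data frame with columns `name`, `horizon`, `n_overrides`,
#'   `requires`, `description`.
#' @export
#' @examples
#' list_scenarios()[, c("name", "horizon")]
list_scenarios <- function() {
  man <- .scenario_registry()
  data.frame(
    name = vapply(man, `[[`, "", "name"),
    horizon = vapply(man, function(s) as.numeric(s$horizon), 0),
    n_overrides = vapply(man, function(s) length(s$overrides), 0L),
    requires = vapply(man, function(s)
      paste(unlist(s$requires), collapse = ", "), ""),
    description = vapply(man, `[[`, "", "description"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Retrieve a scenario preset
#'
#' Returns the default parameter set with the scenario's overrides applied,
#' plus matching simulation settings. Scenarios whose legend leaves a value
#' open (`requires` in the manifest) must have it supplied through `...`.
#'
#' @param name Scenario name (see [list_scenarios()]).
#' @param ... Additional named overrides (canonical keys or display names);
#'   applied after the scenario's own overrides.
#' @param dt,saveper Passed to [sim_settings()].
#' @return A list with elements `params` (`hl_params`), `settings`
#'   (`hl_settings`), `name` and `description`.
#' @export
#' @examples
#' sc <- get_scenario("fig4_default")
#' sc$settings$final_time
get_scenario <- function(name, ..., dt = 0.007812, saveper = 1) {
  man <- .scenario_registry()
  if (!name %in% names(man))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(man), collapse = ", "), call. = FALSE)
  sc <- man[[name]]
  extra <- list(...)
  req <- unlist(sc$requires)
  if (length(req)) {
    have <- if (length(extra)) normalize_param_key(names(extra)) else character()
    missing <- setdiff(normalize_param_key(req), have)
    if (length(missing))
      stop("scenario '", name, "' requires value(s) for: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- default_parameters()
  if (length(sc$overrides)) params <- apply_overrides(params, sc$overrides)
  if (length(extra)) params <- apply_overrides(params, extra)
  list(params = params,
       settings = sim_settings(final_time = as.numeric(sc$horizon),
                               dt = dt, saveper = saveper),
       name = sc$name, description = sc$description)
}

#' Run a registered scenario
#'
#' Convenience wrapper: [get_scenario()] followed by [simulate_model()].
#'
#' @inheritParams get_scenario
#' @return An `hl_trajectory`.
#' @export
run_scenario <- function(name, ..., dt = 0.007812, saveper = 1) {
  sc <- get_scenario(name, ..., dt = dt, saveper = saveper)
  simulate_model(sc$params, sc$settings)
}
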