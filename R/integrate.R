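# Integrator: fixed-step Euler under the published update semantics.

#' Simulation settings
#'
#' @param final_time Horizon in days (published runs use 2000 or 4000).
#' @param dt Euler time step in days. The default 0.007812 is the published
#'   step; the nearby power of two 2^-7 = 0.0078125 gives indistinguishable
#'   results except in the knife-edge amplification experiments (see the
#'   methods vignette) and makes every saved day an exact step time.
#' @param saveper Sampling interval for recorded states (days); must be
#'   `>= dt`.
#' @param initial_time Start time (days).
#' @return A list of class `hl_settings`.
#' @export
sim_settings <- function(final_time = 2000, dt = 0.007812, saveper = 1,
                         initial_time = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(saveper) || saveper < dt)
    stop("saveper must be >= dt", call. = FALSE)
  if (!is.finite(final_time) || final_time <= initial_time)
    stop("final_time must exceed initial_time", call. = FALSE)
  structure(list(initial_time = initial_time, final_time = final_time,
                 dt = dt, saveper = saveper),
            class = "hl_settings")
}

#' Advance the state by one Euler step
#'
#' All flows are evaluated once from the state at time `t`; the six stocks
#' then update simultaneously as `stock + dt * net_change(...)`. The
#' adoptive-transfer influx enters the killer-cell update as the additive
#' term of [net_change()]. This is the reference (interpreted) step; full
#' simulations use a compiled loop with identical arithmetic.
#'
#' @param state An `hl_state`.
#' @param params An `hl_params`.
#' @param t Time at the start of the step (days).
#' @param dt Step length (days).
#' @return The state at `t + dt` (class `hl_state`).
#' @export
euler_step <- function(state, params, t, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (any(!is.finite(unclass(state))))
    stop("non-finite state entering euler_step: ",
         paste(names(state)[!is.finite(unclass(state))], collapse = ", "),
         call. = FALSE)
  f <- compute_flows(state, params, t)
  d <- c(
    csc = net_change(state[["csc"]], f[["csc_prol"]], f[["csc_loss"]]),
    ctac = net_change(state[["ctac"]], f[["ctac_incr"]], f[["ctac_loss"]]),
    mtc = net_change(state[["mtc"]], f[["mtc_incr"]], f[["mtc_loss"]]),
    helper = net_change(state[["helper"]], f[["helper_prol"]], f[["helper_loss"]]),
    killer = net_change(state[["killer"]], f[["killer_prol"]], f[["killer_loss"]],
                        additive = f[["immuno1_rate"]]),
    regulator = net_change(state[["regulator"]], f[["regulator_prol"]],
                           f[["regulator_loss"]])
  )
  out <- unclass(state) + dt * d
  class(out) <- "hl_state"
  out
}

#' Simulate the model
#'
#' Runs the fixed-step Euler integration from `initial_time` to
#' `final_time`, recording the state at every multiple of `saveper` (each
#' recorded point is the step whose time is closest to the save point from
#' below; with the default step 2^-7 every integer day is hit exactly).
#' Identical inputs give bit-identical trajectories.
#'
#' @param params An `hl_params` parameter set (see [default_parameters()]).
#' @param settings An `hl_settings` object (see [sim_settings()]).
#' @return An `hl_trajectory`: a data frame with columns `time`, `csc`,
#'   `ctac`, `mtc`, `helper`, `killer`, `regulator`, carrying the parameter
#'   set and settings as attributes `params` and `settings`.
#' @export
#' @examples
#' traj <- simulate_model(default_parameters(), sim_settings(final_time = 50))
#' tail(traj, 3)
simulate_model <- function(params = default_parameters(),
                           settings = sim_settings()) {
  stopifnot(inherits(settings, "hl_settings"))
  validate_parameters(params)
  m <- sim_euler_cpp(unclass(params),
                     settings$initial_time, settings$final_time,
                     settings$dt, settings$saveper)
  traj <- as.data.frame(m)
  attr(traj, "params") <- params
  attr(traj, "settings") <- settings
  class(traj) <- c("hl_trajectory", "data.frame")
  traj
}

#' @export
print.hl_trajectory <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<hl_trajectory> %d saved states, t = %g..%g (dt = %g)\n",
              nrow(x), s$initial_time, s$final_time, s$dt))
  fin <- x[nrow(x), ]
  cat(sprintf("final burden (csc+ctac+mtc): %.6g cells\n",
              fin$csc + fin$ctac + fin$mtc))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Stock counts against time for all six compartments, optionally on a log
#' scale (counts below `floor` are clipped for display only).
#'
#' @param x An `hl_trajectory`.
#' @param log Use a logarithmic y axis?
#' @param floor Display floor for the log scale.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.hl_trajectory <- function(x, log = TRUE, floor = 1e-2, ...) {
  y <- as.matrix(x[, c("csc", "ctac", "mtc", "helper", "killer", "regulator")])
  if (log) y <- pmax(y, floor)
  cols <- grDevices::hcl.colors(6, "Dark 3")
  graphics::matplot(x$time, y, type = "l", lty = 1, col = cols,
                    xlab = "time (days)", ylab = "cells",
                    log = if (log) "y" else "", ...)
  graphics::legend("topleft", legend = colnames(y), col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
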