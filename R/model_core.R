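# Model core: state vector, pulse semantics, flow equations, guarded update.

.STOCKS <- c("csc", "ctac", "mtc", "helper", "killer", "regulator")

#' Construct a state vector
#'
#' The model state at one time point: cell counts of the six stocks —
#' cancer stem cells (csc), cancer transit amplifying cells (ctac), mature
#' tumor cells (mtc), helper cells, killer cells and regulatory cells.
#'
#' @param csc,ctac,mtc,helper,killer,regulator Non-negative cell counts.
#' @return Named numeric vector of length 6, class `hl_state`.
#' @export
#' @examples
#' state_vector()            # the default initial state (10 cells each)
#' state_vector(csc = 0)
state_vector <- function(csc = 10, ctac = 10, mtc = 10,
                         helper = 10, killer = 10, regulator = 10) {
  s <- c(csc = csc, ctac = ctac, mtc = mtc,
         helper = helper, killer = killer, regulator = regulator)
  if (any(!is.finite(s))) stop("non-finite state value", call. = FALSE)
  if (any(s < 0)) stop("state values must be >= 0", call. = FALSE)
  class(s) <- "hl_state"
  s
}

#' Rectangular pulse indicator
#'
#' Returns 1 on the half-open window `[start, start + duration)` and 0
#' elsewhere. The half-open convention makes `duration = 1` deliver exactly
#' one day of effect; `duration = 0` is never active.
#'
#' @param t Time (days); vectorised.
#' @param start Window start (days).
#' @param duration Window length (days), `>= 0`.
#' @return 0/1 indicator, same length as `t`.
#' @export
#' @examples
#' pulse(c(399, 400, 499, 500), 400, 100)
pulse <- function(t, start, duration) {
  if (duration < 0) stop("pulse duration must be >= 0", call. = FALSE)
  as.numeric(t >= start & t < start + duration)
}

#' Therapy rate from a pulse schedule
#'
#' The instantaneous per-day therapy rate: `pulse(t, start, duration) *
#' intensity`. Intensity may be negative (an influx of cells rather than a
#' kill rate).
#'
#' @param t Time (days).
#' @param start,duration,intensity Schedule fields.
#' @return Per-day rate.
#' @export
therapy_rate <- function(t, start, duration, intensity) {
  pulse(t, start, duration) * intensity
}

#' Tumor-derived stimulation of a bystander compartment
#'
#' Weighted sum of the three tumor stocks. The killer-cell variant of the
#' model clamps this at zero (`clamp = TRUE`); the helper and regulator
#' variants do not.
#'
#' @param state An `hl_state` (or named vector with csc/ctac/mtc entries).
#' @param w_csc,w_ctac,w_mtc Per-cell stimulation couplings (1/cells/day).
#' @param clamp Apply `max(0, .)`?
#' @return Per-day stimulation rate.
#' @export
#' @examples
#' stimulus(state_vector(), 0.001, 0.001, 0.001)       # 0.03
#' stimulus(state_vector(), 1e-4, 1e-4, 0.02, clamp = TRUE)  # 0.202
stimulus <- function(state, w_csc, w_ctac, w_mtc, clamp = FALSE) {
  s <- (state[["csc"]] * w_csc) + (w_ctac * state[["ctac"]]) +
    (state[["mtc"]] * w_mtc)
  if (clamp) max(0, s) else s
}

#' Evaluate all model flows at one time point
#'
#' Evaluates every auxiliary quantity of the model at `(state, params, t)`:
#' proliferation/increase and loss rates of the six stocks, tumor-derived
#' stimulation of each bystander compartment, the active per-day therapy
#' rates of the six cytotoxic pulse schedules, the adoptive-transfer influx
#' (`immuno1_rate`, cells/day) and the killing-amplification factors
#' (`immuno2_*_factor`, dimensionless; they enter the killing terms as the
#' multiplier `1 + factor`).
#'
#' Loss terms wrap the balance of death, killing and helper-derived
#' anti-apoptotic rescue in `max(0, .)` before adding differentiation and
#' therapy, so helper cells can cancel death/killing but never turn a loss
#' flow into a gain. Bystander proliferation is gated: it is zero whenever
#' the compartment's activation product (stock x stimulation, for killers
#' additionally x helper help) is not strictly positive.
#'
#' @param state An `hl_state`.
#' @param params An `hl_params` parameter set.
#' @param t Time (days).
#' @return Named numeric vector of flow values (class `hl_flows`).
#' @export
compute_flows <- function(state, params, t) {
  p <- as.list(unclass(params))
  csc <- state[["csc"]]; ctac <- state[["ctac"]]; mtc <- state[["mtc"]]
  helper <- state[["helper"]]; killer <- state[["killer"]]
  regulator <- state[["regulator"]]

  csc_thx_rate <- therapy_rate(t, p$csc_thx_time, p$csc_thx_dur, p$csc_thx_intens)
  ctac_thx_rate <- therapy_rate(t, p$ctac_thx_time, p$ctac_thx_dur, p$ctac_thx_intens)
  mtc_thx_rate <- therapy_rate(t, p$mtc_thx_time, p$mtc_thx_dur, p$mtc_thx_intens)
  helper_thx_rate <- therapy_rate(t, p$helper_thx_time, p$helper_thx_dur, p$helper_thx_intens)
  killer_thx_rate <- therapy_rate(t, p$killer_thx_time, p$killer_thx_dur, p$killer_thx_intens)
  regulator_thx_rate <- therapy_rate(t, p$regulator_thx_time, p$regulator_thx_dur, p$regulator_thx_intens)
  immuno1_rate <- therapy_rate(t, p$immuno1_time, p$immuno1_dur, p$immuno1_intens)
  i2csc <- therapy_rate(t, p$immuno2_csc_time, p$immuno2_csc_dur, p$immuno2_csc_intens)
  i2ctac <- therapy_rate(t, p$immuno2_ctac_time, p$immuno2_ctac_dur, p$immuno2_ctac_intens)
  i2mtc <- therapy_rate(t, p$immuno2_mtc_time, p$immuno2_mtc_dur, p$immuno2_mtc_intens)

  csc_prol <- max(0, (p$csc_growth * csc) - (csc * csc * p$csc_cap))
  csc_loss <- (max(0, (csc * p$csc_death) +
                     ((1 + i2csc) * p$kill_of_csc * killer) -
                     (helper * p$help_for_csc)) +
               (csc * p$csc_diff)) + (csc * csc_thx_rate)

  ctac_incr <- max(0, (p$csc_diff * csc) + (p$ctac_growth * ctac) -
                     (p$ctac_cap * ctac * ctac))
  ctac_loss <- (max(0, (killer * p$kill_of_ctac * (1 + i2ctac)) +
                      (p$ctac_death * ctac) -
                      (helper * p$help_for_ctac)) +
                (p$ctac_diff * ctac)) + (ctac_thx_rate * ctac)

  mtc_incr <- max(0, (p$mtc_growth * mtc) + (p$ctac_diff * ctac) -
                    (p$mtc_cap * mtc * mtc))
  mtc_loss <- max(0, (killer * p$kill_of_mtc * (1 + i2mtc)) +
                    (p$mtc_death * mtc) -
                    (helper * p$help_for_mtc)) + (mtc_thx_rate * mtc)

  helper_stim <- stimulus(state, p$helper_stim_by_csc, p$helper_stim_by_ctac,
                          p$helper_stim_by_mtc)
  helper_prol <- if (helper * helper_stim > 0)
    max(0, (helper_stim * helper) - (helper * helper * p$helper_cap) -
          (p$regulation_of_helper * regulator)) else 0
  helper_loss <- (helper * p$helper_death) + (helper * helper_thx_rate)

  killer_stim <- stimulus(state, p$killer_stim_by_csc, p$killer_stim_by_ctac,
                          p$killer_stim_by_mtc, clamp = TRUE)
  killer_prol <- if (killer * killer_stim * p$help_for_killer * helper > 0)
    max(0, (killer * killer_stim) - (p$regulation_of_killer * regulator) +
          (helper * p$help_for_killer) - (killer * killer * p$killer_cap)) else 0
  killer_loss <- (killer * p$killer_death) + (killer_thx_rate * killer)

  regulator_stim <- stimulus(state, p$regulator_stim_by_csc,
                             p$regulator_stim_by_ctac, p$regulator_stim_by_mtc)
  regulator_prol <- if (regulator * regulator_stim > 0)
    max(0, (regulator * regulator_stim) -
          (regulator * regulator * p$regulator_cap)) else 0
  regulator_loss <- (regulator * p$regulator_death) +
    (regulator_thx_rate * regulator)

  f <- c(csc_prol = csc_prol, csc_loss = csc_loss,
         ctac_incr = ctac_incr, ctac_loss = ctac_loss,
         mtc_incr = mtc_incr, mtc_loss = mtc_loss,
         helper_prol = helper_prol, helper_loss = helper_loss,
         killer_prol = killer_prol, killer_loss = killer_loss,
         regulator_prol = regulator_prol, regulator_loss = regulator_loss,
         helper_stim_by_tumor = helper_stim,
         killer_stim_by_tumor = killer_stim,
         regulator_stim_by_tumor = regulator_stim,
         csc_thx_rate = csc_thx_rate, ctac_thx_rate = ctac_thx_rate,
         mtc_thx_rate = mtc_thx_rate, helper_thx_rate = helper_thx_rate,
         killer_thx_rate = killer_thx_rate,
         regulator_thx_rate = regulator_thx_rate,
         immuno1_rate = immuno1_rate,
         immuno2_csc_factor = i2csc, immuno2_ctac_factor = i2ctac,
         immuno2_mtc_factor = i2mtc)
  class(f) <- "hl_flows"
  f
}

#' Guarded net rate of change of a stock
#'
#' The model's stock-update rule: with net per-day rate
#' \eqn{r = gain - loss + additive}, the stock changes at rate \eqn{r} if
#' `stock + r > 0`, and otherwise at rate `-stock`. The guard compares the
#' stock against the *per-day* rate (not the per-step increment), exactly as
#' the model is defined; combined with an Euler step this keeps every stock
#' non-negative.
#'
#' @param stock Current stock value (cells, `>= 0`).
#' @param gain,loss Per-day gain and loss rates (cells/day).
#' @param additive Extra additive per-day rate (cells/day); used for the
#'   adoptive-transfer influx into the killer stock.
#' @return Net per-day rate of change (cells/day).
#' @export
net_change <- function(stock, gain, loss, additive = 0) {
  r <- gain - loss + additive
  if (stock + r > 0) r else -stock
}
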