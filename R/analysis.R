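# Analysis: burden summary, outcome classification, escape-window scan,
# minimal-dose and minimal-amplification searches.

#' Total tumor burden
#'
#' Sum of the three tumor sub-compartments (csc + ctac + mtc).
#'
#' @param x An `hl_state`, an `hl_trajectory`, or any data frame/named
#'   vector with `csc`, `ctac`, `mtc` entries.
#' @return A single burden (for a state) or a vector along time (for a
#'   trajectory).
#' @export
tumor_burden <- function(x) {
  if (is.data.frame(x)) x$csc + x$ctac + x$mtc
  else x[["csc"]] + x[["ctac"]] + x[["mtc"]]
}

#' Outcome-classification criteria
#'
#' Thresholds used by [classify_outcome()]. `elimination_threshold` is the
#' burden below which the tumor counts as eliminated (half a cell).
#' `control_ratio` bounds the final/initial burden ratio for "suppressed".
#' A trajectory is in remission once burden drops below `relapse_low` times
#' its running peak, and has relapsed if burden later exceeds
#' `relapse_high` times the initial burden.
#'
#' @param elimination_threshold Cells; must be > 0.
#' @param control_ratio Dimensionless.
#' @param relapse_low Fraction (< 1) of the running burden peak.
#' @param relapse_high Fold (> 1) of the initial burden.
#' @return A list of class `hl_criteria`.
#' @export
outcome_criteria <- function(elimination_threshold = 0.5, control_ratio = 1,
                             relapse_low = 0.1, relapse_high = 10) {
  if (elimination_threshold <= 0)
    stop("elimination_threshold must be > 0", call. = FALSE)
  if (!(relapse_low < 1 && relapse_high > 1))
    stop("need relapse_low < 1 < relapse_high", call. = FALSE)
  structure(list(elimination_threshold = elimination_threshold,
                 control_ratio = control_ratio,
                 relapse_low = relapse_low, relapse_high = relapse_high),
            class = "hl_criteria")
}

#' Classify the outcome of a simulated trajectory
#'
#' Labels, in order of precedence:
#' * `eliminated` — final burden below `elimination_threshold`;
#' * `relapse` — burden entered remission (dropped below `relapse_low`
#'   times its running peak) and later exceeded `relapse_high` times the
#'   initial burden;
#' * `suppressed` — final burden at most `control_ratio` times the initial
#'   burden;
#' * `progression` — otherwise.
#'
#' @param traj An `hl_trajectory` (non-empty).
#' @param criteria An `hl_criteria` object.
#' @return A list of class `hl_outcome`: `label`, `initial_burden`,
#'   `final_burden`, `min_burden`, `min_time`, `regrowth_time` (`NA` unless
#'   a relapse was detected), `final_csc`.
#' @export
#' @examples
#' traj <- simulate_model(default_parameters(), sim_settings(final_time = 100))
#' classify_outcome(traj)$label
classify_outcome <- function(traj, criteria = outcome_criteria()) {
  stopifnot(inherits(criteria, "hl_criteria"))
  if (!is.data.frame(traj) || nrow(traj) == 0)
    stop("empty trajectory", call. = FALSE)
  b <- tumor_burden(traj)
  b0 <- b[1]
  bf <- b[length(b)]
  imin <- which.min(b)
  peak <- cummax(b)
  remission <- which(b < criteria$relapse_low * peak)
  regrowth_time <- NA_real_
  label <- if (bf < criteria$elimination_threshold) {
    "eliminated"
  } else if (length(remission) &&
             any(b[remission[1]:length(b)] > criteria$relapse_high * b0)) {
    i0 <- remission[1]
    ir <- i0 - 1 + which(b[i0:length(b)] > criteria$relapse_high * b0)[1]
    regrowth_time <- traj$time[ir]
    "relapse"
  } else if (bf <= criteria$control_ratio * b0) {
    "suppressed"
  } else {
    "progression"
  }
  structure(list(label = label, initial_burden = b0, final_burden = bf,
                 min_burden = b[imin], min_time = traj$time[imin],
                 regrowth_time = regrowth_time,
                 final_csc = traj$csc[nrow(traj)]),
            class = "hl_outcome")
}

#' @export
print.hl_outcome <- function(x, ...) {
  cat(sprintf("outcome: %s\n", x$label))
  cat(sprintf("  burden: initial %.6g, final %.6g, min %.6g at day %g\n",
              x$initial_burden, x$final_burden, x$min_burden, x$min_time))
  if (!is.na(x$regrowth_time))
    cat(sprintf("  regrowth crossed %s at day %g\n", "threshold",
                x$regrowth_time))
  invisible(x)
}

# outcome counts as tumor control for the burden-based experiments
.is_suppressed <- function(outcome) outcome$label %in% c("eliminated", "suppressed")

#' Scan adoptive-transfer start days for escape windows
#'
#' For each integer start day, simulates a single-window adoptive-transfer
#' pulse of killer cells (`ImmunoTHx1` with duration `dur`) and records
#' whether the tumor was suppressed (label `eliminated` or `suppressed`).
#' The maximal contiguous runs of non-suppressed start days are the
#' immune-escape windows.
#'
#' @param base Base parameter set.
#' @param intensity Pulse intensity (cells/day over one day = cells).
#' @param day_range Integer vector `c(first, last)` of start days.
#' @param criteria Outcome criteria.
#' @param settings Simulation settings (horizon must cover the scan).
#' @param dur Pulse duration in days.
#' @return Data frame `day`, `label`, `final_burden`, `suppressed`, with
#'   attribute `windows`: data frame `start`, `end` of each maximal
#'   non-suppressed run.
#' @export
scan_pulse_window <- function(base = default_parameters(), intensity,
                              day_range, criteria = outcome_criteria(),
                              settings = sim_settings(), dur = 1) {
  days <- seq.int(day_range[1], day_range[2])
  if (any(days < settings$initial_time | days > settings$final_time))
    stop("day_range must lie within the simulation horizon", call. = FALSE)
  rows <- lapply(days, function(d) {
    p <- apply_overrides(base, list(immuno1_time = d, immuno1_dur = dur,
                                    immuno1_intens = intensity))
    out <- tryCatch(classify_outcome(simulate_model(p, settings), criteria),
                    error = function(e)
                      stop("simulation failed at start day ", d, ": ",
                           conditionMessage(e), call. = FALSE))
    data.frame(day = d, label = out$label, final_burden = out$final_burden,
               suppressed = .is_suppressed(out))
  })
  res <- do.call(rbind, rows)
  r <- rle(!res$suppressed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  win <- data.frame(start = res$day[starts[r$values]],
                    end = res$day[ends[r$values]])
  attr(res, "windows") <- win
  res
}

#' Minimal adoptive-transfer dose achieving suppression
#'
#' Finds the smallest `ImmunoTHx1` intensity whose single-day pulse at
#' `start_day` suppresses the tumor, by decade scan followed by geometric
#' bisection to two significant figures. The outcome must be non-suppressed
#' at `search_range[1]` and suppressed at `search_range[2]` (verified), and
#' is assumed monotone in between; a detected non-monotonicity along the
#' decade scan is an error rather than silently accepted.
#'
#' @param base Base parameter set.
#' @param start_day Pulse start day.
#' @param search_range `c(lo, hi)` intensity bracket.
#' @param criteria Outcome criteria.
#' @param settings Simulation settings.
#' @return Minimal suppressing intensity (numeric), with attribute
#'   `bracket = c(largest failing, smallest suppressing)`.
#' @export
find_min_intensity <- function(base = default_parameters(), start_day,
                               search_range, criteria = outcome_criteria(),
                               settings = sim_settings()) {
  lo <- search_range[1]; hi <- search_range[2]
  if (!(lo < hi)) stop("need search_range[1] < search_range[2]", call. = FALSE)
  f <- function(I) {
    p <- apply_overrides(base, list(immuno1_time = start_day, immuno1_dur = 1,
                                    immuno1_intens = I))
    .is_suppressed(classify_outcome(simulate_model(p, settings), criteria))
  }
  s_lo <- f(lo); s_hi <- f(hi)
  if (s_lo || !s_hi)
    stop(sprintf(paste0("invalid bracket: intensity %g is %s and %g is %s; ",
                        "need non-suppressed at the low end and suppressed ",
                        "at the high end"),
                 lo, ifelse(s_lo, "suppressed", "non-suppressed"),
                 hi, ifelse(s_hi, "suppressed", "non-suppressed")),
         call. = FALSE)
  # decade scan to a one-decade bracket
  decades <- 10^seq(ceiling(log10(lo) + 1e-9), floor(log10(hi) - 1e-9))
  seen_supp <- FALSE
  for (I in decades) {
    s <- f(I)
    if (seen_supp && !s)
      stop("outcome is not monotone in intensity near ", format(I),
           call. = FALSE)
    if (s && !seen_supp) { hi <- I; seen_supp <- TRUE }
    if (!s) lo <- I
  }
  # geometric bisection to 2 significant figures
  while (hi / lo > 1.05) {
    mid <- sqrt(lo * hi)
    if (f(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bracket = c(lo, hi))
}

#' Minimal integer parameter value achieving tumor control
#'
#' Scans an integer candidate range of a named parameter (ascending) and
#' returns the smallest value whose simulated outcome counts as control.
#' For the killing-amplification (`ImmunoTHx2*`) experiments the relevant
#' control notion is eradication of the self-renewing compartment
#' (`criterion = "csc_eliminated"`, the default): the controlled state
#' retains a stroma-protected remnant of mature tumor cells, so total
#' burden does not fall back to its initial value even though the tumor is
#' permanently controlled. `criterion = "outcome"` instead requires the
#' burden-based label to be `eliminated`/`suppressed`.
#'
#' @param base Base parameter set.
#' @param target_field Parameter to scan (canonical key or display name).
#' @param candidates Integer candidate values (scanned in sorted order).
#' @param criteria Outcome criteria.
#' @param settings Simulation settings (the amplification experiments use a
#'   4000-day horizon).
#' @param criterion `"csc_eliminated"` or `"outcome"`.
#' @return Smallest controlling integer, or `NA` if none controls; the
#'   attribute `results` holds the per-candidate table.
#' @export
find_threshold_integer <- function(base = default_parameters(), target_field,
                                   candidates,
                                   criteria = outcome_criteria(),
                                   settings = sim_settings(final_time = 4000),
                                   criterion = c("csc_eliminated", "outcome")) {
  criterion <- match.arg(criterion)
  if (!length(candidates)) stop("empty candidate range", call. = FALSE)
  key <- normalize_param_key(target_field)
  candidates <- sort(unique(as.integer(candidates)))
  rows <- vector("list", length(candidates))
  hit <- NA_integer_
  for (i in seq_along(candidates)) {
    ov <- setNames(list(candidates[i]), key)
    out <- classify_outcome(simulate_model(apply_overrides(base, ov), settings),
                            criteria)
    controlled <- if (criterion == "csc_eliminated")
      out$final_csc < criteria$elimination_threshold else .is_suppressed(out)
    rows[[i]] <- data.frame(candidate = candidates[i], label = out$label,
                            final_burden = out$final_burden,
                            final_csc = out$final_csc, controlled = controlled)
    if (controlled) { hit <- candidates[i]; rows <- rows[seq_len(i)]; break }
  }
  structure(hit, results = do.call(rbind, rows))
}
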