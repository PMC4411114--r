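# Independent oracle: a line-by-line transcription of the published
# equation table, written against the display parameter names and kept
# deliberately separate from the package's compute_flows() code path.

oracle_param_list <- function(params) {
  tab <- param_table()
  setNames(as.list(unclass(params)[tab$key]), tab$display)
}

# state: named vector; P: display-named list; t: time (days)
oracle_flows <- function(state, P, t) {
  PULSE <- function(start, dur) if (t >= start && t < start + dur) 1 else 0
  MAX <- function(a, b) max(a, b)
  IF_THEN_ELSE <- function(cond, yes, no) if (cond) yes else no

  CancerStemCells <- state[["csc"]]
  CancerTransitAmplifyingCells <- state[["ctac"]]
  MatureTumorCells <- state[["mtc"]]
  HelperCells <- state[["helper"]]
  KillerCells <- state[["killer"]]
  RegulatoryCells <- state[["regulator"]]

  CSC_THx <- PULSE(P[["CSC THx time"]], P[["CSC Thx dur"]]) * P[["CSC THx intens"]]
  CTAC_THx <- PULSE(P[["CTAC THx time"]], P[["CTAC Thx dur"]]) * P[["CTAC THx intens"]]
  MTC_THx <- PULSE(P[["MTC THx time"]], P[["MTC Thx dur"]]) * P[["MTC THx intens"]]
  Helper_Thx <- PULSE(P[["Helper THx time"]], P[["Helper Thx dur"]]) * P[["Helper THx intens"]]
  Killer_THx <- PULSE(P[["Killer THx time"]], P[["Killer THx dur"]]) * P[["Killer THx intens"]]
  Regulator_THx <- PULSE(P[["Regulator THx time"]], P[["Regulator Thx dur"]]) * P[["Regulator THx intens"]]
  ImmunoTHx1 <- PULSE(P[["ImmunoTHx1 time"]], P[["ImmunoTHx1 dur"]]) * P[["ImmunoTHx1 intens"]]
  ImmunoTHx2CSC <- PULSE(P[["ImmunoTHx2CSC time"]], P[["ImmunoTHx2CSC dur"]]) * P[["ImmunoTHx2CSC intens"]]
  ImmunoTHx2CTAC <- PULSE(P[["ImmunoTHx2CTAC time"]], P[["ImmunoTHx2CTAC dur"]]) * P[["ImmunoTHx2CTAC intens"]]
  ImmunoTHx2MTC <- PULSE(P[["ImmunoTHx2MTC time"]], P[["ImmunoTHx2MTC dur"]]) * P[["ImmunoTHx2MTC intens"]]

  CSC_loss <- (MAX(0, (CancerStemCells * P[["CSC death"]]) +
                     ((1 + ImmunoTHx2CSC) * P[["Kill of CSC"]] * KillerCells) -
                     (HelperCells * P[["Help for CSC"]])) +
               (CancerStemCells * P[["CSC diff"]])) + (CancerStemCells * CSC_THx)
  CSC_prol <- MAX(0, (P[["CSC growth"]] * CancerStemCells) -
                    (CancerStemCells * CancerStemCells * P[["CSC cap"]]))
  CTAC_incr <- MAX(0, (P[["CSC diff"]] * CancerStemCells) +
                     (P[["CTAC growth"]] * CancerTransitAmplifyingCells) -
                     (P[["CTAC cap"]] * CancerTransitAmplifyingCells * CancerTransitAmplifyingCells))
  CTAC_loss <- (MAX(0, (KillerCells * P[["Kill of CTAC"]] * (1 + ImmunoTHx2CTAC)) +
                      (P[["CTAC death"]] * CancerTransitAmplifyingCells) -
                      (HelperCells * P[["Help for CTAC"]])) +
                (P[["CTAC diff"]] * CancerTransitAmplifyingCells)) +
    (CTAC_THx * CancerTransitAmplifyingCells)
  Helper_loss <- (HelperCells * P[["Helper death"]]) + (HelperCells * Helper_Thx)
  Helper_stim_by_Tumor <- (CancerStemCells * P[["Helper stim by CSC"]]) +
    (P[["Helper stim by CTAC"]] * CancerTransitAmplifyingCells) +
    (MatureTumorCells * P[["Helper stim by MTC"]])
  Helper_prol <- IF_THEN_ELSE(HelperCells * Helper_stim_by_Tumor > 0,
    MAX(0, (Helper_stim_by_Tumor * HelperCells) -
          (HelperCells * HelperCells * P[["Helper cap"]]) -
          (P[["Regulation of Helper Cells"]] * RegulatoryCells)), 0)
  Killer_loss <- (KillerCells * P[["Killer death"]]) + (Killer_THx * KillerCells)
  Killer_stim_by_Tumor <- MAX(0, (CancerStemCells * P[["Killer stim by CSC"]]) +
                                (P[["Killer stim by CTAC"]] * CancerTransitAmplifyingCells) +
                                (MatureTumorCells * P[["Killer stim by MTC"]]))
  Killer_prol <- IF_THEN_ELSE(
    KillerCells * Killer_stim_by_Tumor * P[["Help for Killer Cells"]] * HelperCells > 0,
    MAX(0, (KillerCells * Killer_stim_by_Tumor) -
          (P[["Regulation of Killer Cells"]] * RegulatoryCells) +
          (HelperCells * P[["Help for Killer Cells"]]) -
          (KillerCells * KillerCells * P[["Killer cap"]])), 0)
  MTC_incr <- MAX(0, (P[["MTC growth"]] * MatureTumorCells) +
                    (P[["CTAC diff"]] * CancerTransitAmplifyingCells) -
                    (P[["MTC cap"]] * MatureTumorCells * MatureTumorCells))
  MTC_loss <- (MAX(0, (KillerCells * P[["Kill of MTC"]] * (1 + ImmunoTHx2MTC)) +
                     (P[["MTC death"]] * MatureTumorCells) -
                     (HelperCells * P[["Help for MTC"]]))) +
    (MTC_THx * MatureTumorCells)
  Regulator_loss <- (RegulatoryCells * P[["Regulator death"]]) +
    (Regulator_THx * RegulatoryCells)
  Regulator_stim_by_Tumor <- (CancerStemCells * P[["Regulator stim by CSC"]]) +
    (CancerTransitAmplifyingCells * P[["Regulator stim by CTAC"]]) +
    (MatureTumorCells * P[["Regulator stim by MTC"]])
  Regulator_prol <- IF_THEN_ELSE(RegulatoryCells * Regulator_stim_by_Tumor > 0,
    MAX(0, (RegulatoryCells * Regulator_stim_by_Tumor) -
          (RegulatoryCells * RegulatoryCells * P[["Regulator cap"]])), 0)

  c(csc_prol = CSC_prol, csc_loss = CSC_loss,
    ctac_incr = CTAC_incr, ctac_loss = CTAC_loss,
    mtc_incr = MTC_incr, mtc_loss = MTC_loss,
    helper_prol = Helper_prol, helper_loss = Helper_loss,
    killer_prol = Killer_prol, killer_loss = Killer_loss,
    regulator_prol = Regulator_prol, regulator_loss = Regulator_loss,
    helper_stim_by_tumor = Helper_stim_by_Tumor,
    killer_stim_by_tumor = Killer_stim_by_Tumor,
    regulator_stim_by_tumor = Regulator_stim_by_Tumor,
    immuno1_rate = ImmunoTHx1)
}

# random non-negative state on a wide log scale, deterministic given the
# caller's RNG state
random_state <- function() {
  v <- 10^stats::runif(6, -2, 9) * stats::rbinom(6, 1, 0.9)
  state_vector(v[1], v[2], v[3], v[4], v[5], v[6])
}
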