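// Fixed-step Euler integration of the six-stock tumor-microenvironment
// model. The flow expressions mirror R/model_core.R term for term so the
// compiled path and the interpreted path agree to round-off.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pulse01(double t, double start, double dur) {
  return (t >= start && t < start + dur) ? 1.0 : 0.0;
}

static inline double max0(double x) { return x > 0.0 ? x : 0.0; }

// guard compares stock against the per-day rate, not the per-step increment
static inline double net_change(double stock, double r) {
  return (stock + r > 0.0) ? r : -stock;
}

// [[Rcpp::export]]
NumericMatrix sim_euler_cpp(NumericVector params, double t0, double tf,
                            double dt, double saveper) {
  if (!(dt > 0.0)) stop("dt must be > 0");
  if (!(saveper >= dt)) stop("saveper must be >= dt");
  if (!(tf > t0)) stop("final time must exceed initial time");

  CharacterVector nm = params.names();
  std::map<std::string, double> P;
  for (R_xlen_t i = 0; i < params.size(); ++i) {
    if (!std::isfinite(params[i]))
      stop("non-finite parameter value: %s", std::string(nm[i]).c_str());
    P[std::string(nm[i])] = params[i];
  }
  auto par = [&](const char *k) -> double {
    std::map<std::string, double>::const_iterator it = P.find(k);
    if (it == P.end()) stop("missing parameter: %s", k);
    return it->second;
  };

  const double csc_cap = par("csc_cap"), csc_death = par("csc_death"),
    csc_diff = par("csc_diff"), csc_growth = par("csc_growth"),
    csc_thx_dur = par("csc_thx_dur"), csc_thx_intens = par("csc_thx_intens"),
    csc_thx_time = par("csc_thx_time");
  const double ctac_cap = par("ctac_cap"), ctac_death = par("ctac_death"),
    ctac_diff = par("ctac_diff"), ctac_growth = par("ctac_growth"),
    ctac_thx_dur = par("ctac_thx_dur"),
    ctac_thx_intens = par("ctac_thx_intens"),
    ctac_thx_time = par("ctac_thx_time");
  const double help_for_csc = par("help_for_csc"),
    help_for_ctac = par("help_for_ctac"),
    help_for_killer = par("help_for_killer"),
    help_for_mtc = par("help_for_mtc");
  const double helper_cap = par("helper_cap"),
    helper_death = par("helper_death"),
    hs_csc = par("helper_stim_by_csc"), hs_ctac = par("helper_stim_by_ctac"),
    hs_mtc = par("helper_stim_by_mtc"),
    helper_thx_dur = par("helper_thx_dur"),
    helper_thx_intens = par("helper_thx_intens"),
    helper_thx_time = par("helper_thx_time");
  const double i1_dur = par("immuno1_dur"), i1_intens = par("immuno1_intens"),
    i1_time = par("immuno1_time");
  const double i2c_dur = par("immuno2_csc_dur"),
    i2c_intens = par("immuno2_csc_intens"), i2c_time = par("immuno2_csc_time");
  const double i2t_dur = par("immuno2_ctac_dur"),
    i2t_intens = par("immuno2_ctac_intens"),
    i2t_time = par("immuno2_ctac_time");
  const double i2m_dur = par("immuno2_mtc_dur"),
    i2m_intens = par("immuno2_mtc_intens"), i2m_time = par("immuno2_mtc_time");
  const double killer_cap = par("killer_cap"),
    killer_death = par("killer_death"),
    ks_csc = par("killer_stim_by_csc"), ks_ctac = par("killer_stim_by_ctac"),
    ks_mtc = par("killer_stim_by_mtc"),
    killer_thx_dur = par("killer_thx_dur"),
    killer_thx_intens = par("killer_thx_intens"),
    killer_thx_time = par("killer_thx_time");
  const double kill_of_csc = par("kill_of_csc"),
    kill_of_ctac = par("kill_of_ctac"), kill_of_mtc = par("kill_of_mtc");
  const double mtc_cap = par("mtc_cap"), mtc_death = par("mtc_death"),
    mtc_growth = par("mtc_growth"), mtc_thx_dur = par("mtc_thx_dur"),
    mtc_thx_intens = par("mtc_thx_intens"), mtc_thx_time = par("mtc_thx_time");
  const double reg_of_helper = par("regulation_of_helper"),
    reg_of_killer = par("regulation_of_killer");
  const double reg_cap = par("regulator_cap"),
    reg_death = par("regulator_death"),
    rs_csc = par("regulator_stim_by_csc"),
    rs_ctac = par("regulator_stim_by_ctac"),
    rs_mtc = par("regulator_stim_by_mtc"),
    reg_thx_dur = par("regulator_thx_dur"),
    reg_thx_intens = par("regulator_thx_intens"),
    reg_thx_time = par("regulator_thx_time");

  double csc = par("initial_csc"), ctac = par("initial_ctac"),
    mtc = par("initial_mtc"), helper = par("initial_helper"),
    killer = par("initial_killer"), regulator = par("initial_regulator");

  const R_xlen_t n_steps = (R_xlen_t)std::floor((tf - t0) / dt + 1e-9);
  const R_xlen_t n_save = (R_xlen_t)std::floor((tf - t0) / saveper + 1e-9);

  NumericMatrix out(n_save + 1, 7);
  out(0, 0) = t0;
  out(0, 1) = csc; out(0, 2) = ctac; out(0, 3) = mtc;
  out(0, 4) = helper; out(0, 5) = killer; out(0, 6) = regulator;

  R_xlen_t j = 1;  // next save row
  // step index recorded for save j: largest k with t0 + k*dt <= save time
  R_xlen_t next_save_step = (n_save >= 1)
    ? (R_xlen_t)std::floor(1 * saveper / dt + 1e-9) : n_steps + 1;

  for (R_xlen_t k = 0; k < n_steps; ++k) {
    const double t = t0 + k * dt;

    const double csc_thx = pulse01(t, csc_thx_time, csc_thx_dur) * csc_thx_intens;
    const double ctac_thx = pulse01(t, ctac_thx_time, ctac_thx_dur) * ctac_thx_intens;
    const double mtc_thx = pulse01(t, mtc_thx_time, mtc_thx_dur) * mtc_thx_intens;
    const double helper_thx = pulse01(t, helper_thx_time, helper_thx_dur) * helper_thx_intens;
    const double killer_thx = pulse01(t, killer_thx_time, killer_thx_dur) * killer_thx_intens;
    const double reg_thx = pulse01(t, reg_thx_time, reg_thx_dur) * reg_thx_intens;
    const double immuno1 = pulse01(t, i1_time, i1_dur) * i1_intens;
    const double i2csc = pulse01(t, i2c_time, i2c_dur) * i2c_intens;
    const double i2ctac = pulse01(t, i2t_time, i2t_dur) * i2t_intens;
    const double i2mtc = pulse01(t, i2m_time, i2m_dur) * i2m_intens;

    const double csc_prol = max0((csc_growth * csc) - (csc * csc * csc_cap));
    const double csc_loss = (max0((csc * csc_death) +
                                  ((1 + i2csc) * kill_of_csc * killer) -
                                  (helper * help_for_csc)) +
                             (csc * csc_diff)) + (csc * csc_thx);

    const double ctac_incr = max0((csc_diff * csc) + (ctac_growth * ctac) -
                                  (ctac_cap * ctac * ctac));
    const double ctac_loss = (max0((killer * kill_of_ctac * (1 + i2ctac)) +
                                   (ctac_death * ctac) -
                                   (helper * help_for_ctac)) +
                              (ctac_diff * ctac)) + (ctac_thx * ctac);

    const double mtc_incr = max0((mtc_growth * mtc) + (ctac_diff * ctac) -
                                 (mtc_cap * mtc * mtc));
    const double mtc_loss = max0((killer * kill_of_mtc * (1 + i2mtc)) +
                                 (mtc_death * mtc) -
                                 (helper * help_for_mtc)) + (mtc_thx * mtc);

    const double helper_stim = (csc * hs_csc) + (hs_ctac * ctac) + (mtc * hs_mtc);
    const double helper_prol = (helper * helper_stim > 0)
      ? max0((helper_stim * helper) - (helper * helper * helper_cap) -
             (reg_of_helper * regulator))
      : 0.0;
    const double helper_loss = (helper * helper_death) + (helper * helper_thx);

    const double killer_stim = max0((csc * ks_csc) + (ks_ctac * ctac) +
                                    (mtc * ks_mtc));
    const double killer_prol = (killer * killer_stim * help_for_killer * helper > 0)
      ? max0((killer * killer_stim) - (reg_of_killer * regulator) +
             (helper * help_for_killer) - (killer * killer * killer_cap))
      : 0.0;
    const double killer_loss = (killer * killer_death) + (killer_thx * killer);

    const double reg_stim = (csc * rs_csc) + (ctac * rs_ctac) + (mtc * rs_mtc);
    const double reg_prol = (regulator * reg_stim > 0)
      ? max0((regulator * reg_stim) - (regulator * regulator * reg_cap))
      : 0.0;
    const double reg_loss = (regulator * reg_death) + (reg_thx * regulator);

    // synchronous update: all nets from the pre-step state
    const double d_csc = net_change(csc, csc_prol - csc_loss);
    const double d_ctac = net_change(ctac, ctac_incr - ctac_loss);
    const double d_mtc = net_change(mtc, mtc_incr - mtc_loss);
    const double d_helper = net_change(helper, helper_prol - helper_loss);
    const double d_killer = net_change(killer, killer_prol - killer_loss + immuno1);
    const double d_reg = net_change(regulator, reg_prol - reg_loss);

    csc += dt * d_csc; ctac += dt * d_ctac; mtc += dt * d_mtc;
    helper += dt * d_helper; killer += dt * d_killer; regulator += dt * d_reg;

    if (!(std::isfinite(csc) && std::isfinite(ctac) && std::isfinite(mtc) &&
          std::isfinite(helper) && std::isfinite(killer) &&
          std::isfinite(regulator)))
      stop("simulation diverged (non-finite stock) at time %.6f", t + dt);

    if (k + 1 == next_save_step) {
      out(j, 0) = t0 + j * saveper;
      out(j, 1) = csc; out(j, 2) = ctac; out(j, 3) = mtc;
      out(j, 4) = helper; out(j, 5) = killer; out(j, 6) = regulator;
      ++j;
      next_save_step = (j <= n_save)
        ? (R_xlen_t)std::floor(j * saveper / dt + 1e-9) : n_steps + 1;
    }
  }

  colnames(out) = CharacterVector::create("time", "csc", "ctac", "mtc",
                                          "helper", "killer", "regulator");
  return out;
}
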