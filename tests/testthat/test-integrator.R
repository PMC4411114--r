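test_that("a single Euler step matches the hand-evaluated update", {
  p <- default_parameters()
  s1 <- euler_step(state_vector(), p, t = 0, dt = 0.0078125)
  expect_equal(s1[["csc"]], 10 + 0.0078125 * (0.0999999 - 0.11001),
               tolerance = 1e-12)
  expect_equal(s1[["ctac"]], 10 + 0.0078125 * (9.0199999 - 9.39001),
               tolerance = 1e-12)
})

test_that("the adoptive-transfer pulse adds dt * intensity killer cells per step", {
  p <- default_parameters(immuno1_time = 300, immuno1_dur = 1,
                          immuno1_intens = 1e6)
  s <- state_vector()
  dt <- 0.0078125
  inside <- euler_step(s, p, t = 300.5, dt = dt)
  outside <- euler_step(s, p, t = 299.5, dt = dt)
  expect_equal(inside[["killer"]] - outside[["killer"]], dt * 1e6)
  # the influx enters the update even when ordinary net change is clamped
  f <- compute_flows(s, p, t = 300.5)
  expect_identical(f[["immuno1_rate"]], 1e6)
})

test_that("compiled and interpreted integration paths agree", {
  p <- default_parameters(mtc_thx_intens = 0.9, mtc_thx_time = 1,
                          immuno1_time = 2, immuno1_intens = 1e4)
  dt <- 0.0078125
  traj <- simulate_model(p, sim_settings(final_time = 4, dt = dt))
  s <- state_vector()
  for (k in seq_len(4 / dt)) s <- euler_step(s, p, t = (k - 1) * dt, dt = dt)
  expect_equal(as.numeric(traj[nrow(traj), -1]), as.numeric(s),
               tolerance = 1e-12)
})

test_that("the bystander-free limit follows the exact geometric recurrence", {
  p <- default_parameters(initial_helper = 0, initial_killer = 0,
                          initial_regulator = 0)
  dt <- 0.0078125
  traj <- simulate_model(p, sim_settings(final_time = 30, dt = dt))
  expect_true(all(traj$helper == 0 & traj$killer == 0 & traj$regulator == 0))
  # csc_{n+1} = csc_n + dt*(growth - death - diff)*csc_n - dt*cap*csc_n^2
  csc <- 10
  r <- p[["csc_growth"]] - p[["csc_death"]] - p[["csc_diff"]]
  expected <- numeric(31)
  expected[1] <- csc
  for (k in seq_len(30 / dt)) {
    csc <- csc + dt * r * csc - dt * p[["csc_cap"]] * csc^2
    if (k %% (1 / dt) == 0) expected[k * dt + 1] <- csc
  }
  expect_equal(traj$csc, expected, tolerance = 1e-12)
})

test_that("an independent fixed-step solver reproduces the pulse-free dynamics", {
  skip_if_not_installed("deSolve")
  p <- default_parameters()
  dt <- 0.0078125
  deriv <- function(t, y, parms) {
    s <- state_vector(y[1], y[2], y[3], y[4], y[5], y[6])
    f <- compute_flows(s, p, t)
    list(c(net_change(y[1], f[["csc_prol"]], f[["csc_loss"]]),
           net_change(y[2], f[["ctac_incr"]], f[["ctac_loss"]]),
           net_change(y[3], f[["mtc_incr"]], f[["mtc_loss"]]),
           net_change(y[4], f[["helper_prol"]], f[["helper_loss"]]),
           net_change(y[5], f[["killer_prol"]], f[["killer_loss"]],
                      additive = f[["immuno1_rate"]]),
           net_change(y[6], f[["regulator_prol"]], f[["regulator_loss"]])))
  }
  times <- seq(0, 2, by = dt)
  ref <- deSolve::ode(rep(10, 6), times, deriv, NULL, method = "euler")
  traj <- simulate_model(p, sim_settings(final_time = 2, dt = dt))
  expect_equal(as.numeric(traj[nrow(traj), -1]),
               as.numeric(ref[nrow(ref), -1]), tolerance = 1e-10)
})

test_that("simulation is deterministic and records the expected grid", {
  p <- default_parameters()
  st <- sim_settings(final_time = 100)
  a <- simulate_model(p, st)
  b <- simulate_model(p, st)
  expect_identical(a, b)
  expect_identical(a$time, as.numeric(0:100))
  expect_identical(as.numeric(a[1, -1]), rep(10, 6))
})

test_that("stocks stay non-negative under randomized parameters and states", {
  set.seed(123)
  for (i in 1:20) {
    tab <- param_table()
    fac <- 10^stats::runif(nrow(tab), -1, 1)
    vals <- tab$default * fac
    # keep schedules meaningful: leave times/durations at default
    keep <- grepl("_time$|_dur$", tab$key)
    vals[keep] <- tab$default[keep]
    # switch some therapies on with random sign where allowed
    intens <- grepl("intens$", tab$key)
    vals[intens] <- stats::runif(sum(intens), -0.5, 1)
    p <- default_parameters(overrides = setNames(vals, tab$key))
    traj <- simulate_model(p, sim_settings(final_time = 50))
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("halving the time step leaves the tumor burden nearly unchanged", {
  p <- default_parameters()
  a <- simulate_model(p, sim_settings(dt = 0.007812))
  b <- simulate_model(p, sim_settings(dt = 0.007812 / 2))
  rel <- abs(tumor_burden(a) - tumor_burden(b)) / tumor_burden(b)
  expect_lt(max(rel), 0.005)
})

test_that("untreated growth and its known switches behave as published", {
  horizon <- sim_settings(final_time = 2000)
  b_default <- tumor_burden(simulate_model(default_parameters(), horizon))
  expect_gt(b_default[length(b_default)], 1000 * b_default[1])

  # without cancer stem cells the burden collapses (a small transient rise
  # from differentiation into the mature compartment precedes the decay)
  b_nocsc <- tumor_burden(simulate_model(default_parameters(initial_csc = 0),
                                         horizon))
  expect_lt(b_nocsc[length(b_nocsc)], b_nocsc[1])
  expect_lt(max(b_nocsc), 2 * b_nocsc[1])

  b_nohelp <- tumor_burden(simulate_model(
    default_parameters(initial_helper = 0), horizon))
  expect_lte(b_nohelp[length(b_nohelp)], b_nohelp[1])

  b_killcsc <- tumor_burden(simulate_model(
    default_parameters(kill_of_csc = 0.1), horizon))
  expect_lte(b_killcsc[length(b_killcsc)], b_killcsc[1])
})

test_that("a diverging run fails with a diagnostic naming the time", {
  p <- default_parameters(csc_growth = 1e308)
  expect_error(simulate_model(p, sim_settings(final_time = 10)), "diverged")
})
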