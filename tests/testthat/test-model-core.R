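test_that("pulse is active exactly on the half-open window", {
  expect_identical(pulse(399, 400, 100), 0)
  expect_identical(pulse(400, 400, 100), 1)
  expect_identical(pulse(499.999, 400, 100), 1)
  expect_identical(pulse(500, 400, 100), 0)
  expect_identical(pulse(c(0, 1000), 400, 0), c(0, 0))  # zero duration never fires
  expect_error(pulse(0, 0, -1), ">= 0")
})

test_that("therapy_rate scales the pulse by a sign-preserving intensity", {
  expect_identical(therapy_rate(450, 400, 100, 0.9), 0.9)
  expect_identical(therapy_rate(450, 400, 100, 0), 0)
  expect_identical(therapy_rate(1000, 1000, 1, -0.9), -0.9)
  expect_identical(therapy_rate(350, 400, 100, 0.9), 0)
})

test_that("tumor stimulus is the weighted stock sum, clamped only on request", {
  s <- state_vector()
  expect_equal(stimulus(s, 0.001, 0.001, 0.001), 0.03)
  expect_equal(stimulus(s, 1e-4, 1e-4, 0.02, clamp = TRUE), 0.202)
  z <- state_vector(0, 0, 0, 0, 0, 0)
  expect_identical(stimulus(z, 1, 1, 1), 0)
})

test_that("flows at the default initial state match hand-evaluated values", {
  f <- compute_flows(state_vector(), default_parameters(), t = 0)
  expect_equal(f[["csc_prol"]], 0.0999999)
  expect_equal(f[["csc_loss"]], 0.11001)
  expect_equal(f[["ctac_incr"]], 9.0199999)
  expect_equal(f[["ctac_loss"]], 9.39001)
  expect_equal(f[["mtc_incr"]], 9.0999999)
  expect_equal(f[["mtc_loss"]], 4.99001)
  # killer gain is clamped to zero (regulation exceeds stimulation), the
  # other bystander gains are positive
  expect_identical(f[["killer_prol"]], 0)
  expect_equal(f[["regulator_prol"]], 0.2)
  expect_equal(f[["helper_prol"]], 0.2989999)
})

test_that("net change follows the guarded update rule", {
  expect_identical(net_change(10, 5, 0), 5)
  expect_identical(net_change(10, 0, 20), -10)   # fallback branch
  expect_identical(net_change(0, 0, 0), 0)       # guard 0 > 0 is false
  expect_identical(net_change(10, 0, 5, additive = 20), 15)
})

test_that("the all-zero state is a fixed point", {
  z <- state_vector(0, 0, 0, 0, 0, 0)
  p <- default_parameters()
  f <- compute_flows(z, p, t = 0)
  rates <- grep("prol|incr|loss|stim|immuno2", names(f), value = TRUE)
  expect_true(all(unclass(f)[rates] == 0))
  expect_identical(unclass(euler_step(z, p, t = 0, dt = 0.0078125)), unclass(z))
})

test_that("compute_flows agrees with the equation-table transcription on random states", {
  set.seed(42)
  p <- default_parameters(
    mtc_thx_intens = 0.9, csc_thx_intens = 0.035,
    helper_thx_intens = 0.1, killer_thx_intens = 0.2,
    regulator_thx_intens = -0.9, immuno1_intens = 1e6,
    immuno2_csc_intens = 53, immuno2_ctac_intens = 7
  )
  P <- oracle_param_list(p)
  for (i in 1:300) {
    s <- random_state()
    t <- stats::runif(1, 0, 4000)
    f <- compute_flows(s, p, t)
    o <- oracle_flows(s, P, t)
    expect_equal(unclass(f)[names(o)], o, tolerance = 1e-14)
  }
})

test_that("gain and loss flows are non-negative for any non-negative state", {
  set.seed(7)
  p <- default_parameters(killer_thx_intens = 0.5, immuno2_mtc_intens = 10)
  rates <- c("csc_prol", "csc_loss", "ctac_incr", "ctac_loss", "mtc_incr",
             "mtc_loss", "helper_prol", "helper_loss", "killer_prol",
             "killer_loss", "regulator_prol", "regulator_loss")
  for (i in 1:200) {
    f <- compute_flows(random_state(), p, stats::runif(1, 0, 2000))
    expect_true(all(unclass(f)[rates] >= 0))
  }
})

test_that("flows depend on time only through the pulse schedules", {
  p <- default_parameters()  # all intensities zero
  set.seed(11)
  s <- random_state()
  expect_identical(unclass(compute_flows(s, p, t = 0)),
                   unclass(compute_flows(s, p, t = 450)))
  # with an active schedule the therapy window is visible
  p2 <- apply_overrides(p, list(mtc_thx_intens = 0.9))
  f_in <- compute_flows(s, p2, t = 450)
  f_out <- compute_flows(s, p2, t = 350)
  expect_identical(f_in[["mtc_thx_rate"]], 0.9)
  expect_identical(f_out[["mtc_thx_rate"]], 0)
})
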