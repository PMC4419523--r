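test_that("read current is linear in the read regime and refuses overdrive", {
  p <- device_params()
  expect_equal(read_current(synapse_state(3.5, p), 1.0, p), 3.5)
  expect_equal(read_current(synapse_state(4.2, p), 0, p), 0)
  expect_equal(read_current(synapse_state(p$g_min, p), 1.0, p), 1.5)
  expect_equal(read_current(synapse_state(2, p), -0.5, p), -1)
  expect_error(read_current(synapse_state(2, p), 1.5, p), "read regime")
})

test_that("rate calibration converts printed per-pulse rates to coefficients", {
  p <- device_params()
  expect_equal(calibrate_rate(p, 0.35)$alpha_pot, 0.0875)
  expect_equal(calibrate_rate(p, 0.2)$alpha_pot, 0.05)
  expect_equal(calibrate_rate(p, 0.35)$alpha_dep, 0.0875)
  expect_error(calibrate_rate(p, 0.6), "window")
  # calibration is verified by the update itself: one pulse at g_min moves
  # the conductance by exactly the target rate
  p35 <- calibrate_rate(p, 0.35)
  s <- apply_pulse(synapse_state(p$g_min, p35), p35, 2)
  expect_equal(s$g - p$g_min, 0.35)
})

test_that("pulse updates are threshold-gated, state-dependent and clamped", {
  p <- device_params()
  # low-conductance state: rate inside the printed 0.2-0.5 nA/V window
  d_low <- apply_pulse(synapse_state(p$g_min, p), p, 2)$g - p$g_min
  expect_gte(d_low, p$rate_low[1])
  expect_lte(d_low, p$rate_low[2])
  # near saturation (headroom 0.4): inside the printed 0.02-0.05 window
  g0 <- p$g_max - 0.4
  d_high <- apply_pulse(synapse_state(g0, p), p, 2)$g - g0
  expect_gte(d_high, p$rate_high[1])
  expect_lte(d_high, p$rate_high[2])
  # sub-threshold pulses leave the state bit-identical (disturb off)
  s <- synapse_state(3.5, p)
  for (v in c(1, -1, 0.5, 0)) expect_identical(apply_pulse(s, p, v)$g, 3.5)
  # saturation fixed points
  expect_equal(apply_pulse(synapse_state(p$g_max, p), p, 2)$g, p$g_max)
  expect_equal(apply_pulse(synapse_state(p$g_min, p), p, -2)$g, p$g_min)
  expect_error(apply_pulse(s, p, NaN), "non-finite")
})

test_that("disturb model applies a scaled sub-threshold update when enabled", {
  p <- device_params(disturb_enabled = TRUE, disturb_fraction = 0.5)
  s <- apply_pulse(synapse_state(3.5, p), p, 1)   # half-selected, |v| <= V_R
  expect_equal(s$g, 3.5 + 0.5 * p$alpha_pot * (p$g_max - 3.5))
  p0 <- device_params(disturb_enabled = TRUE, disturb_fraction = 0)
  expect_identical(apply_pulse(synapse_state(3.5, p0), p0, 1)$g, 3.5)
})

test_that("pulse trains are monotone, converge to the bounds, and follow the
           geometric closed form", {
  p <- device_params()
  pot <- pulse_train(synapse_state(p$g_min, p), p, 200, "potentiation")
  dep <- pulse_train(synapse_state(p$g_max, p), p, 200, "depression")
  expect_true(all(diff(pot) >= 0))
  expect_true(all(diff(dep) <= 0))
  expect_equal(pot[200], 5.5, tolerance = 1e-6)
  expect_equal(dep[200], 1.5, tolerance = 1e-6)
  # closed form: g_max - g_n = (1 - alpha)^n (g_max - g_0), exactly
  n <- seq_len(200)
  expect_equal(p$g_max - pot, (1 - p$alpha_pot)^n * (p$g_max - p$g_min))
  # n = 1 is a single pulse
  expect_equal(pulse_train(synapse_state(2, p), p, 1, "potentiation"),
               apply_pulse(synapse_state(2, p), p, 2)$g)
  # symmetry: potentiation from g_min mirrors depression from g_max
  expect_equal(pot - p$g_min, p$g_max - dep)
})

test_that("conductance stays within bounds under random pulse storms", {
  p <- device_params()
  set.seed(11)
  for (rep in 1:20) {
    s <- synapse_state(runif(1, p$g_min, p$g_max), p)
    for (v in runif(50, -3, 3)) {
      s <- apply_pulse(s, p, v)
      expect_gte(s$g, p$g_min)
      expect_lte(s$g, p$g_max)
    }
  }
})

test_that("rate jitter is seeded and reproducible", {
  p <- device_params(jitter_sd = 0.2)
  set.seed(3); a <- pulse_train(synapse_state(p$g_min, p), p, 20, "potentiation")
  set.seed(3); b <- pulse_train(synapse_state(p$g_min, p), p, 20, "potentiation")
  expect_identical(a, b)
  expect_true(all(diff(a) >= 0))
})
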