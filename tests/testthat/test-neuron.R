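test_that("integrator output follows the first-order closed form", {
  np <- neuron_params()
  tt <- seq(0, 0.05, by = 1e-4)
  expect_equal(integrate_output(np, 0, tt), rep(np$v_reset, length(tt)))
  # saturation limit
  expect_equal(integrate_output(np, 116, 10), np$v_reset - np$gain * 116,
               tolerance = 1e-6)
  # early drop is almost linear: first-order Taylor within 1% at t = tau/100
  i <- 58
  t1 <- np$tau / 100
  lin <- np$v_reset - (np$gain * i / np$tau) * t1
  expect_equal(integrate_output(np, i, t1), lin,
               tolerance = 0.01 * (np$v_reset - lin))
  # monotone non-increasing for positive current
  v <- integrate_output(np, 80, tt)
  expect_true(all(diff(v) <= 0))
  expect_error(integrate_output(np, -1, 0.1), "negative")
})

test_that("time to fire matches the closed form and its firing condition", {
  np <- neuron_params()
  # gain * i = 2 V -> v_sat = 2, t = tau log 2
  i2 <- 2 / np$gain
  expect_equal(time_to_fire(np, i2), np$tau * log(2))
  # v_sat exactly at threshold: never fires (strict crossing)
  expect_true(is.na(time_to_fire(np, 1 / np$gain)))
  # fires iff gain * i exceeds the 1 V margin
  margin <- (np$v_reset - np$v_th) / np$gain
  expect_true(is.na(time_to_fire(np, margin * 0.999)))
  expect_false(is.na(time_to_fire(np, margin * 1.001)))
  # strictly decreasing in current on the firing region
  tf <- time_to_fire(np, seq(margin * 1.01, margin * 3, length.out = 40))
  expect_true(all(diff(tf) < 0))
  # cross-check against stepped simulation at 1e-6 relative
  v_step <- np$v_reset
  v_sat <- np$v_reset - np$gain * i2
  dt <- np$tau / 5000
  k <- 0
  while (v_step >= np$v_th) {
    v_step <- v_sat + (v_step - v_sat) * exp(-dt / np$tau)
    k <- k + 1
  }
  # the stepped crossing lands within one step of the closed form
  expect_lt(abs(k * dt - np$tau * log(2)), dt)
})

test_that("stepped integration agrees with the closed-form trace", {
  np <- neuron_params(dt = 10e-3 / 1000)
  xb <- init_crossbar()
  code <- rep(c(1, 0), 16)
  tr <- run_trial(xb, code, np)
  # exponential-integrator stepping of dv/dt = (v_sat - v)/tau
  i <- row_currents(xb, code)[1]
  v_sat <- np$v_reset - np$gain * i
  nsteps <- round(np$t_integrate / np$dt)
  v <- numeric(nsteps + 1)
  v[1] <- np$v_reset
  f <- exp(-np$dt / np$tau)
  for (k in seq_len(nsteps)) v[k + 1] <- v_sat + (v[k] - v_sat) * f
  expect_lt(max(abs(v - tr$traces[seq_len(nsteps + 1), 1])), 1e-6)
})

test_that("a trial resets every neuron and censors fires at the window", {
  np <- neuron_params()
  xb <- init_crossbar()
  code <- rep(c(1, 0), 16)     # uniform crossbar: symmetric input
  tr <- run_trial(xb, code, np)
  expect_true(all(is.na(tr$fires)) || length(unique(tr$fires)) == 1)
  expect_equal(unname(tr$traces[nrow(tr$traces), ]), rep(np$v_reset, 6))
  expect_identical(tr$fires, fire_record(xb, code, np))
  # currents just above margin but crossing after the window: censored
  slow <- neuron_params(t_integrate = 1e-3)
  i_slow <- (slow$v_reset - slow$v_th) / slow$gain * 1.001
  expect_false(is.na(time_to_fire(slow, i_slow)))
  xb2 <- xb; xb2$G[, ] <- 0 + 3.5
  expect_true(all(is.na(fire_record(xb2, code, slow))))
})

test_that("larger currents fire strictly earlier", {
  np <- neuron_params()
  xb <- init_crossbar()
  set.seed(13)
  xb$G <- matrix(runif(192, 1.5, 5.5), 6, 32)
  code <- rbinom(32, 1, 0.6)
  i <- row_currents(xb, code)
  tf <- fire_record(xb, code, np)
  both <- which(!is.na(tf))
  for (a in both) for (b in both)
    if (i[a] > i[b]) expect_lt(tf[a], tf[b])
})
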