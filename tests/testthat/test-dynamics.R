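test_that("decay factor is the exact exponential propagator", {
  expect_equal(decay_factor(2.0, 0), 1)
  expect_equal(decay_factor(2.0, 0.1), exp(-0.05))
  expect_equal(round(decay_factor(2.0, 0.1), 6), 0.951229)
  expect_gte(decay_factor(10, 0.1), decay_factor(0.5, 0.1))
  expect_error(decay_factor(0, 0.1), "tau")
  expect_error(decay_factor(-1, 0.1), "tau")
})

test_that("conductance decay compounds exactly", {
  p <- canonical_params("GrC")
  s <- neuron_state(p)
  s$g_exc <- 1.0
  s1 <- decay_conductance(s, p, 0.1)
  expect_equal(s1$g_exc, exp(-0.2))
  expect_equal(round(s1$g_exc, 5), 0.81873)
  expect_equal(s1$g_inh, 0)

  # k steps of h equal one step of k*h
  sk <- s
  for (i in 1:25) sk <- decay_conductance(sk, p, 0.1)
  expect_equal(sk$g_exc, 1.0 * exp(-25 * 0.1 / p$tau_syn_e))

  s0 <- neuron_state(p)
  expect_equal(decay_conductance(s0, p, 5)$g_exc, 0)
})

test_that("membrane propagator fixes the resting state and the tonic steady state", {
  p <- canonical_params("GrC")  # i_offset = 0
  s <- neuron_state(p)
  for (i in 1:1000) s <- step_membrane(s, p, 0.1)
  expect_equal(s$v, p$v_rest)

  # DCNC steady state under its offset current alone
  d <- canonical_params("DCNC")
  v_inf <- d$v_rest + d$i_offset * d$tau_m / d$cm
  expect_equal(v_inf, -23.26, tolerance = 2e-4)
  # one propagator step from rest matches the closed form
  sd <- neuron_state(d)
  sd <- step_membrane(sd, d, 0.1)
  expect_equal(sd$v, v_inf + (d$v_rest - v_inf) * exp(-0.1 / d$tau_m))
})

test_that("sub-cycling is exact for frozen inputs and n_sc = 1 reduces to one pair", {
  d <- canonical_params("DCNC")
  # pure offset current: propagator composition is exact, so the result is
  # independent of n_sc
  s1 <- neuron_state(d); s8 <- neuron_state(d)
  for (i in 1:50) {
    s1 <- step_subcycled(s1, d, 0.1, 1)$state
    s8 <- step_subcycled(s8, d, 0.1, 8)$state
  }
  expect_equal(s1$v, s8$v, tolerance = 1e-12)

  p <- canonical_params("GrC")
  sa <- neuron_state(p); sa$g_exc <- 0.002
  sb <- sa
  sa <- step_subcycled(sa, p, 0.1, 1)$state
  sb <- decay_conductance(sb, p, 0.1)
  sb <- step_membrane(sb, p, 0.1)
  expect_equal(sa$v, sb$v)
  expect_equal(sa$g_exc, sb$g_exc)
})

test_that("sub-cycled solution converges to the adaptive continuous-time oracle", {
  p <- canonical_params("GrC")
  w <- 2e-3  # strong sub-threshold transient through a fast synapse
  oracle <- ode_oracle(p, spikes_e = 10, w_e = w, t_end = 20)
  run_disc <- function(n_sc) {
    s <- neuron_state(p)
    v <- numeric(200)
    for (t in 1:200) {
      if (t == 101) s$g_exc <- s$g_exc + w  # arrival at 10 ms
      s <- step_subcycled(s, p, 0.1, n_sc)$state
      v[t] <- s$v
    }
    v
  }
  t_grid <- (1:200) * 0.1
  v_ref <- stats::approx(oracle$t, oracle$v, xout = t_grid)$y
  err <- function(n_sc) max(abs(run_disc(n_sc) - v_ref))
  # the transient deflects v by ~19 mV; the default two sub-cycles track the
  # continuous solution to a few percent of that
  expect_lt(err(2), 1.0)
  expect_lte(err(8), err(1) + 1e-9) # refinement does not hurt
})

test_that("threshold, reset and refractory clamp follow the timestep contract", {
  d <- canonical_params("DCNC")
  s <- neuron_state(d)
  spikes <- integer(0)
  vs <- numeric(3000)
  for (t in 1:3000) {
    r <- step_subcycled(s, d, 0.1, 2)
    s <- r$state
    vs[t] <- s$v
    if (r$spiked) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 2)
  # refractory: exactly round(tau_refract/dt) = 37 clamped steps after a spike
  k <- spikes[1]
  expect_true(all(vs[(k):(k + 37)] == d$v_reset))
  expect_gt(vs[k + 38], d$v_reset)
  # inter-spike period matches the closed-form LIF period (~38.7 ms)
  period_ms <- mean(diff(spikes)) * 0.1
  expect_equal(period_ms, 1000 / intrinsic_rate(d), tolerance = 0.005)
  expect_equal(intrinsic_rate(d), 25.8, tolerance = 0.002)
  # first threshold crossing within one timestep of the continuous solution
  v_inf <- d$v_rest + d$i_offset * d$tau_m / d$cm
  t_cross <- d$tau_m * log((v_inf - d$v_rest) / (v_inf - d$v_thresh))
  expect_lte(abs(spikes[1] * 0.1 - t_cross), 0.1 + 1e-9)
})

test_that("a cell that never reaches threshold has intrinsic rate zero", {
  p <- canonical_params("GrC")
  expect_equal(intrinsic_rate(p), 0)
  # GoC sits just above threshold: tonic but below 10 Hz
  g <- canonical_params("GoC")
  expect_gt(intrinsic_rate(g), 0)
  expect_lt(intrinsic_rate(g), 10)
})
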