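test_that("dual-exponential peak time matches the closed form", {
  expect_equal(peak_time(1, 4), 4 / 3 * log(4), tolerance = 1e-12)
  expect_equal(peak_time(1, 4), 1.8484, tolerance = 1e-4)
  expect_equal(peak_time(3, 3), 3)  # alpha-function limit
  # brute-force argmax of the simulated profile agrees within dt
  p <- synapse_params("AMPA", gbar = 1e-3, e_rev = 0, tau_rise = 1,
                      tau_decay = 4)
  tr <- simulate_synapse(p, spike_times = 5, duration = 30, dt = 0.025)
  t_num <- tr$t[which.max(tr$BA)] - 5
  expect_lt(abs(t_num - peak_time(1, 4)), 0.025 + 1e-9)
})

test_that("peak normalization: isolated event reaches gbar * release", {
  for (taus in list(c(1, 4), c(3.7, 212), c(2, 7), c(5, 25))) {
    p <- synapse_params("AMPA", gbar = 2e-3, e_rev = 0, tau_rise = taus[1],
                        tau_decay = taus[2], U1 = 0.2)
    tr <- simulate_synapse(p, spike_times = 10, duration = 10 + 6 * taus[2],
                           dt = 0.025)
    expect_equal(max(tr$g), 2e-3 * 0.2, tolerance = 5e-3)
  }
})

test_that("first-pulse release probability equals U1", {
  p <- synapse_params("AMPA", gbar = 1, e_rev = 0, tau_rise = 1,
                      tau_decay = 4, U1 = 0.2)
  st <- on_spike(synapse_state(), p)
  released <- 1 - st$R_res
  expect_equal(released, 0.2)
  expect_equal(st$U_SE, 0.2)
})

test_that("short-term depression and facilitation behave as parameterized", {
  # depressing cortical synapse: second of two close spikes releases less
  p_dep <- synapse_params("AMPA", gbar = 1, e_rev = 0, tau_rise = 1,
                          tau_decay = 4, tau_rec = 200, tau_facil = 1,
                          U1 = 0.2)
  st <- synapse_state()
  st <- on_spike(st, p_dep); r1 <- 1 - st$R_res
  for (i in 1:200) st <- advance_synapse(st, p_dep, 0.025)  # 5 ms
  before <- st$R_res
  st <- on_spike(st, p_dep); r2 <- before - st$R_res
  expect_lt(r2, r1)

  # facilitating striato-pallidal synapse: paired-pulse ratio > 1 at 20 ms
  p_fac <- synapse_params("GABA_A", gbar = 1, e_rev = -80, tau_rise = 2,
                          tau_decay = 5, tau_rec = 1, tau_facil = 200,
                          U1 = 0.3)
  tr <- simulate_synapse(p_fac, spike_times = c(10, 30), duration = 60,
                         dt = 0.025)
  peak1 <- max(tr$g[tr$t < 30])
  peak2 <- max(tr$g[tr$t >= 30])
  expect_gt(peak2 / peak1, 1)  # paired-pulse ratio above one
})

test_that("between-event dynamics relax to the rest state", {
  p <- synapse_params("GABA_B", gbar = 1, e_rev = -95, tau_rise = 5,
                      tau_decay = 25, tau_rec = 400, U1 = 0.2)
  st <- on_spike(synapse_state(), p)
  for (i in 1:40000) st <- advance_synapse(st, p, 0.5)  # 20 s
  expect_equal(st$A, 0, tolerance = 1e-8)
  expect_equal(st$B, 0, tolerance = 1e-8)
  expect_equal(st$R_res, 1, tolerance = 1e-8)
  expect_equal(st$U_SE, 0, tolerance = 1e-8)
  expect_equal(st$G, 0, tolerance = 1e-6)
})

test_that("resource recovery follows its exponential time constant", {
  p <- synapse_params("AMPA", gbar = 1, e_rev = 0, tau_rise = 1,
                      tau_decay = 4, tau_rec = 100, U1 = 1)
  st <- on_spike(synapse_state(), p)   # full depletion: U1 = 1
  expect_equal(st$R_res, 0)
  for (i in 1:1000) st <- advance_synapse(st, p, 0.1)  # t = tau_rec
  expect_equal(st$R_res, 1 - exp(-1), tolerance = 1e-6)
})

test_that("G-protein cascade has steady state K3 b / K4 under clamped drive", {
  p <- synapse_params("GABA_B", gbar = 1, e_rev = -95, tau_rise = 5,
                      tau_decay = 25, K3 = 0.098, K4 = 6.25e-3)
  b <- 0.4
  st <- synapse_state()
  for (i in 1:40000) {
    st$A <- 0; st$B <- b        # clamp the gating variable
    st <- advance_synapse(st, p, 0.25)
  }
  expect_equal(st$G, 0.098 * b / 6.25e-3, tolerance = 1e-4)
})

test_that("NMDA magnesium block matches its closed form and limits", {
  expect_equal(mg_block(0), 1 / (1 + 1 / 3.57))
  expect_equal(mg_block(0), 0.7812, tolerance = 1e-4)
  expect_gt(mg_block(100), 0.995)
  expect_lt(mg_block(-150), 1e-3)
  p <- synapse_params("NMDA", gbar = 1e-3, e_rev = 0, tau_rise = 3.7,
                      tau_decay = 80)
  st <- synapse_state(); st$B <- 0.5
  expect_equal(ionotropic_current(st, p, 0), 0)  # reversal
})

test_that("Hill gating of the GABA-B conductance", {
  expect_equal(hill_gate(1.4, Kd = 1.4, n = 4), 0.5)
  expect_equal(hill_gate(0), 0)
  expect_equal(hill_gate(14, Kd = 1.4, n = 4), 1e4 / (1e4 + 1))
  p <- synapse_params("GABA_B", gbar = 2e-3, e_rev = -95, tau_rise = 5,
                      tau_decay = 25)
  st <- synapse_state(); st$G <- 1.4
  expect_equal(gabab_current(st, p, -75), 2e-3 * 0.5 * 20)
})

test_that("resources are conserved through event-driven stimulation", {
  set.seed(3)
  p <- synapse_params("AMPA", gbar = 1, e_rev = 0, tau_rise = 1,
                      tau_decay = 4, tau_rec = 150, tau_facil = 50,
                      U1 = 0.35)
  st <- synapse_state()
  for (i in 1:300) {
    if (runif(1) < 0.2) st <- on_spike(st, p)
    st <- advance_synapse(st, p, runif(1, 0.1, 3))
    expect_true(st$R_res >= 0 && st$R_res <= 1)
    expect_true(st$U_SE >= 0 && st$U_SE <= 1)
  }
})

test_that("GABA-B conductance depresses over a 10-pulse 50 Hz train", {
  p <- projection_params()$GPE_STN.GABA_B
  spikes <- seq(10, by = 20, length.out = 10)
  tr <- simulate_synapse(p, spikes, duration = 400, dt = 0.05)
  # G-peaks after early pulses exceed the increments late in the train
  g_inc <- diff(range(tr$G[tr$t < 50])) # early rise
  late_inc <- max(tr$G[tr$t >= 190 & tr$t < 210]) -
    min(tr$G[tr$t >= 190 & tr$t < 210])
  expect_lt(late_inc, g_inc)
  # per-pulse B-A jumps shrink (short-term depression of release)
  ba_peaks <- vapply(seq_along(spikes), function(i)
    max(tr$BA[tr$t >= spikes[i] & tr$t < spikes[i] + 20]), numeric(1))
  expect_lt(ba_peaks[10], ba_peaks[1])
})

test_that("projection tables carry the tabulated kinetics", {
  pp <- projection_params(calibration = NULL)
  expect_equal(pp$CTX_STN.AMPA$gbar, 4.44e-3)
  expect_equal(pp$CTX_STN.NMDA_slow$tau_decay, 212)
  expect_equal(pp$GPE_STN.GABA_A$gbar, 18e-3)
  expect_equal(pp$GPE_STN.GABA_B$K4, 6.25e-3)
  expect_equal(pp$iMSN_GPE.GABA_A$tau_facil, 200)
  expect_equal(pp$GPE_GPE.GABA_A$delay, 0.5)
  # calibration multiplies whole projections by prefix
  cal <- projection_params()
  expect_equal(cal$STN_GPE.AMPA$gbar, 3.75e-4 * 2)
  expect_equal(cal$CTX_STN.NMDA_fast$gbar, 5.04e-3 * 0.07)
})
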