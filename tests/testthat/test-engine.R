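test_that("a passive compartment relaxes with its membrane time constant", {
  # c_m / g_m = 1e-6 / 5e-5 = 20 ms; start 10 mV above rest
  flat <- passive_chain(n = 1, v0 = -50)
  out <- run_flat(flat, duration = 40)
  t <- out$t_rec
  v_num <- out$v_soma[, 1]
  v_ref <- -60 + 10 * exp(-t / 20)
  err <- max(abs(v_num - v_ref)) / 10
  # first-order backward Euler bound: relative error ~ t dt / (2 tau^2),
  # about 0.13% at the end of this trace
  expect_lt(err, 2e-3)
})

test_that("equal-potential coupled compartments stay isopotential", {
  flat <- passive_chain(n = 2, v0 = -45)
  out <- run_flat(flat, duration = 30)
  expect_equal(out$v_final[1], out$v_final[2], tolerance = 1e-12)
  # and both follow the isopotential passive solution
  expect_equal(out$v_final[1], -60 + 15 * exp(-30 / 20), tolerance = 1e-3)
})

test_that("passive chain steady state matches the analytic linear solve", {
  n <- 3
  iclamp <- c(0.05, 0, 0)  # nA into the first compartment
  flat <- passive_chain(n = n, v0 = -60, iclamp = iclamp)
  out <- run_flat(flat, duration = 600)
  # analytic: G v = b with axial coupling and leak conductances
  gl <- flat$g_leak_uS[1]; gax <- flat$g_ax_uS[2]
  G <- matrix(0, n, n)
  for (i in 1:n) G[i, i] <- gl
  for (i in 2:n) {
    G[i, i] <- G[i, i] + gax; G[i - 1, i - 1] <- G[i - 1, i - 1] + gax
    G[i, i - 1] <- -gax; G[i - 1, i] <- -gax
  }
  b <- gl * rep(-60, n) + iclamp
  v_ref <- solve(G, b)
  expect_equal(out$v_final, v_ref, tolerance = 1e-6)
})

test_that("seeded runs are bit-identical, different seeds differ", {
  net <- micro_network(seed = 4, condition = "parkinsonian")
  cfg <- micro_config(seed = 4, duration = 500, warmup = 100)
  a <- run_network(net, cfg)
  b <- run_network(net, cfg)
  expect_identical(a$v_soma, b$v_soma)
  expect_identical(a$spikes, b$spikes)
  cfg2 <- micro_config(seed = 5, duration = 500, warmup = 100)
  c <- run_network(net, cfg2)
  expect_false(identical(a$v_soma, c$v_soma))
})

test_that("initial voltages are drawn inside the class intervals", {
  cfg <- micro_config()
  set.seed(1)
  v <- initialize_voltages(c(rep("STN", 500), rep("GPe", 500)), cfg)
  expect_true(all(v[1:500] >= -70 & v[1:500] <= -60))
  expect_true(all(v[501:1000] >= -73 & v[501:1000] <= -63))
})

test_that("spike detection finds upward crossings with a refractory guard", {
  dt <- 0.05
  expect_equal(detect_spikes(rep(-70, 100), dt), numeric(0))
  # one synthetic action potential crossing -10 mV once
  t <- seq(0, 10, by = dt)
  v <- -70 + 90 * exp(-((t - 5) / 0.5)^2)
  sp <- detect_spikes(v, dt)
  expect_equal(length(sp), 1L)
  expect_lt(abs(sp - 4.6), 0.3)
  # 20 Hz periodic spiking over 1 s gives 20 spikes
  v20 <- rep(-70, 20000)
  for (k in 0:19) v20[k * 1000 + 10 + 1:5] <- 20
  expect_equal(length(detect_spikes(v20, dt)), 20L)
  # a plateau above threshold is a single event
  vpl <- c(rep(-70, 10), rep(0, 400), rep(-70, 10))
  expect_equal(length(detect_spikes(vpl, dt)), 1L)
})

test_that("the warm-up interval is discarded from all records", {
  net <- micro_network(seed = 6)
  cfg <- micro_config(seed = 6, duration = 700, warmup = 300)
  sim <- run_network(net, cfg)
  expect_equal(sim$duration, 400)
  expect_true(all(unlist(sim$spikes) >= 0 & unlist(sim$spikes) <= 400))
  expect_equal(nrow(sim$v_soma),
               length(seq(300 / 0.025, 700 / 0.025 - 1, by = 2)))
  expect_error(engine_config(duration = 500, warmup_discard = 600),
               "warmup")
})

test_that("halving the step leaves early spikes and rates converged", {
  # single STN cell driven by a constant somatic current. Early spike times
  # agree to a fraction of a millisecond; over a full second the
  # first-order integrator accumulates limit-cycle phase drift, so the
  # long-horizon comparison is on counts, not on individual spike times.
  net <- build_network(n_stn = 1, n_gpe = 2, n_ctx = 2, n_imsn = 2,
                       afferents = list(CTX_STN = 1L, GPE_STN = 1L,
                                        STN_GPE = 1L, GPE_GPE = 1L,
                                        iMSN_GPE = 1L),
                       morph_stn = build_reduced_morphology(
                         "STN", segments_per_branch = 4),
                       morph_gpe = build_reduced_morphology(
                         "GPe", segments_per_branch = 4), seed = 1)
  net$syn$gbar[] <- 0
  net$rates <- list(CTX = 0, iMSN = 0, STN_surrogate = 0, GPe_surrogate = 0)
  run_dt <- function(dt) {
    cfg <- engine_config(dt = dt, duration = 1000, warmup_discard = 0,
                         seed = 1, noise_sd_stn = 0, noise_sd_gpe = 0,
                         record_every = 1L)
    gen <- list(STN_surrogate = list(), GPe_surrogate = list(),
                CTX = rep(list(numeric(0)), 2),
                iMSN = rep(list(numeric(0)), 2))
    flat <- stngpe:::.flatten_network(
      net, cfg, gen, v_init = c(-65, -68, -68),
      rec_cells = list(STN = 1L, GPe = 1L),
      iclamp_list = list("1" = 0.08))
    out <- run_flat(flat, duration = 1000, dt = dt, seed = 1)
    out$spikes[[1]]
  }
  s1 <- run_dt(0.025)
  s2 <- run_dt(0.0125)
  expect_gt(length(s1), 5)
  expect_lt(abs(s1[1] - s2[1]), 0.5)
  expect_lt(abs(length(s1) - length(s2)) / length(s1), 0.05)
})

test_that("biophysical cells fire and traces stay bounded in a network run", {
  net <- micro_network(seed = 2, condition = "parkinsonian")
  sim <- run_network(net, micro_config(seed = 2))
  expect_false(sim$error)
  expect_true(all(abs(sim$v_soma) < 200))
  expect_gt(sum(lengths(sim$spikes)), 10)
  # record export round-trip
  d <- withr::local_tempdir()
  export_record(sim, d)
  expect_true(file.exists(file.path(d, "spikes.txt")))
  expect_true(file.exists(file.path(d, "v_soma.csv")))
})
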