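stn <- stn_channels()
gpe <- gpe_channels()

test_that("printed half-activation points are reproduced", {
  # fast rectifier activation: half-open at -5 mV
  expect_equal(steady_state(stn$Kv31$gates[[1]], v = -5), 0.5)
  # HCN activation: half-open at -75 mV
  expect_equal(steady_state(stn$HCN$gates[[1]], v = -75), 0.5)
})

test_that("linoid rate singularity resolves to the analytic limit c*k", {
  g <- gate_spec("m", 2L, "rate", params = list(
    alpha = rate_primitive("linoid", c = 0.32, theta = 13.1, k = 4),
    beta = rate_primitive("linoid", c = -0.28, theta = 40.1, k = -5)))
  a_at <- stngpe:::.eval_rate_primitive(g$params$alpha, 13.1)
  expect_equal(a_at, 0.32 * 4)
  # continuity across the singular point
  a_lo <- stngpe:::.eval_rate_primitive(g$params$alpha, 13.1 - 1e-6)
  a_hi <- stngpe:::.eval_rate_primitive(g$params$alpha, 13.1 + 1e-6)
  expect_equal(a_lo, 1.28, tolerance = 1e-6)
  expect_equal(a_hi, 1.28, tolerance = 1e-6)
})

test_that("tabulated constant time constants are honoured", {
  expect_equal(time_constant(gpe$NaF$gates[[1]], v = c(-80, -40, 0)),
               rep(0.028, 3))
  expect_equal(time_constant(gpe$Kv2$gates[[2]], v = c(-90, 10)),
               rep(3400, 3)[1:2])
})

test_that("sigmoid-table time constants stay within [tau0, tau1]", {
  g <- gpe$NaF$gates[[2]]  # tau0 = 0.025, tau1 = 4
  v <- seq(-120, 60, by = 0.5)
  tau <- time_constant(g, v)
  expect_true(all(tau > 0))
  expect_true(all(tau <= 4 + 1e-9))
  expect_true(all(tau >= 0.025 - 1e-9))
  # interior value strictly between the extremes at the tau midpoint
  tmid <- time_constant(g, -43)
  expect_gt(tmid, 0.025); expect_lt(tmid, 4)
})

test_that("channel current follows the ohmic gate product", {
  expect_equal(channel_current(0, c(0.5, 0.2), c(2L, 1L), -30, 50), 0)
  expect_equal(channel_current(1e-3, c(1, 1), c(2L, 1L), 10, 0), 1e-2)
  # m = 0.5, h = 0.2, exponents (2, 1): open fraction 0.05
  expect_equal(channel_current(2e-3, c(0.5, 0.2), c(2L, 1L), -20, 50),
               2e-3 * 0.05 * (-70))
})

test_that("gate updates relax exactly to steady state at frozen voltage", {
  n <- stn$KDR$gates[[1]]
  v <- 0; dt <- 0.025
  x0 <- 0
  xinf <- steady_state(n, v)
  tau <- time_constant(n, v)
  x <- x0
  for (i in 1:10) x <- advance_gate(n, x, v = v, dt = dt)
  expect_equal(x, xinf + (x0 - xinf) * exp(-10 * dt / tau), tolerance = 1e-9)
  # fixed point and long-time limit
  expect_equal(advance_gate(n, xinf, v = v, dt = 0.5), xinf)
  expect_equal(advance_gate(n, 0.1, v = v, dt = 1e6), xinf)
})

test_that("calcium Nernst potential matches the closed form", {
  expect_equal(nernst_calcium(2, 2), 0)
  expect_equal(nernst_calcium(1e-4, 2, 308.15), 131.48, tolerance = 1e-3)
  d <- nernst_calcium(1e-4, 4, 308.15) - nernst_calcium(1e-4, 2, 308.15)
  expect_equal(d, 1e3 * 8.314 * 308.15 / (2 * 96485) * log(2),
               tolerance = 1e-12)
  expect_error(nernst_calcium(0, 2), "positive")
})

test_that("shell calcium relaxes to rest with tau_ca and stays positive", {
  ca0 <- 1e-4
  expect_equal(update_calcium(ca0, 0, tau_ca = 185.7, ca_rest = ca0,
                              dt = 1), ca0)
  # closed-form relaxation from 2x rest after exactly one time constant
  ca <- 2 * ca0
  steps <- 1857; dt <- 0.1
  for (i in seq_len(steps)) ca <- update_calcium(ca, 0, tau_ca = 185.7,
                                                 ca_rest = ca0, dt = dt)
  expect_equal(ca, ca0 + ca0 * exp(-1), tolerance = 1e-6)
  # strong outward flux cannot push the concentration negative
  ca2 <- update_calcium(1e-4, 10, tau_ca = 1, ca_rest = 1e-4, dt = 1)
  expect_gt(ca2, 0)
})

test_that("simple sigmoid gates are monotone over the physiological range", {
  v <- seq(-100, 40, by = 1)
  checks <- list(
    list(stn$Kv31$gates[[1]], +1), list(stn$HCN$gates[[1]], -1),
    list(gpe$NaF$gates[[1]], +1), list(gpe$NaF$gates[[2]], -1),
    list(gpe$Kv3$gates[[1]], +1), list(gpe$HCNf$gates[[1]], -1),
    list(gpe$KCNQ$gates[[1]], +1))
  for (chk in checks) {
    x <- steady_state(chk[[1]], v = v)
    expect_true(all(diff(x) * chk[[2]] >= 0), label = chk[[1]]$name)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("rate form and inf/tau form are consistent", {
  v <- seq(-100, 40, by = 2.5)
  for (g in list(stn$NaF$gates[[1]], stn$NaF$gates[[2]],
                 stn$KDR$gates[[1]], stn$CaT$gates[[1]])) {
    ab <- stngpe:::.gate_alpha_beta(g, v)
    expect_equal(steady_state(g, v = v), ab$alpha / (ab$alpha + ab$beta))
    expect_equal(time_constant(g, v), 1 / (ab$alpha + ab$beta),
                 tolerance = 1e-9)
  }
})

test_that("gate values never leave [0, 1] under random updates", {
  set.seed(11)
  gates <- c(lapply(setdiff(names(stn), "calcium"),
                    function(nm) stn[[nm]]$gates[[1]]),
             lapply(setdiff(names(gpe), "calcium"),
                    function(nm) gpe[[nm]]$gates[[1]]))
  for (g in gates) {
    if (g$form == "wang_sd" || g$depends_on == "calcium") next
    x <- runif(1)
    vs <- runif(2000, -120, 60)
    dts <- runif(2000, 0.005, 1)
    for (i in seq_along(vs)) {
      x <- advance_gate(g, x, v = vs[i], dt = dts[i])
      if (x < 0 || x > 1) break
    }
    expect_true(x >= 0 && x <= 1, label = g$name)
  }
})

test_that("coupled T-type inactivation steady state conserves probability", {
  g <- stn$CaT$gates[[2]]
  v <- seq(-110, 0, by = 5)
  s <- steady_state(g, v = v)
  expect_true(all(s >= 0 & s <= 1))
  # de-inactivated at hyperpolarized, inactivated at depolarized potentials
  expect_gt(steady_state(g, v = -100), 0.9)
  expect_lt(steady_state(g, v = -40), 0.1)
})

test_that("calcium-dependent gates require positive calcium", {
  w <- stn$sKCa$gates[[1]]
  expect_error(steady_state(w, ca = 0), "ca > 0")
  expect_gt(steady_state(w, ca = 1), steady_state(w, ca = 1e-4))
})

test_that("channel config serialization round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_channel_config(stn, p)
  doc <- yaml::read_yaml(p)
  expect_equal(doc$NaF$gbar_by_region$soma, 14.83e-3)
  expect_equal(doc$calcium$tau_ca, 185.7)
})
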