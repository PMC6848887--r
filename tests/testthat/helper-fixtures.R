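# shared fixtures: micro network + engine configs small enough for unit tests

micro_network <- function(seed = 7L, condition = "control") {
  net <- build_network(
    n_stn = 5, n_gpe = 10, n_ctx = 50, n_imsn = 100,
    afferents = list(CTX_STN = 10L, GPE_STN = 4L, STN_GPE = 5L,
                     GPE_GPE = 4L, iMSN_GPE = 10L),
    morph_stn = build_reduced_morphology("STN", segments_per_branch = 4),
    morph_gpe = build_reduced_morphology("GPe", segments_per_branch = 4),
    seed = seed)
  if (condition == "parkinsonian") net <- apply_state(net)
  net
}

micro_config <- function(seed = 7L, duration = 1200, warmup = 400, ...) {
  engine_config(duration = duration, warmup_discard = warmup, seed = seed, ...)
}

# minimal hand-built flat network for direct engine tests: n passive
# compartments in a chain, no channels, no synapses
passive_chain <- function(n = 1, c_m = 1, g_m = 5e-5, e_m = -60, R_a = 150,
                          length = 20, diameter = 20, v0 = -50,
                          iclamp = numeric(n), noise_sd = 0, dt = 0.025) {
  area_cm2 <- pi * diameter * length * 1e-8
  half_r <- R_a * (length * 1e-4 / 2) / (pi * (diameter * 1e-4 / 2)^2)
  g_ax <- c(0, rep(1e6 / (2 * half_r), n - 1))
  gr <- stngpe:::.vgrid()
  list(
    parent = c(-1L, seq_len(n - 1) - 1L)[seq_len(n)],
    cap_nF = rep(c_m * area_cm2 * 1e3, n),
    g_ax_uS = g_ax,
    g_leak_uS = rep(g_m * area_cm2 * 1e6, n),
    e_leak = rep(e_m, n),
    comp_cell = rep(0L, n),
    ca_rest = rep(1e-4, n), ca_taufac = rep(0, n), ca_tau = rep(1, n),
    ca_flux = rep(0, n), nernst_fac = rep(13.3, n), ca_out = rep(2, n),
    iclamp = iclamp,
    soma_comp = 0L, noise_sd = noise_sd, v_init = v0,
    gate_specs = list(), grid_v0 = gr$v0, grid_dv = gr$dv, grid_n = gr$n,
    ch_comp = integer(0), ch_g_uS = numeric(0), ch_erev = numeric(0),
    ch_use_ca_erev = integer(0), ch_is_ca = integer(0),
    ch_ngates = integer(0),
    ch_gspec = matrix(0L, 0, 3), ch_gexp = matrix(0L, 0, 3),
    sy_comp = integer(0), sy_type = integer(0), sy_g_uS = numeric(0),
    sy_erev = numeric(0), sy_afac = numeric(0), sy_bfac = numeric(0),
    sy_rfac = numeric(0), sy_ufac = numeric(0), sy_U1 = numeric(0),
    sy_fpeak = numeric(0), sy_k4fac = numeric(0), sy_k3term = numeric(0),
    sy_kd = numeric(0), sy_nhill = numeric(0), sy_delay_steps = integer(0),
    sy_source = integer(0), sy_rec_slot = integer(0),
    sy_rec_sign = integer(0),
    n_sources = 1L, n_rec_slots = 0L,
    gen_event_step = integer(0), gen_event_source = integer(0))
}

run_flat <- function(flat, duration, dt = 0.025, seed = 1, record_every = 1L,
                     spike_threshold = -10) {
  stngpe:::.engine_run(flat, list(
    dt = dt, n_steps = as.integer(round(duration / dt)), record_start = 0L,
    record_every = as.integer(record_every),
    spike_threshold = spike_threshold,
    refrac_steps = as.integer(round(1 / dt)), seed = seed))
}

# von Mises sampler (Best & Fisher 1979), enough for the phase-pipeline oracle
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}
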