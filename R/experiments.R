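#' Reproducible simulation experiments
#'
#' Runners for the network's characteristic experiments: conductance sweeps
#' of individual projections in the autonomous network, the frequency
#' response to oscillatory cortical bursting, and the cortico-striatal
#' phase-offset protocol. Each runner repeats every condition over a set of
#' seeds and aggregates the analysis results.
#'
#' Two problem-size profiles are provided: `"full"` (50 STN + 100 GPe
#' biophysical cells, 1000 CTX + 2000 iMSN generators, 6 s simulated with the
#' first 2 s discarded) and `"desk"` (10 + 20 cells, 200 + 400 generators,
#' 3 s with 1 s discarded), which keeps sweeps tractable on a single core
#' while preserving the in-degrees and population ratios.
#'
#' @name experiments
NULL

#' Simulation profile
#' @param profile `"desk"` or `"full"`.
#' @return list of population sizes and durations.
#' @export
sim_profile <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full")
    list(n_stn = 50L, n_gpe = 100L, n_ctx = 1000L, n_imsn = 2000L,
         duration = 6000, warmup = 2000)
  else
    list(n_stn = 10L, n_gpe = 20L, n_ctx = 200L, n_imsn = 400L,
         duration = 3000, warmup = 1000, segments = 4L)
}

#' Build the baseline parkinsonian network for a profile
#' @param profile `"desk"` or `"full"`.
#' @param seed integer seed.
#' @param condition `"parkinsonian"` (default) or `"control"`.
#' @return a `stngpe_network`.
#' @export
baseline_network <- function(profile = "desk", seed = 1L,
                             condition = c("parkinsonian", "control")) {
  condition <- match.arg(condition)
  pr <- sim_profile(profile)
  segs <- if (is.null(pr$segments)) 6L else pr$segments
  net <- build_network(n_stn = pr$n_stn, n_gpe = pr$n_gpe, n_ctx = pr$n_ctx,
                       n_imsn = pr$n_imsn, seed = seed,
                       morph_stn = build_reduced_morphology(
                         "STN", segments_per_branch = segs),
                       morph_gpe = build_reduced_morphology(
                         "GPe", segments_per_branch = segs))
  if (condition == "parkinsonian") net <- apply_state(net)
  net
}

#' Engine configuration for a profile
#' @param profile `"desk"` or `"full"`.
#' @param seed integer seed.
#' @param ... overrides passed to [engine_config()].
#' @export
profile_config <- function(profile = "desk", seed = 1L, ...) {
  pr <- sim_profile(profile)
  args <- utils::modifyList(
    list(duration = pr$duration, warmup_discard = pr$warmup, seed = seed),
    list(...))
  do.call(engine_config, args)
}

#' Named sweep presets
#'
#' The figure-level experiments of the study as sweep specifications:
#' `ctx_stn` (cortical drive 0.2/0.7/1.3), `gpe_gpe` (collateral inhibition
#' 0.33/2.0), `gpe_stn` (pallido-subthalamic inhibition 0.33/2.0),
#' `gabaa_gabab` (GABA-A scale sweep with GABA-B halved),
#' `frequency_response` (3-60 Hz cortical bursting),
#' `ctx_scale_20hz` (cortical conductance sweep under 20 Hz bursting) and
#' `phase_offset` (cortico-striatal offsets in 45 degree steps).
#' @return named list of preset definitions.
#' @export
sweep_presets <- function() {
  list(
    ctx_stn = list(projection = "CTX_STN", values = c(0.2, 0.7, 1.3)),
    gpe_gpe = list(projection = "GPE_GPE", values = c(0.33, 2.0)),
    gpe_stn = list(projection = "GPE_STN", values = c(0.33, 2.0)),
    gabaa_gabab = list(projection = "GPE_STN.GABA_A",
                       values = c(1, 2, 4, 6), gabab_scale = 0.5),
    frequency_response = list(freqs = seq(3, 60, by = 3)),
    ctx_scale_20hz = list(projection = "CTX_STN",
                          values = seq(0.1, 1.3, by = 0.1), osc_freq = 20),
    phase_offset = list(offsets = seq(0, 315, by = 45), osc_freq = 20)
  )
}

#' Run a projection-conductance sweep on the autonomous network
#'
#' One simulation per (scale value, seed) on the baseline parkinsonian
#' network with Poisson inputs; reports rates, dominant frequency, phase
#' vectors, burst metrics and E/I accounting per run.
#'
#' @param projection projection prefix or parameter-set name (see
#'   [scale_projection()]).
#' @param values conductance scale factors (non-empty).
#' @param seeds integer vector of seeds.
#' @param profile `"desk"` or `"full"`.
#' @param gabab_scale optional additional fixed scale on the GPe->STN GABA-B
#'   conductance (for the GABA-A:GABA-B ratio protocol).
#' @param center optional fixed phase band centre, Hz.
#' @return data frame with one row per run, class `stngpe_sweep`.
#' @export
run_sweep <- function(projection, values, seeds = 1:3, profile = "desk",
                      gabab_scale = NULL, center = NULL) {
  if (!length(values)) stop("empty sweep value list")
  rows <- list()
  for (seed in seeds) {
    net0 <- baseline_network(profile, seed = seed)
    if (!is.null(gabab_scale))
      net0 <- scale_projection(net0, "GPE_STN.GABA_B", gabab_scale)
    for (val in values) {
      net <- scale_projection(net0, projection, val)
      sim <- run_network(net, profile_config(profile, seed = seed))
      an <- analyze_sim(sim, center = center)
      ei <- tryCatch(ei_accounting(sim, "STN"), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        value = val, seed = seed,
        rate_stn = mean(an$rates$STN), rate_gpe = mean(an$rates$GPe),
        peak_freq = an$center,
        vlen_stn = .or_na(an$vectors$STN$pop_length),
        vlen_gpe = .or_na(an$vectors$GPe$pop_length),
        vang_stn = .or_na(an$vectors$STN$pop_angle),
        vang_gpe = .or_na(an$vectors$GPe$pop_angle),
        cv_isi_stn = an$bursts$STN$median_cv_isi,
        intra_rate_stn = .or_na(an$bursts$STN$median_intra_rate),
        ei_stn = .or_na(ei$ei_ratio),
        diverged = sim$error)
    }
  }
  structure(do.call(rbind, rows), class = c("stngpe_sweep", "data.frame"),
            projection = projection)
}

.or_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else x

#' Frequency response to oscillatory cortical bursting
#'
#' Runs the parkinsonian network with oscillatory-bursting cortical trains at
#' each frequency and reports STN/GPe band power in a 5 Hz band centred on
#' the input frequency, plus population vector lengths against the input
#' phase. Burst size is shortened when the oscillation period cannot contain
#' the default burst.
#'
#' @param freqs input frequencies, Hz.
#' @param seeds integer seeds.
#' @param profile `"desk"` or `"full"`.
#' @return data frame, one row per (frequency, seed).
#' @export
frequency_response <- function(freqs = seq(3, 60, by = 3), seeds = 1:3,
                               profile = "desk") {
  stopifnot(all(freqs > 0))
  rows <- list()
  for (seed in seeds) {
    net <- baseline_network(profile, seed = seed)
    for (f in freqs) {
      sim <- .run_with_osc(net, profile, seed, ctx_freq = f)
      row <- .osc_metrics(sim, f)
      rows[[length(rows) + 1]] <- cbind(data.frame(freq = f, seed = seed), row)
    }
  }
  do.call(rbind, rows)
}

# oscillatory run helper: CTX (and optionally iMSN) bursting inputs
.run_with_osc <- function(net, profile, seed, ctx_freq, imsn_freq = NULL,
                          imsn_offset = 0, config = NULL) {
  if (is.null(config)) config <- profile_config(profile, seed = seed)
  period <- 1000 / ctx_freq
  max_spk <- max(2L, min(7L, floor(period / 6) + 1L))
  set.seed(seed * 1000L + round(ctx_freq))
  ctx <- oscillatory_burst_trains(
    osc_burst_spec(net$sizes$CTX, background_rate = net$rates$CTX,
                   osc_frequency = ctx_freq,
                   spikes_per_burst = c(min(4L, max_spk), max_spk)),
    config$duration)
  inputs <- list(CTX = ctx)
  if (!is.null(imsn_freq)) {
    inputs$iMSN <- phase_offset_trains(
      osc_burst_spec(net$sizes$iMSN, background_rate = net$rates$iMSN,
                     osc_frequency = imsn_freq),
      config$duration, offset_degrees = imsn_offset)
  }
  sim <- run_network(net, config, inputs = inputs)
  sim$osc <- list(ctx_freq = ctx_freq, warmup = config$warmup_discard,
                  ctx_trains = ctx, imsn_trains = inputs$iMSN,
                  imsn_offset = imsn_offset)
  sim
}

# metrics for oscillatory runs: band power at the input frequency and
# phase locking against the cortical input oscillation's phase
.osc_metrics <- function(sim, f) {
  an <- analyze_sim(sim, center = f)
  # reference phase from the pooled cortical pseudo-voltage
  warm <- sim$osc$warmup
  ctx_cut <- lapply(sim$osc$ctx_trains,
                    function(s) s[s >= warm] - warm)
  pv <- rowMeans(pseudo_voltage(ctx_cut, sim$duration, dt = 1000 / sim$fs))
  ph <- tryCatch(instantaneous_phase(pv, sim$fs, f), error = function(e) NULL)
  vec <- function(p) {
    if (is.null(ph)) return(list(pop_length = NA_real_, pop_angle = NA_real_))
    tryCatch(phase_vectors(sim$spikes[sim$cellpop == p], ph),
             error = function(e) list(pop_length = NA_real_,
                                      pop_angle = NA_real_))
  }
  vs <- vec("STN"); vg <- vec("GPe")
  data.frame(
    power_stn = band_power(an$psd$STN, f), power_gpe = band_power(an$psd$GPe, f),
    vlen_stn = vs$pop_length, vlen_gpe = vg$pop_length,
    vang_stn = vs$pop_angle, vang_gpe = vg$pop_angle,
    rate_stn = mean(an$rates$STN), rate_gpe = mean(an$rates$GPe),
    diverged = sim$error)
}

#' Cortical-conductance sweep under 20 Hz oscillatory input
#'
#' Scales the cortico-subthalamic conductance while driving the network with
#' 20 Hz (by default) oscillatory cortical bursting; reports the STN PSD
#' power at the input frequency per scale.
#'
#' @param scales conductance scale factors.
#' @param seeds integer seeds.
#' @param osc_freq input frequency, Hz.
#' @param profile `"desk"` or `"full"`.
#' @return data frame, one row per (scale, seed).
#' @export
ctx_scale_experiment <- function(scales = seq(0.1, 1.3, by = 0.1),
                                 seeds = 1:3, osc_freq = 20,
                                 profile = "desk") {
  rows <- list()
  for (seed in seeds) {
    net0 <- baseline_network(profile, seed = seed)
    for (sc in scales) {
      net <- scale_projection(net0, "CTX_STN", sc)
      sim <- .run_with_osc(net, profile, seed, ctx_freq = osc_freq)
      row <- .osc_metrics(sim, osc_freq)
      rows[[length(rows) + 1]] <- cbind(data.frame(scale = sc, seed = seed),
                                        row)
    }
  }
  do.call(rbind, rows)
}

#' Cortico-striatal phase-offset experiment
#'
#' Drives the parkinsonian network with simultaneous 20 Hz oscillatory
#' cortical and striatal bursting; the striatal burst onset is offset from
#' the cortical one in phase steps. The facilitating striato-pallidal
#' synapses are compensated by reducing their conductance to 40% of baseline
#' whenever striatal bursting is applied, keeping GPe rates physiological.
#'
#' @param offsets phase offsets, degrees in `[0, 360)`.
#' @param seeds integer seeds.
#' @param osc_freq oscillation frequency, Hz.
#' @param profile `"desk"` or `"full"`.
#' @param imsn_gbar_scale compensation scale on iMSN->GPe conductance.
#' @return data frame, one row per (offset, seed).
#' @export
phase_offset_experiment <- function(offsets = seq(0, 315, by = 45),
                                    seeds = 1:3, osc_freq = 20,
                                    profile = "desk",
                                    imsn_gbar_scale = 0.4) {
  stopifnot(all(offsets >= 0 & offsets < 360))
  rows <- list()
  for (seed in seeds) {
    net <- baseline_network(profile, seed = seed)
    net <- scale_projection(net, "iMSN_GPE.GABA_A", imsn_gbar_scale)
    for (off in offsets) {
      sim <- .run_with_osc(net, profile, seed, ctx_freq = osc_freq,
                           imsn_freq = osc_freq, imsn_offset = off)
      row <- .osc_metrics(sim, osc_freq)
      rows[[length(rows) + 1]] <- cbind(data.frame(offset = off, seed = seed),
                                        row)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a sweep table over seeds
#' @param tab data frame from a runner.
#' @param by name of the swept column.
#' @param metric metric column to aggregate.
#' @return data frame with mean and sd per swept value.
#' @export
sweep_summary <- function(tab, by, metric) {
  agg <- stats::aggregate(tab[[metric]], list(value = tab[[by]]),
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x)))
  data.frame(value = agg$value, mean = agg$x[, "mean"], sd = agg$x[, "sd"])
}

#' Deterministic fixture bundle for tests
#'
#' Generates the small test inputs used across the test suite: toy
#' morphologies, a 5-STN/10-GPe micro-network, phase-locked and uniform
#' synthetic spike trains, and a sinusoidal reference trace. Byte-identical
#' given the seed.
#'
#' @param seed integer seed.
#' @return named list of fixtures.
#' @export
make_fixtures <- function(seed = 42L) {
  set.seed(seed)
  morph_stn <- build_reduced_morphology("STN")
  morph_gpe <- build_reduced_morphology("GPe")
  micro <- build_network(n_stn = 5, n_gpe = 10, n_ctx = 50, n_imsn = 100,
                         afferents = list(CTX_STN = 20L, GPE_STN = 8L,
                                          STN_GPE = 5L, GPE_GPE = 6L,
                                          iMSN_GPE = 30L),
                         seed = seed)
  f <- 18; dur <- 4000
  locked <- lapply(1:20, function(i) {
    cycles <- seq(0, dur - 1, by = 1000 / f)
    sort(cycles + stats::rnorm(length(cycles), 0, 0.5))
  })
  uniform <- poisson_trains(20, 20, dur)
  tt <- seq(0, dur - 0.05, by = 0.05)
  sine <- sin(2 * pi * f * tt / 1000)
  list(morph_stn = morph_stn, morph_gpe = morph_gpe, micro_network = micro,
       locked_trains = locked, uniform_trains = uniform,
       sine = sine, sine_freq = f, fs = 20000, duration = dur)
}
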