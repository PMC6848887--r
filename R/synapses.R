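#' Synaptic current models
#'
#' All synapses share a dual-exponential conductance profile whose event
#' amplitude is governed by Tsodyks-Markram short-term plasticity. The gating
#' variable is `B - A`, where A and B decay with `tau_rise` and `tau_decay`;
#' an afferent spike arriving at time t (after the axonal delay) increments
#' both by `f_peak * U_SE * R`, where R is the available vesicle fraction and
#' `U_SE` the running release probability. `f_peak` normalizes the profile so
#' that an isolated event of release fraction r reaches a peak conductance of
#' `gbar * r` at `t_peak` after arrival. NMDA receptors carry an additional
#' voltage-dependent magnesium-block factor. GABA-B receptors are
#' metabotropic: `B - A` drives G-protein production, and the G concentration
#' gates the conductance through a Hill function.
#'
#' Event ordering on a spike follows the usual Tsodyks-Markram convention:
#' the facilitation update is applied first (`U_SE += U1 (1 - U_SE)`), then
#' the release fraction `r = U_SE * R` is drawn down from the resource pool.
#' With `U_SE` initialized at 0 the first event's release fraction is exactly
#' `U1`.
#'
#' @name synapse_models
NULL

#' Synapse parameter set
#'
#' @param receptor `"AMPA"`, `"NMDA"`, `"GABA_A"` or `"GABA_B"`.
#' @param gbar peak conductance per synapse, uS.
#' @param e_rev reversal potential, mV (0 for AMPA/NMDA, -80 GABA_A,
#'   -95 GABA_B).
#' @param tau_rise,tau_decay conductance profile time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param tau_rec,tau_facil recovery and facilitation time constants, ms.
#' @param U1 release-probability increment per spike, in (0, 1].
#' @param delay axonal propagation delay, ms.
#' @param K3,K4 GABA-B G-protein production (per ms, per unit gating) and
#'   decay (per ms) rates.
#' @param Kd,n_hill GABA-B Hill dissociation constant and exponent.
#' @return object of class `synapse_params`.
#' @export
synapse_params <- function(receptor, gbar, e_rev, tau_rise, tau_decay,
                           tau_rec = 200, tau_facil = 1, U1 = 0.2, delay = 1,
                           K3 = 0.098, K4 = 6.25e-3, Kd = 1.4, n_hill = 4) {
  stopifnot(receptor %in% c("AMPA", "NMDA", "GABA_A", "GABA_B"),
            tau_decay > tau_rise, tau_rise > 0, U1 > 0, U1 <= 1, gbar >= 0,
            delay > 0)
  structure(list(receptor = receptor, gbar = gbar, e_rev = e_rev,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 tau_rec = tau_rec, tau_facil = tau_facil, U1 = U1,
                 delay = delay, K3 = K3, K4 = K4, Kd = Kd, n_hill = n_hill),
            class = "synapse_params")
}

#' Time of peak of the dual-exponential profile
#'
#' `t_peak = tau_rise tau_decay / (tau_decay - tau_rise) *
#'  log(tau_decay / tau_rise)`; in the equal-time-constant limit the profile
#' degenerates to an alpha function with `t_peak = tau`.
#' @param tau_rise,tau_decay ms.
#' @return peak time, ms.
#' @export
peak_time <- function(tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0)
  ifelse(abs(tau_decay - tau_rise) < 1e-12 * tau_decay,
         tau_rise,
         tau_rise * tau_decay / (tau_decay - tau_rise) *
           log(tau_decay / tau_rise))
}

#' Peak-normalization factor of the dual-exponential profile
#' @inheritParams peak_time
#' @return dimensionless factor `f_peak`.
#' @export
f_peak <- function(tau_rise, tau_decay) {
  tp <- peak_time(tau_rise, tau_decay)
  if (abs(tau_decay - tau_rise) < 1e-12 * tau_decay) return(exp(1))
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Fresh synapse state
#' @return list with gating exponentials A, B, resources R_res, running
#'   release probability U_SE and G-protein concentration G.
#' @export
synapse_state <- function() {
  list(A = 0, B = 0, R_res = 1, U_SE = 0, G = 0)
}

#' Apply an afferent spike to a synapse
#'
#' @param state a [synapse_state()].
#' @param params a [synapse_params()].
#' @return updated state.
#' @export
on_spike <- function(state, params) {
  state$U_SE <- state$U_SE + params$U1 * (1 - state$U_SE)
  r <- state$U_SE * state$R_res
  state$R_res <- state$R_res - r
  fp <- f_peak(params$tau_rise, params$tau_decay)
  state$A <- state$A + fp * r
  state$B <- state$B + fp * r
  state
}

#' Advance synapse state between events
#'
#' A and B decay exponentially, resources recover towards 1 with `tau_rec`,
#' the release probability decays with `tau_facil`, and (GABA-B) the
#' G-protein concentration integrates `dG/dt = K3 (B - A) - K4 G` with B - A
#' treated as constant over the step.
#'
#' @inheritParams on_spike
#' @param dt time step, ms.
#' @return updated state.
#' @export
advance_synapse <- function(state, params, dt) {
  stopifnot(dt > 0)
  ba0 <- state$B - state$A
  state$A <- state$A * exp(-dt / params$tau_rise)
  state$B <- state$B * exp(-dt / params$tau_decay)
  state$R_res <- 1 + (state$R_res - 1) * exp(-dt / params$tau_rec)
  state$U_SE <- state$U_SE * exp(-dt / params$tau_facil)
  if (params$receptor == "GABA_B") {
    ek <- exp(-params$K4 * dt)
    state$G <- state$G * ek + params$K3 * ba0 * (1 - ek) / params$K4
  }
  state
}

#' NMDA magnesium-block factor
#'
#' `m(v) = 1 / (1 + exp(-0.062 v) / 3.57)`; approaches 1 at depolarized and 0
#' at hyperpolarized potentials.
#' @param v membrane potential, mV.
#' @return factor in (0, 1).
#' @export
mg_block <- function(v) 1 / (1 + exp(-0.062 * v) / 3.57)

#' Ionotropic synaptic current
#'
#' `I = gbar (B - A) (v - E)`, with the magnesium-block factor for NMDA.
#' @inheritParams on_spike
#' @param v postsynaptic membrane potential, mV.
#' @return current, nA (gbar in uS, v in mV).
#' @export
ionotropic_current <- function(state, params, v) {
  g <- params$gbar * (state$B - state$A)
  if (params$receptor == "NMDA") g <- g * mg_block(v)
  g * (v - params$e_rev)
}

#' Hill gating of the GABA-B conductance
#' @param G G-protein concentration.
#' @param Kd,n Hill parameters.
#' @return gating fraction in `[0, 1)`.
#' @export
hill_gate <- function(G, Kd = 1.4, n = 4) G^n / (G^n + Kd^n)

#' Metabotropic GABA-B current
#'
#' `I = gbar G^n / (G^n + Kd^n) (v - E_GABAB)`.
#' @inheritParams ionotropic_current
#' @return current, nA.
#' @export
gabab_current <- function(state, params, v) {
  params$gbar * hill_gate(state$G, params$Kd, params$n_hill) *
    (v - params$e_rev)
}

#' Event-driven simulation of a single synapse
#'
#' Reference simulator used by the tests: advances the state on a fixed grid
#' and applies spikes at the given (post-delay) arrival times. Returns the
#' time series of the gating variable, conductance and state.
#'
#' @param params a [synapse_params()].
#' @param spike_times arrival times, ms.
#' @param duration ms.
#' @param dt grid step, ms.
#' @param v holding potential for the current trace, mV.
#' @return data frame with columns t, BA (= B - A), g (uS), G, R_res, U_SE,
#'   i (nA).
#' @export
simulate_synapse <- function(params, spike_times, duration, dt = 0.025,
                             v = -70) {
  n <- ceiling(duration / dt)
  st <- synapse_state()
  out <- matrix(0, n, 6)
  sp <- sort(spike_times); k <- 1L
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    while (k <= length(sp) && sp[k] <= t + 1e-12) {
      st <- on_spike(st, params)
      k <- k + 1L
    }
    ba <- st$B - st$A
    g <- params$gbar * if (params$receptor == "GABA_B")
      hill_gate(st$G, params$Kd, params$n_hill) else ba
    i_now <- if (params$receptor == "GABA_B") gabab_current(st, params, v)
             else ionotropic_current(st, params, v)
    out[i, ] <- c(t, ba, g, st$G, st$R_res, i_now)
    st <- advance_synapse(st, params, dt)
  }
  data.frame(t = out[, 1], BA = out[, 2], g = out[, 3], G = out[, 4],
             R_res = out[, 5], i = out[, 6])
}

#' Projection parameter tables
#'
#' The per-projection synaptic parameter sets of the network: receptor
#' composition, kinetics, short-term plasticity, delays and peak conductances
#' (uS per synapse). Names follow `SOURCE_TARGET.RECEPTOR`; the cortical
#' projection places an AMPA + slow-NMDA pair distally and a fast-NMDA
#' synapse proximally on STN cells.
#'
#' The tabulated per-synapse conductances were hand-tuned for the original
#' cell-model implementations and their absolute units are not fixed by the
#' tables; on this package's reduced morphologies and reconstructed kinetics
#' they are recalibrated by fixed per-projection factors (`calibration`)
#' chosen once so that (a) the parkinsonian network's population firing
#' rates fall inside the experimentally reported ranges (STN 17-37 Hz, GPe
#' near 14.6 Hz) and (b) the cortical drive is AMPA-dominated with an
#' NMDA:AMPA per-event charge ratio near 1.4, in the physiological range.
#' See the methods vignette for the full rationale.
#'
#' @param calibration named multipliers applied to the tabulated conductances
#'   (matched by name prefix, so `CTX_STN.NMDA` covers both NMDA components).
#' @return named list of [synapse_params()].
#' @export
projection_params <- function(calibration = c(CTX_STN.AMPA = 4.2,
                                              CTX_STN.NMDA = 0.07,
                                              STN_GPE = 2.0)) {
  out <- list(
    CTX_STN.AMPA = synapse_params("AMPA", gbar = 4.44e-3, e_rev = 0,
      tau_rise = 1, tau_decay = 4, tau_rec = 200, tau_facil = 1, U1 = 0.2,
      delay = 5.9),
    CTX_STN.NMDA_slow = synapse_params("NMDA", gbar = 5.04e-3, e_rev = 0,
      tau_rise = 3.7, tau_decay = 212, tau_rec = 200, tau_facil = 1, U1 = 0.2,
      delay = 5.9),
    CTX_STN.NMDA_fast = synapse_params("NMDA", gbar = 5.04e-3, e_rev = 0,
      tau_rise = 3.7, tau_decay = 80, tau_rec = 200, tau_facil = 1, U1 = 0.2,
      delay = 5.9),
    GPE_STN.GABA_A = synapse_params("GABA_A", gbar = 18e-3, e_rev = -80,
      tau_rise = 2, tau_decay = 7, tau_rec = 400, tau_facil = 1, U1 = 0.2,
      delay = 2.0),
    GPE_STN.GABA_B = synapse_params("GABA_B", gbar = 3.75e-3, e_rev = -95,
      tau_rise = 5, tau_decay = 25, tau_rec = 400, tau_facil = 1, U1 = 0.2,
      delay = 2.0, K3 = 0.098, K4 = 6.25e-3, Kd = 1.4, n_hill = 4),
    STN_GPE.AMPA = synapse_params("AMPA", gbar = 3.75e-4, e_rev = 0,
      tau_rise = 1, tau_decay = 4, tau_rec = 200, tau_facil = 800, U1 = 0.1,
      delay = 2),
    GPE_GPE.GABA_A = synapse_params("GABA_A", gbar = 2e-4, e_rev = -80,
      tau_rise = 2, tau_decay = 5, tau_rec = 400, tau_facil = 1, U1 = 0.2,
      delay = 0.5),
    GPE_GPE.GABA_B = synapse_params("GABA_B", gbar = 0.4e-4, e_rev = -95,
      tau_rise = 5, tau_decay = 25, tau_rec = 400, tau_facil = 1, U1 = 0.2,
      delay = 0.5, K3 = 0.098, K4 = 6.25e-3, Kd = 1.4, n_hill = 4),
    iMSN_GPE.GABA_A = synapse_params("GABA_A", gbar = 3e-4, e_rev = -80,
      tau_rise = 2, tau_decay = 5, tau_rec = 1, tau_facil = 200, U1 = 0.3,
      delay = 5)
  )
  for (proj in names(calibration)) {
    hit <- startsWith(names(out), proj)
    for (nm in names(out)[hit])
      out[[nm]]$gbar <- out[[nm]]$gbar * calibration[[proj]]
  }
  out
}

#' Serialize projection parameters as a structured config
#' @param params result of [projection_params()].
#' @param path output YAML file.
#' @export
write_projection_config <- function(params = projection_params(), path) {
  yaml::write_yaml(lapply(params, unclass), path)
  invisible(path)
}
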