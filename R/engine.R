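#' Simulation engine configuration
#'
#' @param dt integration step, ms (fixed-step backward Euler; default
#'   0.025 ms).
#' @param duration total simulated time, ms.
#' @param warmup_discard initial interval dropped from all returned records,
#'   ms (must be shorter than `duration`).
#' @param seed integer seed controlling the somatic noise, initial voltages
#'   and surrogate spike trains of the run.
#' @param v_init_range_stn,v_init_range_gpe uniform intervals (mV) for the
#'   per-cell initial membrane potential.
#' @param noise_sd_stn,noise_sd_gpe standard deviation of the Gaussian
#'   somatic noise current, nA, redrawn every step.
#' @param spike_threshold somatic upward-crossing threshold, mV.
#' @param record_every voltage/current recording stride in steps (2 gives a
#'   0.05 ms sampling period, i.e. 20 kHz).
#' @param n_record_cells number of cells per population on which all synaptic
#'   currents are recorded (for E/I accounting).
#' @return object of class `engine_config`.
#' @export
engine_config <- function(dt = 0.025, duration = 3000, warmup_discard = 1000,
                          seed = 1L,
                          v_init_range_stn = c(-70, -60),
                          v_init_range_gpe = c(-73, -63),
                          noise_sd_stn = 0.1, noise_sd_gpe = 0.0075,
                          spike_threshold = -10, record_every = 2L,
                          n_record_cells = 3L) {
  stopifnot(dt > 0, warmup_discard < duration)
  structure(list(dt = dt, duration = duration,
                 warmup_discard = warmup_discard, seed = as.integer(seed),
                 v_init_range_stn = v_init_range_stn,
                 v_init_range_gpe = v_init_range_gpe,
                 noise_sd_stn = noise_sd_stn, noise_sd_gpe = noise_sd_gpe,
                 spike_threshold = spike_threshold,
                 record_every = as.integer(record_every),
                 n_record_cells = as.integer(n_record_cells)),
            class = "engine_config")
}

# voltage grid on which gate kinetics are tabulated for the compiled engine
.vgrid <- function() list(v0 = -120, dv = 0.25, n = 721L)

# compile one gate_spec into the table representation used by the engine;
# tables are produced by the R reference evaluators so both routes agree.
.compile_gate <- function(g, dt, ca_tau_hint = NULL) {
  gr <- .vgrid()
  v <- gr$v0 + gr$dv * (seq_len(gr$n) - 1)
  if (g$depends_on == "calcium") {
    type <- if (g$form == "ca_sigmoid") 2L else 3L
    params <- if (g$form == "ca_sigmoid")
      c(g$params$xmax, g$params$theta, g$params$k, 0)
    else c(g$params$x0, g$params$amp, g$params$theta, g$params$k)
    return(list(type = type, params = params,
                cafac = 1 - exp(-dt / g$params$tau_const)))
  }
  if (g$form == "wang_sd") {
    ab <- .wang_sd_rates(g, v)
    return(list(type = 4L, as = ab$alpha_s, bs = ab$beta_s,
                ad = ab$alpha_d, bd = ab$beta_d))
  }
  xinf <- .gate_xinf_v(g, v)
  if (g$instantaneous) return(list(type = 1L, xinf = xinf))
  tau <- .gate_tau_v(g, v)
  list(type = 0L, xinf = xinf, taufac = exp(-dt / tau))
}

# flatten a network + config into the plain-array form the C++ engine takes
.flatten_network <- function(network, config, gen_trains, v_init,
                             rec_cells, iclamp_list = NULL) {
  channels <- list(STN = stn_channels(), GPe = gpe_channels())
  morphs <- network$morph
  n_stn <- network$sizes$STN; n_gpe <- network$sizes$GPe
  dt <- config$dt

  # compile the union of gate specs across both cell classes
  specs <- list(); spec_key <- character(0)
  chan_tmpl <- list()  # per class: channel template rows with spec ids
  for (cls in c("STN", "GPe")) {
    tmpl <- list()
    for (chname in setdiff(names(channels[[cls]]), "calcium")) {
      ch <- channels[[cls]][[chname]]
      gids <- integer(0)
      for (g in ch$gates) {
        key <- paste(cls, chname, g$name)
        spec_key <- c(spec_key, key)
        specs[[key]] <- .compile_gate(g, dt)
        gids <- c(gids, length(specs) - 1L)  # 0-based
      }
      mult <- network$channel_mult[[cls]][[chname]]
      if (is.null(mult)) mult <- 1
      tmpl[[chname]] <- list(name = chname, spec = ch, gspec = gids,
                             gexp = vapply(ch$gates, `[[`, 0L, "exponent"),
                             mult = mult)
    }
    chan_tmpl[[cls]] <- tmpl
  }

  # compartments for all biophysical cells (STN first, then GPe)
  comp <- list(parent = integer(0), cap = numeric(0), g_ax = numeric(0),
               g_leak = numeric(0), e_leak = numeric(0), cell = integer(0),
               ca_rest = numeric(0), ca_tau = numeric(0), ca_flux = numeric(0),
               nernst = numeric(0), ca_out = numeric(0))
  soma_comp <- integer(0); cellpop <- character(0)
  ch_cols <- list(comp = integer(0), g = numeric(0), erev = numeric(0),
                  use_ca = integer(0), is_ca = integer(0), ngates = integer(0))
  ch_gspec <- NULL; ch_gexp <- NULL
  offset <- 0L
  F_const <- 96485

  add_cell <- function(cls, cell_idx0) {
    m <- morphs[[cls]]; cdf <- m$compartments
    calc <- channels[[cls]]$calcium
    area_cm2 <- compartment_areas(m) * 1e-8
    n <- nrow(cdf)
    par0 <- ifelse(is.na(cdf$parent_id), -1L, cdf$parent_id - 1L + offset)
    # axial conductance to parent (uS): series half-cylinder resistances
    g_ax <- numeric(n)
    for (i in seq_len(n)) {
      p <- cdf$parent_id[i]
      if (is.na(p)) next
      half_r <- function(j) {
        l_cm <- cdf$length[j] * 1e-4 / 2
        a_cm <- cdf$diameter[j] * 1e-4 / 2
        cdf$R_a[j] * l_cm / (pi * a_cm^2)
      }
      g_ax[i] <- 1e6 / (half_r(i) + half_r(p))  # ohm -> uS
    }
    comp$parent <<- c(comp$parent, par0)
    comp$cap <<- c(comp$cap, cdf$c_m * area_cm2 * 1e3)        # nF
    comp$g_ax <<- c(comp$g_ax, g_ax)
    comp$g_leak <<- c(comp$g_leak, cdf$g_m * area_cm2 * 1e6)  # uS
    comp$e_leak <<- c(comp$e_leak, cdf$E_m)
    comp$cell <<- c(comp$cell, rep(cell_idx0, n))
    comp$ca_rest <<- c(comp$ca_rest, rep(calc$ca_rest, n))
    comp$ca_tau <<- c(comp$ca_tau, rep(calc$tau_ca, n))
    d_cm <- calc$shell_depth * 1e-4
    comp$ca_flux <<- c(comp$ca_flux, 1e-6 / (2 * F_const * d_cm * area_cm2))
    comp$nernst <<- c(comp$nernst,
                      rep(1e3 * 8.314 * calc$temperature / (2 * F_const), n))
    comp$ca_out <<- c(comp$ca_out, rep(calc$ca_out, n))
    soma_comp <<- c(soma_comp, offset)  # soma is the first (root) compartment
    cellpop <<- c(cellpop, cls)

    # channel instances
    maxpd <- max(cdf$path_distance)
    for (tm in chan_tmpl[[cls]]) {
      for (i in seq_len(n)) {
        frac <- if (maxpd > 0) cdf$path_distance[i] / maxpd else 0
        gbar <- .gbar_for_compartment(tm$spec, cdf$region[i], frac) * tm$mult
        if (gbar <= 0) next
        ng <- length(tm$gspec)
        ch_cols$comp <<- c(ch_cols$comp, offset + i - 1L)
        ch_cols$g <<- c(ch_cols$g, gbar * area_cm2[i] * 1e6)  # uS
        use_ca <- identical(tm$spec$reversal, "nernst_calcium")
        ch_cols$erev <<- c(ch_cols$erev,
                           if (use_ca) 0 else tm$spec$reversal)
        ch_cols$use_ca <<- c(ch_cols$use_ca, as.integer(use_ca))
        ch_cols$is_ca <<- c(ch_cols$is_ca, as.integer(tm$spec$is_ca_source))
        ch_cols$ngates <<- c(ch_cols$ngates, ng)
        ch_gspec <<- rbind(ch_gspec, c(tm$gspec, rep(-1L, 3 - ng)))
        ch_gexp <<- rbind(ch_gexp, c(tm$gexp, rep(0L, 3 - ng)))
      }
    }
    offset <<- offset + n
  }
  for (i in seq_len(n_stn)) add_cell("STN", i - 1L)
  for (i in seq_len(n_gpe)) add_cell("GPe", n_stn + i - 1L)

  ncell <- n_stn + n_gpe
  noise_sd <- ifelse(cellpop == "STN", config$noise_sd_stn,
                     config$noise_sd_gpe)

  # global source indexing: [bio cells 0..ncell-1][generators]
  # generator order: STN surrogates, GPe surrogates, CTX, iMSN
  gen_sizes <- c(STN_surrogate = network$sizes$STN_surrogate,
                 GPe_surrogate = network$sizes$GPe_surrogate,
                 CTX = network$sizes$CTX, iMSN = network$sizes$iMSN)
  gen_base <- ncell + c(0, cumsum(gen_sizes))[seq_along(gen_sizes)]
  names(gen_base) <- names(gen_sizes)

  syn <- network$syn
  src_global <- integer(nrow(syn))
  for (r in seq_len(nrow(syn))) {
    sp <- syn$source_pop[r]; sk <- syn$source_kind[r]; sc <- syn$source_cell[r]
    src_global[r] <- if (sk == "bio") {
      if (sp == "STN") sc - 1L else n_stn + sc - 1L
    } else if (sk == "surrogate") {
      gen_base[[paste0(sp, "_surrogate")]] + sc - 1L
    } else gen_base[[sp]] + sc - 1L
  }

  # recorded-cell slots (for E/I accounting): map target cells to slots
  rec_global <- c(rec_cells$STN, n_stn + rec_cells$GPe)  # 1-based cell index
  slot_of <- rep(-1L, ncell); slot_of[rec_global] <- seq_along(rec_global) - 1L
  tgt_global <- ifelse(syn$target_pop == "STN", syn$target_cell,
                       n_stn + syn$target_cell)
  rec_slot <- slot_of[tgt_global]
  rec_sign <- ifelse(syn$receptor %in% c("AMPA", "NMDA"), 1L, -1L)

  rec_type <- match(syn$receptor, c("AMPA", "NMDA", "GABA_A", "GABA_B")) - 1L
  comp_global <- integer(nrow(syn))
  for (r in seq_len(nrow(syn))) {
    base <- if (syn$target_pop[r] == "STN")
      (syn$target_cell[r] - 1L) * nrow(morphs$STN$compartments)
    else n_stn * nrow(morphs$STN$compartments) +
      (syn$target_cell[r] - 1L) * nrow(morphs$GPe$compartments)
    comp_global[r] <- base + syn$comp[r] - 1L
  }
  fpk <- mapply(f_peak, syn$tau_rise, syn$tau_decay)
  k4fac <- exp(-syn$K4 * dt)

  # generator events
  gev <- .gen_events(gen_trains, gen_base, dt)

  iclamp <- numeric(offset)
  if (!is.null(iclamp_list))
    for (nm in names(iclamp_list)) iclamp[as.integer(nm)] <- iclamp_list[[nm]]

  gr <- .vgrid()
  list(
    parent = comp$parent, cap_nF = comp$cap, g_ax_uS = comp$g_ax,
    g_leak_uS = comp$g_leak, e_leak = comp$e_leak, comp_cell = comp$cell,
    ca_rest = comp$ca_rest,
    ca_taufac = 1 - exp(-dt / comp$ca_tau), ca_tau = comp$ca_tau,
    ca_flux = comp$ca_flux, nernst_fac = comp$nernst, ca_out = comp$ca_out,
    iclamp = iclamp,
    soma_comp = soma_comp, noise_sd = noise_sd, v_init = v_init,
    gate_specs = unname(specs), grid_v0 = gr$v0, grid_dv = gr$dv,
    grid_n = gr$n,
    ch_comp = ch_cols$comp, ch_g_uS = ch_cols$g, ch_erev = ch_cols$erev,
    ch_use_ca_erev = ch_cols$use_ca, ch_is_ca = ch_cols$is_ca,
    ch_ngates = ch_cols$ngates,
    ch_gspec = if (is.null(ch_gspec)) matrix(0L, 0, 3) else ch_gspec,
    ch_gexp = if (is.null(ch_gexp)) matrix(0L, 0, 3) else ch_gexp,
    sy_comp = comp_global, sy_type = rec_type, sy_g_uS = syn$gbar,
    sy_erev = syn$e_rev,
    sy_afac = exp(-dt / syn$tau_rise), sy_bfac = exp(-dt / syn$tau_decay),
    sy_rfac = exp(-dt / syn$tau_rec), sy_ufac = exp(-dt / syn$tau_facil),
    sy_U1 = syn$U1, sy_fpeak = fpk,
    sy_k4fac = k4fac, sy_k3term = syn$K3 * (1 - k4fac) / syn$K4,
    sy_kd = syn$Kd, sy_nhill = syn$n_hill,
    sy_delay_steps = pmax(1L, as.integer(round(syn$delay / dt))),
    sy_source = src_global, sy_rec_slot = rec_slot, sy_rec_sign = rec_sign,
    n_sources = as.integer(ncell + sum(gen_sizes)),
    n_rec_slots = length(rec_global),
    gen_event_step = gev$step, gen_event_source = gev$source,
    ncell = ncell, cellpop = cellpop, rec_global = rec_global)
}

# convert generator spike trains (list per generator group) to sorted events
.gen_events <- function(gen_trains, gen_base, dt) {
  steps <- integer(0); src <- integer(0)
  for (nm in names(gen_trains)) {
    trains <- gen_trains[[nm]]
    for (i in seq_along(trains)) {
      tt <- trains[[i]]
      if (!length(tt)) next
      steps <- c(steps, as.integer(round(tt / dt)))
      src <- c(src, rep(gen_base[[nm]] + i - 1L, length(tt)))
    }
  }
  o <- order(steps)
  list(step = steps[o], source = src[o])
}

#' Draw initial membrane potentials for a population mix
#'
#' Per-cell uniform value in the class interval, shared by all compartments
#' of the cell; gates are set to their steady state at that voltage and shell
#' calcium to rest when the engine starts.
#' @param cellpop character vector of cell classes (`"STN"`/`"GPe"`).
#' @param config an [engine_config()].
#' @return numeric vector of initial voltages, mV.
#' @export
initialize_voltages <- function(cellpop, config) {
  r_stn <- config$v_init_range_stn; r_gpe <- config$v_init_range_gpe
  ifelse(cellpop == "STN",
         stats::runif(length(cellpop), r_stn[1], r_stn[2]),
         stats::runif(length(cellpop), r_gpe[1], r_gpe[2]))
}

#' Run a network simulation
#'
#' Generates the surrogate spike trains (Poisson at the network's configured
#' rates unless oscillatory inputs are supplied), integrates the network, and
#' returns the post-warm-up record: spike times per biophysical cell, somatic
#' voltage traces, and the synaptic currents of the designated recorded cells.
#'
#' @param network a `stngpe_network`.
#' @param config an [engine_config()].
#' @param inputs optional list overriding generator trains; elements `CTX`
#'   and/or `iMSN` may each be a list of spike-time vectors (ms) of the
#'   population size.
#' @return object of class `stngpe_sim`.
#' @export
run_network <- function(network, config = engine_config(), inputs = NULL) {
  stopifnot(inherits(network, "stngpe_network"),
            inherits(config, "engine_config"))
  set.seed(config$seed)
  dur <- config$duration
  gen_trains <- list(
    STN_surrogate = poisson_trains(network$sizes$STN_surrogate,
                                   network$rates$STN_surrogate, dur),
    GPe_surrogate = poisson_trains(network$sizes$GPe_surrogate,
                                   network$rates$GPe_surrogate, dur),
    CTX = if (!is.null(inputs$CTX)) inputs$CTX
          else poisson_trains(network$sizes$CTX, network$rates$CTX, dur),
    iMSN = if (!is.null(inputs$iMSN)) inputs$iMSN
           else poisson_trains(network$sizes$iMSN, network$rates$iMSN, dur))
  n_stn <- network$sizes$STN; n_gpe <- network$sizes$GPe
  cellpop <- c(rep("STN", n_stn), rep("GPe", n_gpe))
  v_init <- initialize_voltages(cellpop, config)
  nrec <- min(config$n_record_cells, n_stn, n_gpe)
  rec_cells <- list(STN = sort(sample.int(n_stn, nrec)),
                    GPe = sort(sample.int(n_gpe, nrec)))

  flat <- .flatten_network(network, config, gen_trains, v_init, rec_cells)
  n_steps <- as.integer(round(dur / config$dt))
  rec_start <- as.integer(round(config$warmup_discard / config$dt))
  if (rec_start >= n_steps) stop("no analyzable record after warm-up discard")
  out <- .engine_run(flat, list(
    dt = config$dt, n_steps = n_steps, record_start = rec_start,
    record_every = config$record_every,
    spike_threshold = config$spike_threshold,
    refrac_steps = as.integer(round(1 / config$dt)),
    seed = config$seed))
  if (isTRUE(out$diverged))
    warning(sprintf(
      "simulation diverged at step %d (cell %s, compartment %s); partial record returned",
      out$steps_done, out$div_cell, out$div_comp))

  warm <- config$warmup_discard
  spikes <- lapply(out$spikes, function(s) s[s >= warm] - warm)
  fs <- 1000 / (config$dt * config$record_every)
  structure(list(
    spikes = spikes,
    cellpop = cellpop,
    v_soma = out$v_soma,
    t = out$t_rec - warm,
    fs = fs,
    dt = config$dt, record_every = config$record_every,
    duration = dur - warm,
    sizes = network$sizes,
    condition = network$condition,
    syn_currents = list(
      STN = list(cells = rec_cells$STN,
                 exc = out$exc[, seq_len(nrec), drop = FALSE],
                 inh = out$inh[, seq_len(nrec), drop = FALSE]),
      GPe = list(cells = rec_cells$GPe,
                 exc = out$exc[, nrec + seq_len(nrec), drop = FALSE],
                 inh = out$inh[, nrec + seq_len(nrec), drop = FALSE])),
    error = isTRUE(out$diverged),
    config = config), class = "stngpe_sim")
}

#' @export
print.stngpe_sim <- function(x, ...) {
  cat(sprintf("<stngpe_sim> %s condition, %.0f ms analyzed at %g kHz sampling\n",
              x$condition, x$duration, x$fs / 1000))
  for (p in c("STN", "GPe")) {
    r <- population_rates(x, p)
    cat(sprintf("  %s: %d cells, mean rate %.1f Hz\n", p, length(r), mean(r)))
  }
  if (x$error) cat("  ** simulation diverged; record is partial **\n")
  invisible(x)
}

#' Mean firing rate per cell of a population
#' @param sim a `stngpe_sim`.
#' @param population `"STN"` or `"GPe"`.
#' @return numeric vector, Hz.
#' @export
population_rates <- function(sim, population = c("STN", "GPe")) {
  population <- match.arg(population)
  idx <- which(sim$cellpop == population)
  vapply(sim$spikes[idx], length, 0L) / (sim$duration / 1000)
}

#' Detect spikes in a sampled voltage trace
#'
#' Upward threshold crossings with a 1 ms refractory guard.
#' @param v voltage trace, mV.
#' @param dt sampling period, ms.
#' @param threshold crossing threshold, mV.
#' @return spike times, ms (relative to the start of the trace).
#' @export
detect_spikes <- function(v, dt, threshold = -10) {
  above <- v >= threshold
  cross <- which(above[-1] & !above[-length(above)]) + 1L
  if (!length(cross)) return(numeric(0))
  times <- (cross - 1) * dt
  keep <- c(TRUE, diff(times) > 1)
  # enforce the refractory guard sequentially
  out <- numeric(0); last <- -Inf
  for (tt in times) if (tt - last > 1) { out <- c(out, tt); last <- tt }
  out
}

#' Population mean somatic voltage trace
#' @param sim a `stngpe_sim`.
#' @param population `"STN"` or `"GPe"`.
#' @return numeric vector (mV) at the record sampling rate `sim$fs`.
#' @export
population_trace <- function(sim, population = c("STN", "GPe")) {
  population <- match.arg(population)
  rowMeans(sim$v_soma[, sim$cellpop == population, drop = FALSE])
}

#' Export a simulation record to plain-text files
#'
#' Writes spikes as a two-column text file and the somatic voltage matrix as
#' CSV with a time column.
#' @param sim a `stngpe_sim`.
#' @param dir output directory (created if needed).
#' @export
export_record <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spike_trains(sim$spikes, file.path(dir, "spikes.txt"))
  utils::write.csv(data.frame(t = sim$t, sim$v_soma),
                   file.path(dir, "v_soma.csv"), row.names = FALSE)
  invisible(dir)
}
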