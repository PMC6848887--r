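.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Assemble the STN-GPe network
#'
#' Populations: biophysical STN and GPe cells (multicompartment), plus an
#' additional 10% of each modelled as Poisson surrogate spike sources, and
#' purely generator-based cortical (CTX) and indirect-pathway striatal (iMSN)
#' populations. Connectivity is stochastic with a fixed in-degree per
#' projection: each postsynaptic cell draws its afferents uniformly without
#' replacement from the presynaptic pool (biophysical + surrogate sources).
#'
#' Subcellular placement follows the projection's placement rule: cortical
#' afferents place one AMPA + slow-NMDA synapse distally and one fast-NMDA
#' synapse proximally on each STN target; pallidal afferents to STN place a
#' GABA-A + GABA-B pair proximally; subthalamic afferents to GPe place AMPA
#' distally; pallidal collaterals a GABA-A + GABA-B pair proximally; striatal
#' afferents GABA-A proximally.
#'
#' @param n_stn,n_gpe numbers of biophysical STN and GPe cells.
#' @param n_ctx,n_imsn numbers of cortical and striatal generators.
#' @param afferents named list of per-projection in-degrees; defaults are the
#'   control-condition values (STN: 20 CTX + 8 GPe; GPe: 10 STN + 6 GPe + 30
#'   iMSN).
#' @param params projection parameter sets, see [projection_params()].
#' @param morph_stn,morph_gpe morphologies (defaults:
#'   [build_reduced_morphology()] per class).
#' @param seed integer seed controlling adjacency and placement.
#' @return object of class `stngpe_network`.
#' @export
build_network <- function(n_stn = 50, n_gpe = 100, n_ctx = 1000,
                          n_imsn = 2000,
                          afferents = list(CTX_STN = 20L, GPE_STN = 8L,
                                           STN_GPE = 10L, GPE_GPE = 6L,
                                           iMSN_GPE = 30L),
                          params = projection_params(),
                          morph_stn = build_reduced_morphology("STN"),
                          morph_gpe = build_reduced_morphology("GPe"),
                          seed = 1L) {
  set.seed(seed)
  n_stn_sur <- as.integer(round(0.1 * n_stn))
  n_gpe_sur <- as.integer(round(0.1 * n_gpe))
  pool <- list(CTX = n_ctx, iMSN = n_imsn,
               STN = n_stn + n_stn_sur, GPe = n_gpe + n_gpe_sur)
  for (pr in names(afferents))
    if (afferents[[pr]] > pool[[sub("_.*", "", sub("GPE", "GPe", pr))]])
      stop("afferent count for ", pr, " exceeds source population size")

  distal_stn <- select_compartments(morph_stn, "distal")
  prox_stn <- select_compartments(morph_stn, "proximal_stn")
  distal_gpe <- select_compartments(morph_gpe, "distal")
  prox_gpe <- select_compartments(morph_gpe, "proximal_gpe")

  rows <- list(); ri <- 0L
  add <- function(target_pop, target_cell, comp, pset_name, source_pop,
                  source_kind, source_cell, afferent_id) {
    p <- params[[pset_name]]
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(
      target_pop = target_pop, target_cell = target_cell, comp = comp,
      pset = pset_name, receptor = p$receptor,
      source_pop = source_pop, source_kind = source_kind,
      source_cell = source_cell, afferent_id = afferent_id,
      gbar = p$gbar, e_rev = p$e_rev, tau_rise = p$tau_rise,
      tau_decay = p$tau_decay, tau_rec = p$tau_rec,
      tau_facil = p$tau_facil, U1 = p$U1, delay = p$delay,
      K3 = p$K3, K4 = p$K4, Kd = p$Kd, n_hill = p$n_hill)
  }
  draw_sources <- function(pop, k, exclude_bio = NA_integer_) {
    tot <- pool[[pop]]
    ids <- seq_len(tot)
    if (!is.na(exclude_bio)) ids <- ids[ids != exclude_bio]
    if (length(ids) < k) stop("afferent count exceeds available sources")
    ids[sample.int(length(ids), k)]
  }
  src_kind <- function(pop, id, n_bio) {
    if (pop %in% c("CTX", "iMSN")) "generator"
    else if (id <= n_bio) "bio" else "surrogate"
  }
  src_cell <- function(pop, id, n_bio) {
    if (pop %in% c("CTX", "iMSN")) id
    else if (id <= n_bio) id else id - n_bio
  }

  aff_counter <- 0L
  for (tc in seq_len(n_stn)) {
    for (s in draw_sources("CTX", afferents$CTX_STN)) {
      aff_counter <- aff_counter + 1L
      dcomp <- .pick1(distal_stn); pcomp <- .pick1(prox_stn)
      add("STN", tc, dcomp, "CTX_STN.AMPA", "CTX", "generator", s, aff_counter)
      add("STN", tc, dcomp, "CTX_STN.NMDA_slow", "CTX", "generator", s, aff_counter)
      add("STN", tc, pcomp, "CTX_STN.NMDA_fast", "CTX", "generator", s, aff_counter)
    }
    for (s in draw_sources("GPe", afferents$GPE_STN)) {
      aff_counter <- aff_counter + 1L
      pcomp <- .pick1(prox_stn)
      kind <- src_kind("GPe", s, n_gpe); cell <- src_cell("GPe", s, n_gpe)
      add("STN", tc, pcomp, "GPE_STN.GABA_A", "GPe", kind, cell, aff_counter)
      add("STN", tc, pcomp, "GPE_STN.GABA_B", "GPe", kind, cell, aff_counter)
    }
  }
  for (tc in seq_len(n_gpe)) {
    for (s in draw_sources("STN", afferents$STN_GPE)) {
      aff_counter <- aff_counter + 1L
      kind <- src_kind("STN", s, n_stn); cell <- src_cell("STN", s, n_stn)
      add("GPe", tc, .pick1(distal_gpe), "STN_GPE.AMPA", "STN", kind, cell,
          aff_counter)
    }
    for (s in draw_sources("GPe", afferents$GPE_GPE, exclude_bio = tc)) {
      aff_counter <- aff_counter + 1L
      pcomp <- .pick1(prox_gpe)
      kind <- src_kind("GPe", s, n_gpe); cell <- src_cell("GPe", s, n_gpe)
      add("GPe", tc, pcomp, "GPE_GPE.GABA_A", "GPe", kind, cell, aff_counter)
      add("GPe", tc, pcomp, "GPE_GPE.GABA_B", "GPe", kind, cell, aff_counter)
    }
    for (s in draw_sources("iMSN", afferents$iMSN_GPE)) {
      aff_counter <- aff_counter + 1L
      add("GPe", tc, .pick1(prox_gpe), "iMSN_GPE.GABA_A", "iMSN",
          "generator", s, aff_counter)
    }
  }

  structure(list(
    sizes = list(STN = n_stn, GPe = n_gpe, CTX = n_ctx, iMSN = n_imsn,
                 STN_surrogate = n_stn_sur, GPe_surrogate = n_gpe_sur),
    afferents = afferents,
    morph = list(STN = morph_stn, GPe = morph_gpe),
    syn = do.call(rbind, rows),
    rates = list(CTX = 10, iMSN = 1.5, STN_surrogate = 14.6,
                 GPe_surrogate = 33.7),
    channel_mult = list(STN = list(), GPe = list()),
    condition = "control",
    seed = seed),
    class = "stngpe_network")
}

#' @export
print.stngpe_network <- function(x, ...) {
  cat(sprintf("<stngpe_network> %s condition\n", x$condition))
  cat(sprintf("  STN %d (+%d surrogate), GPe %d (+%d surrogate), CTX %d, iMSN %d\n",
              x$sizes$STN, x$sizes$STN_surrogate, x$sizes$GPe,
              x$sizes$GPe_surrogate, x$sizes$CTX, x$sizes$iMSN))
  cat(sprintf("  %d synapses across %d projections\n", nrow(x$syn),
              length(unique(x$syn$pset))))
  invisible(x)
}

#' Apply the parkinsonian parameter state
#'
#' Atomically applies the dopamine-depletion modifications to a
#' control-condition network:
#' * STN surrogate rate 14.6 -> 29.5 Hz; GPe surrogate rate 33.7 -> 14.6 Hz;
#'   iMSN rate 1.5 -> 6.64 Hz.
#' * GPe->STN GABA-A and GABA-B peak conductance x 1.5; GABA-B profile decay
#'   time constant + 2 ms.
#' * Cortico-subthalamic afferent count reduced to 70% (pruned per target
#'   cell), remaining CTX->STN conductances rescaled by
#'   `strengthening_ratio / 0.7` (functional strengthening of surviving
#'   synapses).
#' * HCN conductance x 0.5 in both cell classes.
#' * STN->GPe AMPA x 1.5; GPe->GPe GABA-A and GABA-B x 1.5.
#' * iMSN->GPe release probability U1 x 1.5 and GABA-A conductance x 1.5.
#'
#' @param network a control-condition `stngpe_network`.
#' @param strengthening_ratio AMPA/NMDA current-scaling ratio applied to the
#'   surviving cortical synapses before dividing by the surviving fraction
#'   (default 1, config data).
#' @param seed seed for the afferent pruning.
#' @return the modified network (`condition == "parkinsonian"`).
#' @export
apply_state <- function(network, strengthening_ratio = 1, seed = network$seed) {
  stopifnot(inherits(network, "stngpe_network"))
  if (network$condition != "control")
    stop("parkinsonian state already applied; multipliers are not idempotent")
  set.seed(seed + 1L)
  syn <- network$syn

  # rates
  network$rates$STN_surrogate <- 29.5
  network$rates$GPe_surrogate <- 14.6
  network$rates$iMSN <- 6.64

  # GPe -> STN inhibition strengthened, GABA-B decay prolonged
  i <- syn$pset == "GPE_STN.GABA_A"; syn$gbar[i] <- syn$gbar[i] * 1.5
  i <- syn$pset == "GPE_STN.GABA_B"
  syn$gbar[i] <- syn$gbar[i] * 1.5
  syn$tau_decay[i] <- syn$tau_decay[i] + 2

  # cortical afferent pruning + functional strengthening of survivors
  keep_frac <- 0.7
  ctx <- which(syn$pset %in% c("CTX_STN.AMPA", "CTX_STN.NMDA_slow",
                               "CTX_STN.NMDA_fast"))
  drop <- integer(0)
  for (tc in unique(syn$target_cell[ctx])) {
    affs <- unique(syn$afferent_id[ctx][syn$target_cell[ctx] == tc])
    n_keep <- round(keep_frac * length(affs))
    gone <- sample(affs, length(affs) - n_keep)
    drop <- c(drop, ctx[syn$afferent_id[ctx] %in% gone])
  }
  syn$gbar[setdiff(ctx, drop)] <-
    syn$gbar[setdiff(ctx, drop)] * strengthening_ratio / keep_frac
  if (length(drop)) syn <- syn[-drop, ]

  # intrinsic and remaining synaptic scalings
  network$channel_mult$STN$HCN <- 0.5
  network$channel_mult$GPe$HCNf <- 0.5
  network$channel_mult$GPe$HCNs <- 0.5
  i <- syn$pset == "STN_GPE.AMPA"; syn$gbar[i] <- syn$gbar[i] * 1.5
  i <- syn$pset == "GPE_GPE.GABA_A"; syn$gbar[i] <- syn$gbar[i] * 1.5
  i <- syn$pset == "GPE_GPE.GABA_B"; syn$gbar[i] <- syn$gbar[i] * 1.5
  i <- syn$pset == "iMSN_GPE.GABA_A"
  syn$U1[i] <- pmin(syn$U1[i] * 1.5, 1)
  syn$gbar[i] <- syn$gbar[i] * 1.5

  network$syn <- syn
  network$condition <- "parkinsonian"
  network
}

#' Scale the conductance of a projection
#'
#' Multiplies the per-synapse peak conductance of every synapse belonging to
#' the named projection(s); this is the knob the parameter-sweep experiments
#' turn.
#' @param network a `stngpe_network`.
#' @param psets character vector of projection parameter-set names (see
#'   [projection_params()]), or a prefix such as `"CTX_STN"` matching all
#'   receptors of a projection.
#' @param scale multiplier (> 0).
#' @export
scale_projection <- function(network, psets, scale) {
  stopifnot(scale > 0)
  hit <- network$syn$pset %in% psets |
    sub("\\..*", "", network$syn$pset) %in% psets
  if (!any(hit)) stop("no synapses match projection(s) ",
                      paste(psets, collapse = ", "))
  network$syn$gbar[hit] <- network$syn$gbar[hit] * scale
  network
}

#' Export the adjacency as an edge list
#' @param network a `stngpe_network`.
#' @param path optional CSV path; if given the table is also written there.
#' @return data frame with one row per synapse.
#' @export
network_edges <- function(network, path = NULL) {
  ed <- network$syn[, c("source_pop", "source_kind", "source_cell",
                        "target_pop", "target_cell", "comp", "receptor",
                        "gbar", "delay")]
  if (!is.null(path)) utils::write.csv(ed, path, row.names = FALSE)
  ed
}

#' Per-cell in-degree of a projection
#' @param network a `stngpe_network`.
#' @param pset projection prefix, e.g. `"CTX_STN"`.
#' @return integer vector of afferent counts per target cell.
#' @export
in_degree <- function(network, pset) {
  syn <- network$syn[sub("\\..*", "", network$syn$pset) == pset, ]
  tapply(syn$afferent_id, syn$target_cell, function(a) length(unique(a)))
}

#' Excitation-inhibition accounting from recorded synaptic currents
#'
#' Uses the synaptic currents recorded on the designated cells of each
#' population (three per population by default): the time-integrated absolute
#' excitatory and inhibitory synaptic charge per recorded cell is averaged
#' and scaled to the population size. The E/I ratio is excitatory over
#' inhibitory total charge (infinite when there is no inhibition), net is the
#' signed difference.
#'
#' @param sim a `stngpe_sim` from [run_network()].
#' @param population `"STN"` or `"GPe"`.
#' @return list with `exc`, `inh` (nA ms, population totals), `ei_ratio`,
#'   `net`, and the per-cell table.
#' @export
ei_accounting <- function(sim, population = c("STN", "GPe")) {
  population <- match.arg(population)
  rec <- sim$syn_currents[[population]]
  if (is.null(rec) || length(rec$cells) < 3L)
    stop("E/I accounting needs synaptic currents recorded on >= 3 cells")
  dt_rec <- sim$dt * sim$record_every
  per_cell <- data.frame(
    cell = rec$cells,
    exc = colSums(abs(rec$exc)) * dt_rec,
    inh = colSums(abs(rec$inh)) * dt_rec)
  n_pop <- sim$sizes[[population]]
  exc <- mean(per_cell$exc) * n_pop
  inh <- mean(per_cell$inh) * n_pop
  list(exc = exc, inh = inh,
       ei_ratio = if (inh > 0) exc / inh else Inf,
       net = exc - inh, per_cell = per_cell)
}

#' Calibrate projection scale factors to target firing rates
#'
#' Coordinate-wise bisection on the conductance scale of the tunable
#' projections until the simulated mean population rates fall inside the
#' target intervals. Deterministic given the seed; returns best-so-far with a
#' warning flag when the iteration budget is exhausted.
#'
#' @param network a `stngpe_network`.
#' @param targets named list of rate intervals, Hz, e.g.
#'   `list(STN = c(17, 37))`.
#' @param tunable named list mapping each target population to the projection
#'   prefix to tune, e.g. `list(STN = "CTX_STN")`.
#' @param config an [engine_config()] used for the calibration runs.
#' @param max_iter bisection iterations per projection.
#' @param scale_range initial bracket for the log-scale search.
#' @return list with `scales`, `rates`, `converged`.
#' @export
calibrate_rates <- function(network, targets, tunable, config,
                            max_iter = 8L, scale_range = c(0.1, 10)) {
  for (tn in names(targets))
    if (diff(targets[[tn]]) <= 0) stop("target interval for ", tn,
                                       " has non-positive width")
  rate_of <- function(net) {
    sim <- run_network(net, config)
    vapply(names(targets), function(p) mean(population_rates(sim, p)),
           numeric(1))
  }
  scales <- stats::setNames(rep(1, length(targets)), names(targets))
  rates <- rate_of(network)
  converged <- all(mapply(function(r, tgt) r >= tgt[1] && r <= tgt[2],
                          rates, targets))
  if (converged)
    return(list(scales = scales, rates = rates, converged = TRUE))
  for (pop in names(targets)) {
    tgt <- targets[[pop]]
    lo <- log(scale_range[1]); hi <- log(scale_range[2])
    best <- 1; best_rate <- rates[[pop]]
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      net_try <- scale_projection(network, tunable[[pop]], exp(mid))
      r <- rate_of(net_try)[[pop]]
      if (abs(r - mean(tgt)) < abs(best_rate - mean(tgt))) {
        best <- exp(mid); best_rate <- r
      }
      if (r >= tgt[1] && r <= tgt[2]) { best <- exp(mid); best_rate <- r; break }
      # rates increase with excitatory scale; assume monotone response
      if (r < tgt[1]) lo <- mid else hi <- mid
    }
    scales[[pop]] <- best
    rates[[pop]] <- best_rate
  }
  conv <- all(mapply(function(r, tgt) r >= tgt[1] && r <= tgt[2],
                     rates, targets))
  if (!conv) warning("rate calibration did not converge; returning best-so-far")
  list(scales = scales, rates = rates, converged = conv)
}
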