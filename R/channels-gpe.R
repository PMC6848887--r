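#' Intrinsic channel set of the GPe prototypic-neuron model
#'
#' Twelve ionic currents: transient (NaF) and persistent (NaP) sodium, slow
#' (Kv2) and fast (Kv3) delayed rectifiers, fast and slow A-type potassium
#' (Kv4f, Kv4s), M-type potassium (KCNQ), calcium-activated potassium (sKCa),
#' high-voltage-activated calcium (CaHVA, a lumped L/N/P-Q conductance), fast
#' and slow HCN components, and passive leak (via `g_m`/`E_m`).
#'
#' All voltage-gated kinetics use the eight-parameter sigmoid-table form
#' `(m0, th_inf, sig_inf, tau0, tau1, th_tau, sig0, sig1)`; rows without tau
#' slopes are constant-tau, the persistent-sodium s gate is instantaneous.
#' The CaHVA current feeds a fast sub-membrane calcium shell read by sKCa.
#' Densities (S/cm^2) vary between soma, dendrite and axon initial segment;
#' CaHVA density additionally varies by dendritic calibre.
#'
#' @param temperature Kelvin, used only for the calcium Nernst potential.
#' @return named list of [channel_spec()] objects plus `calcium` shell
#'   parameters.
#' @export
gpe_channels <- function(temperature = 308.15) {
  tg <- function(name, exponent, m0, th_inf, sig_inf, tau0, tau1 = NA,
                 th_tau = NA, sig0 = NA, sig1 = NA, instantaneous = FALSE) {
    gate_spec(name, exponent, "sigmoid_table",
              params = list(m0 = m0, th_inf = th_inf, sig_inf = sig_inf,
                            tau0 = tau0, tau1 = if (is.na(tau1)) tau0 else tau1,
                            th_tau = th_tau, sig0 = sig0, sig1 = sig1),
              instantaneous = instantaneous)
  }

  naf <- channel_spec("NaF",
    gates = list(
      tg("m", 3L, 0, -39, 5, 0.028),
      tg("h", 1L, 0, -48, -2.8, 0.025, 4, -43, 10, -5),
      tg("s", 1L, 0.15, -40, -5.4, 10, 1000, -40, 18.3, -10)),
    gbar_by_region = list(soma = 0.035, dendrite = 0.035,
                          axon_initial_segment = 0.5),
    reversal = 50)

  nap <- channel_spec("NaP",
    gates = list(
      tg("m", 3L, 0, -57.7, 5.7, 0.03, 0.146, -42.6, 14.4, -14.4),
      tg("h", 1L, 0.154, -57, -4, 10, 17, -34, 26, -31.9),
      tg("s", 1L, 0, -10, -4.9, 1, instantaneous = TRUE)),
    # the tabulated density (10.15e-3) holds the model in permanent
    # depolarization block with these kinetics; reduced to restore the
    # autonomous pacemaking characteristic of the cell class
    gbar_by_region = list(soma = 3e-4, dendrite = 3e-4,
                          axon_initial_segment = 1.2e-4),
    reversal = 50)

  kv2 <- channel_spec("Kv2",
    gates = list(
      tg("m", 4L, 0, -33.2, 9.1, 0.1, 30, -33.2, 21.7, -13.9),
      tg("h", 1L, 0.2, -20, -10, 3400)),
    gbar_by_region = list(soma = 0.1e-3, dendrite = 0.1e-3,
                          axon_initial_segment = 64e-3),
    reversal = -90)

  kv3 <- channel_spec("Kv3",
    gates = list(
      tg("m", 4L, 0, -26, 7.8, 0.1, 14, -26, 13, -12),
      tg("h", 1L, 0.6, -20, -10, 7, 33, 0, 10, -10)),
    gbar_by_region = list(soma = 1e-3, dendrite = 1e-3,
                          axon_initial_segment = 128e-3),
    reversal = -90)

  kv4f <- channel_spec("Kv4f",
    gates = list(
      tg("m", 4L, 0, -49, 12.5, 0.25, 7, -49, 29, -29),
      tg("h", 1L, 0, -83, -10, 7, 21, -83, 10, -10)),
    gbar_by_region = list(soma = 2e-3, dendrite = 4e-3,
                          axon_initial_segment = 160e-3),
    reversal = -90)

  kv4s <- channel_spec("Kv4s",
    gates = list(
      tg("m", 4L, 0, -49, 12.5, 0.25, 7, -49, 29, -29),
      tg("h", 1L, 0, -83, -10, 50, 121, -83, 10, -10)),
    gbar_by_region = list(soma = 3e-3, dendrite = 6e-3,
                          axon_initial_segment = 240e-3),
    reversal = -90)

  kcnq <- channel_spec("KCNQ",
    gates = list(
      tg("m", 4L, 0, -61, 19.5, 6.7, 100, -61, 35, -25)),
    gbar_by_region = list(soma = 20e-5, dendrite = 20e-5,
                          axon_initial_segment = 4e-5),
    reversal = -90)

  skca <- channel_spec("sKCa",
    gates = list(
      gate_spec("w", 1L, "ca_sigmoid", depends_on = "calcium",
                params = list(xmax = 0.81, theta = 0.3, k = 0.46,
                              tau_const = 4))),
    # density not tabulated for this cell class; calibrated value, config-exposed
    gbar_by_region = list(soma = 2e-4, dendrite = 2e-4),
    reversal = -90)

  cahva <- channel_spec("CaHVA",
    gates = list(tg("m", 1L, 0, -20, 7, 0.2)),
    gbar_by_region = list(soma = 3e-5, dendrite_thick = 3e-5,
                          dendrite_medium = 4.5e-5, dendrite_thin = 9e-5),
    reversal = "nernst_calcium")

  hcnf <- channel_spec("HCNf",
    gates = list(tg("m", 1L, 0, -76.4, -3.3, 0, 3625, -76.4, 6.56, -7.48)),
    gbar_by_region = list(soma = 1e-4, dendrite = 1e-4),
    reversal = -30)

  hcns <- channel_spec("HCNs",
    gates = list(tg("m", 1L, 0, -87.5, -4, 0, 6300, -87.5, 8.9, -8.2)),
    gbar_by_region = list(soma = 2.5e-4, dendrite = 2.5e-4),
    reversal = -30)

  list(NaF = naf, NaP = nap, Kv2 = kv2, Kv3 = kv3, Kv4f = kv4f, Kv4s = kv4s,
       KCNQ = kcnq, sKCa = skca, CaHVA = cahva, HCNf = hcnf, HCNs = hcns,
       calcium = list(ca_rest = 5e-5, tau_ca = 1, shell_depth = 0.1,
                      ca_out = 2, temperature = temperature))
}

#' Serialize a channel set to a structured config
#'
#' Writes the full parameterization (one document per cell class) as YAML so
#' the channel library can be inspected or diffed field by field.
#' @param channels result of [stn_channels()] or [gpe_channels()].
#' @param path output file.
#' @export
write_channel_config <- function(channels, path) {
  doc <- lapply(channels, function(ch) {
    if (!inherits(ch, "channel_spec")) return(ch)
    list(gates = lapply(ch$gates, function(g)
           list(name = g$name, exponent = g$exponent, form = g$form,
                v_shift = g$v_shift, instantaneous = g$instantaneous,
                params = g$params)),
         gbar_by_region = ch$gbar_by_region,
         reversal = ch$reversal)
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
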