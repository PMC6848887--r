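#' Intrinsic channel set of the STN projection-neuron model
#'
#' Ten ionic currents: transient (NaF) and persistent (NaP) sodium, delayed
#' rectifier (KDR), fast rectifier (Kv3.1) and calcium-activated (sKCa)
#' potassium, low-threshold T-type (CaT), L-type (CaL) and N-type (CaN)
#' calcium, the hyperpolarization-activated HCN current, and passive leak
#' (leak is carried by the compartment's `g_m`/`E_m`, not listed here).
#'
#' Conductance densities are stored in S/cm^2 as tabulated for the source
#' model; length-2 dendritic entries define a linear density gradient from the
#' dendrite origin (first value) to the tip (second value). The transient
#' sodium and delayed-rectifier rate equations are written in rest-shifted
#' voltage (shift -60 mV), the convention of the Traub-family kinetics they
#' derive from. The T-type current uses the coupled slow-inactivation scheme
#' (gates s, d) with open fraction `r^3 s`; the N-type current uses an
#' instantaneous high-voltage activation gate `q^2` with a slow inactivation
#' gate `u`; the L-type current carries calcium-dependent inactivation. The
#' reconstruction choices for table entries whose printed forms are ambiguous
#' are documented in the methods vignette.
#'
#' @param temperature Kelvin, used only for the calcium Nernst potential.
#' @return named list of [channel_spec()] objects plus a `calcium` element
#'   with the shell parameters (`ca_rest` mM, `tau_ca` ms, `shell_depth` um).
#' @export
stn_channels <- function(temperature = 308.15) {
  sh <- -60  # rate equations in rest-relative voltage: evaluated at v + 60
  naf <- channel_spec("NaF",
    gates = list(
      gate_spec("m", 2L, "rate", v_shift = -sh, params = list(
        alpha = rate_primitive("linoid", c = 0.32, theta = 13.1, k = 4),
        beta  = rate_primitive("linoid", c = -0.28, theta = 40.1, k = -5))),
      gate_spec("h", 1L, "rate", v_shift = -sh, params = list(
        alpha = rate_primitive("expf", c = 0.128, theta = 17, k = 18),
        beta  = rate_primitive("sigmoid", c = 4, theta = 40, k = 5)))),
    gbar_by_region = list(soma = 14.83e-3, dendrite = 1e-7,
                          axon_initial_segment = 14.83e-3),
    reversal = 50)

  nap <- channel_spec("NaP",
    gates = list(
      gate_spec("p", 1L, "inf_tau", instantaneous = TRUE,
                params = list(theta = -52, k = 3))),  # midpoint set for autonomous pacemaking
    gbar_by_region = list(soma = 1.11e-5, dendrite = 8.10e-6),
    reversal = 50)

  kdr <- channel_spec("KDR",
    gates = list(
      gate_spec("n", 1L, "rate", v_shift = -sh, params = list(
        alpha = rate_primitive("linoid", c = 0.016, theta = 35.1, k = 5),
        beta  = rate_primitive("expf", c = 0.25, theta = 20, k = 40)))),
    gbar_by_region = list(soma = 3.84e-3, dendrite = c(4.22e-5, 9.32e-5)),
    reversal = -90)

  kv31 <- channel_spec("Kv31",
    gates = list(
      gate_spec("p", 1L, "inf_tau", params = list(
        theta = -5, k = 9,
        tau_a = 18.7, tau_th1 = -28, tau_k1 = 6, tau_th2 = -4, tau_k2 = -16))),
    gbar_by_region = list(soma = 1.34e-2, dendrite = c(8.91e-4, 10e-4)),
    reversal = -90)

  skca <- channel_spec("sKCa",
    gates = list(
      gate_spec("w", 1L, "ca_sigmoid", depends_on = "calcium",
                params = list(xmax = 0.81, theta = 0.3, k = 0.46,
                              tau_const = 40))),
    gbar_by_region = list(soma = 6.84e-5, dendrite = 3.92e-5),
    reversal = -90)

  cat_ <- channel_spec("CaT",
    gates = list(
      gate_spec("r", 3L, "rate", params = list(
        alpha = rate_primitive("sigmoid", c = 1, theta = -28.2, k = 13.5,
                               a = 1.7),
        beta  = rate_primitive("expsig", th1 = -63, k1 = 7.8, a = 1.7,
                               th2 = -28.8, k2 = 13.5))),
      gate_spec("s", 1L, "wang_sd", params = list())),
    gbar_by_region = list(soma = 0, dendrite = c(1.17e-3, 1.67e-3)),
    reversal = "nernst_calcium")

  cal <- channel_spec("CaL",
    gates = list(
      gate_spec("q", 2L, "inf_tau", params = list(
        theta = -24.6, k = 11.3,
        # 1.25 / cosh(0.03 (v + 37.1)) as a symmetric two-exponential bell
        tau_a = 2.5, tau_th1 = -37.1, tau_k1 = 100 / 3,
        tau_th2 = -37.1, tau_k2 = -100 / 3)),
      gate_spec("h", 1L, "ca_inact", depends_on = "calcium",
                params = list(x0 = 0.53, amp = 0.47, theta = 0.7, k = 0.15,
                              tau_const = 122))),
    # tabulated dendritic range [1.21, 18.7]e-4 mapped proximal-high to
    # distal-low: L-type channels concentrate peri-somatically, and the
    # distal co-location with NMDA synapses otherwise produces runaway
    # dendritic plateaus
    gbar_by_region = list(soma = 9.50e-4, dendrite = c(18.7e-4, 1.21e-4)),
    reversal = "nernst_calcium")

  can <- channel_spec("CaN",
    gates = list(
      gate_spec("q", 2L, "inf_tau", instantaneous = TRUE,
                params = list(theta = -20, k = 7)),
      gate_spec("u", 1L, "inf_tau", params = list(
        theta = -60, k = -12.5,
        # 98 / cosh(0.021 (v - 10.1))
        tau_a = 196, tau_th1 = 10.1, tau_k1 = 1 / 0.021,
        tau_th2 = 10.1, tau_k2 = -1 / 0.021))),
    gbar_by_region = list(soma = 1.15e-3, dendrite = 4.79e-4),
    reversal = "nernst_calcium")

  hcn <- channel_spec("HCN",
    gates = list(
      gate_spec("f", 1L, "inf_tau", params = list(
        theta = -75, k = -5.5,
        # Huguenard-style anomalous-rectifier time constant
        tau_a = 1, tau_th1 = -169.65, tau_k1 = 1 / 0.086,
        tau_th2 = 26.71, tau_k2 = -1 / 0.07))),
    gbar_by_region = list(soma = 1.01e-3, dendrite = 5.10e-4),
    reversal = -30)

  list(NaF = naf, NaP = nap, KDR = kdr, Kv31 = kv31, sKCa = skca,
       CaT = cat_, CaL = cal, CaN = can, HCN = hcn,
       calcium = list(ca_rest = 1e-4, tau_ca = 185.7, shell_depth = 0.1,
                      ca_out = 2, temperature = temperature))
}
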