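#' Gating-kinetics specifications
#'
#' Every voltage- or calcium-dependent gate in the channel library is
#' described by a `gate_spec`: a small parametric object from which both the
#' R reference evaluators ([steady_state()], [time_constant()]) and the
#' compiled integrator (via voltage-grid lookup tables built in R) compute
#' identical kinetics.
#'
#' Supported functional forms (`form`):
#' * `"rate"`: opening/closing rates alpha(v), beta(v), each one of a small
#'   set of rate primitives; steady state alpha/(alpha+beta), time constant
#'   1/(alpha+beta). The linoid primitive `c (theta - v)/(exp((theta-v)/k) - 1)`
#'   resolves its removable 0/0 singularity at v = theta by the analytic limit
#'   `c k` (guard |theta - v| < 1e-6 mV).
#' * `"inf_tau"`: Boltzmann steady state `xmax / (1 + exp(-(v - theta)/k))`
#'   (negative `k` encodes inactivation) with a time constant that is either a
#'   constant or a two-exponential bell
#'   `a / (exp((th1 - v)/k1) + exp((th2 - v)/k2)) + b`.
#' * `"sigmoid_table"`: the eight-parameter GPe form
#'   `x_inf = m0 + (1 - m0)/(1 + exp(-(v - th_inf)/sig_inf))`,
#'   `tau = tau0 + (tau1 - tau0)/(exp(-(v - th_tau)/sig0) + exp((v - th_tau)/|sig1|))`;
#'   rows with no tau slopes (tau0 = tau1) give a constant, rows with no tau
#'   at all are instantaneous gates.
#' * `"ca_sigmoid"`: calcium-activated gate (sKCa),
#'   `x_inf = xmax / (1 + exp(-(log10(ca_uM) - theta)/k))`, constant tau.
#' * `"ca_inact"`: calcium-dependent inactivation (CaL),
#'   `x_inf = x0 + amp / (1 + exp((ca_uM - theta)/k))`, constant tau.
#' * `"wang_sd"`: coupled slow-inactivation pair (s, d) of the T-type calcium
#'   current: `ds/dt = alpha_s (1 - s - d) - beta_s s`,
#'   `dd/dt = beta_d (1 - s - d) - alpha_d d`. The channel open fraction uses
#'   s only.
#'
#' A `v_shift` (mV) is added to the membrane potential before evaluating the
#' kinetics; it expresses rate equations written in rest-relative voltage.
#'
#' @param name gate name.
#' @param exponent integer power of the gate in the channel current.
#' @param form functional form, see Details.
#' @param params named numeric parameters of the form.
#' @param depends_on `"voltage"` or `"calcium"`.
#' @param v_shift voltage shift in mV added before evaluation.
#' @param instantaneous if `TRUE` the gate tracks its steady state exactly.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(name, exponent = 1L,
                      form = c("rate", "inf_tau", "sigmoid_table",
                               "ca_sigmoid", "ca_inact", "wang_sd"),
                      params = list(), depends_on = c("voltage", "calcium"),
                      v_shift = 0, instantaneous = FALSE) {
  form <- match.arg(form)
  depends_on <- match.arg(depends_on)
  stopifnot(exponent >= 0)
  structure(list(name = name, exponent = as.integer(exponent), form = form,
                 params = params, depends_on = depends_on, v_shift = v_shift,
                 instantaneous = isTRUE(instantaneous)),
            class = "gate_spec")
}

# rate primitives ------------------------------------------------------------

# linoid c*(theta - v)/(exp((theta - v)/k) - 1), limit c*k at v = theta
.rate_linoid <- function(v, c_, theta, k) {
  u <- theta - v
  out <- numeric(length(v))
  sing <- abs(u) < 1e-6
  out[sing] <- c_ * k
  out[!sing] <- c_ * u[!sing] / (exp(u[!sing] / k) - 1)
  out
}

.rate_exp <- function(v, c_, theta, k) c_ * exp((theta - v) / k)

.rate_sigmoid <- function(v, c_, theta, k, a = 1) c_ / (a + exp((theta - v) / k))

# exp((th1 - v)/k1) / (a + exp((th2 - v)/k2))
.rate_expsig <- function(v, th1, k1, a, th2, k2) {
  exp((th1 - v) / k1) / (a + exp((th2 - v) / k2))
}

.eval_rate_primitive <- function(p, v) {
  switch(p$kind,
    linoid  = .rate_linoid(v, p$c, p$theta, p$k),
    expf    = .rate_exp(v, p$c, p$theta, p$k),
    sigmoid = .rate_sigmoid(v, p$c, p$theta, p$k, if (is.null(p$a)) 1 else p$a),
    expsig  = .rate_expsig(v, p$th1, p$k1, p$a, p$th2, p$k2),
    stop("unknown rate primitive ", p$kind))
}

rate_primitive <- function(..kind.., ...) c(list(kind = ..kind..), list(...))

# form evaluators ------------------------------------------------------------

.gate_alpha_beta <- function(g, v) {
  v <- v + g$v_shift
  list(alpha = .eval_rate_primitive(g$params$alpha, v),
       beta  = .eval_rate_primitive(g$params$beta, v))
}

.gate_xinf_v <- function(g, v) {
  vv <- v + g$v_shift
  p <- g$params
  switch(g$form,
    rate = {
      ab <- .gate_alpha_beta(g, v)
      ab$alpha / (ab$alpha + ab$beta)
    },
    inf_tau = {
      xmax <- if (is.null(p$xmax)) 1 else p$xmax
      xmax / (1 + exp(-(vv - p$theta) / p$k))
    },
    sigmoid_table = p$m0 + (1 - p$m0) / (1 + exp(-(vv - p$th_inf) / p$sig_inf)),
    stop("gate form ", g$form, " is not voltage-only"))
}

.gate_tau_v <- function(g, v) {
  vv <- v + g$v_shift
  p <- g$params
  tau <- switch(g$form,
    rate = {
      ab <- .gate_alpha_beta(g, v)
      1 / (ab$alpha + ab$beta)
    },
    inf_tau = {
      if (!is.null(p$tau_const)) rep(p$tau_const, length(v))
      else {
        b <- if (is.null(p$tau_b)) 0 else p$tau_b
        p$tau_a / (exp((p$tau_th1 - vv) / p$tau_k1) +
                   exp((p$tau_th2 - vv) / p$tau_k2)) + b
      }
    },
    sigmoid_table = {
      if (is.na(p$th_tau) || p$tau0 == p$tau1) rep(p$tau0, length(v))
      else {
        den <- exp(-(vv - p$th_tau) / p$sig0) + exp((vv - p$th_tau) / abs(p$sig1))
        p$tau0 + (p$tau1 - p$tau0) / den
      }
    },
    stop("gate form ", g$form, " is not voltage-only"))
  pmax(tau, 0.01)  # floor keeps exp(-dt/tau) well-defined at extreme voltages
}

.gate_xinf_ca <- function(g, ca) {
  p <- g$params
  ca_uM <- ca * 1e3  # mM -> uM
  switch(g$form,
    ca_sigmoid = p$xmax / (1 + exp(-(log10(ca_uM) - p$theta) / p$k)),
    ca_inact   = p$x0 + p$amp / (1 + exp((ca_uM - p$theta) / p$k)),
    stop("gate form ", g$form, " is not calcium-dependent"))
}

#' Steady-state open fraction of a gate
#'
#' @param g a [gate_spec()].
#' @param v membrane potential, mV.
#' @param ca shell calcium concentration, mM (required for calcium-dependent
#'   gates; must be positive).
#' @return open fraction in `[0, 1]`.
#' @export
steady_state <- function(g, v = NULL, ca = NULL) {
  stopifnot(inherits(g, "gate_spec"))
  if (g$depends_on == "calcium") {
    if (is.null(ca) || any(ca <= 0))
      stop("calcium-dependent gate '", g$name, "' requires ca > 0")
    return(.gate_xinf_ca(g, ca))
  }
  stopifnot(is.finite(v))
  if (g$form == "wang_sd") {
    # steady state of the coupled (s, d) pair, reported for the s component:
    # with w = 1 - s - d, s* = (alpha_s/beta_s) w*, d* = (beta_d/alpha_d) w*
    ab <- .wang_sd_rates(g, v)
    w <- 1 / (1 + ab$alpha_s / ab$beta_s + ab$beta_d / ab$alpha_d)
    (ab$alpha_s / ab$beta_s) * w
  } else {
    .gate_xinf_v(g, v)
  }
}

#' Voltage-dependent time constant of a gate
#'
#' @inheritParams steady_state
#' @return time constant in ms (strictly positive).
#' @export
time_constant <- function(g, v) {
  stopifnot(inherits(g, "gate_spec"))
  if (g$depends_on == "calcium") return(rep(g$params$tau_const, length(v)))
  if (g$instantaneous) return(rep(0, length(v)))
  .gate_tau_v(g, v)
}

#' Advance a gate by one time step at frozen voltage
#'
#' Exponential-Euler update `x' = x_inf + (x - x_inf) exp(-dt/tau)`; exact for
#' the linear gate ODE when v (and ca) are held fixed over the step.
#'
#' @param g a [gate_spec()].
#' @param x current open fraction.
#' @param v membrane potential, mV.
#' @param ca shell calcium, mM (calcium-dependent gates).
#' @param dt time step, ms (> 0).
#' @return updated open fraction, clamped to `[0, 1]`.
#' @export
advance_gate <- function(g, x, v = NULL, ca = NULL, dt) {
  stopifnot(dt > 0)
  if (g$depends_on == "calcium") {
    xinf <- .gate_xinf_ca(g, ca)
    tau <- g$params$tau_const
  } else {
    xinf <- .gate_xinf_v(g, v)
    if (g$instantaneous) return(pmin(pmax(xinf, 0), 1))
    tau <- .gate_tau_v(g, v)
  }
  pmin(pmax(xinf + (x - xinf) * exp(-dt / tau), 0), 1)
}

# Wang-style coupled (s, d) inactivation rates for the T-type current
.wang_sd_rates <- function(g, v) {
  p <- g$params
  alpha_s <- exp(-(v + 160.3) / 17.8)
  root <- sqrt(0.25 + exp((v + 83.5) / 6.3))
  beta_s <- (root - 0.5) * alpha_s
  alpha_d <- (1 + exp((v + 37.4) / 30)) / (240 * (0.5 + root))
  beta_d <- (root - 0.5) * alpha_d
  list(alpha_s = alpha_s, beta_s = beta_s, alpha_d = alpha_d, beta_d = beta_d)
}

#' Ionic current through a channel
#'
#' Ohmic current `I = gbar * prod(x_i^p_i) * (v - e_rev)` in mA/cm^2 when
#' `gbar` is in S/cm^2 and voltages in mV.
#'
#' @param gbar maximal conductance, S/cm^2.
#' @param gates numeric vector of gate open fractions.
#' @param exponents integer vector of gate exponents (recycled against gates).
#' @param v membrane potential, mV.
#' @param e_rev reversal potential, mV.
#' @return current density, mA/cm^2.
#' @export
channel_current <- function(gbar, gates, exponents, v, e_rev) {
  stopifnot(gbar >= 0, length(gates) == length(exponents))
  gbar * prod(gates^exponents) * (v - e_rev)
}

#' Nernst potential for calcium
#'
#' `E_Ca = (R T / (z F)) ln(ca_out / ca_in)` with z = 2.
#'
#' @param ca_in,ca_out intra-/extracellular calcium, mM (> 0).
#' @param temperature Kelvin (default 308.15 K, i.e. 35 C).
#' @return reversal potential, mV.
#' @export
nernst_calcium <- function(ca_in, ca_out = 2, temperature = 308.15) {
  if (any(ca_in <= 0) || any(ca_out <= 0))
    stop("calcium concentrations must be positive")
  R <- 8.314; F <- 96485
  1e3 * R * temperature / (2 * F) * log(ca_out / ca_in)
}

#' Advance sub-membrane shell calcium by one step
#'
#' First-order buffering `d[Ca]/dt = -I_Ca / (2 F d) + ([Ca]0 - [Ca]) / tau`,
#' with the unit-conversion constant folded in so that `i_ca_total` in mA/cm^2
#' and `shell_depth` in micrometres give mM/ms. Integrated by the exact
#' exponential update at frozen current.
#'
#' @param ca current shell calcium, mM.
#' @param i_ca_total total calcium current density, mA/cm^2 (inward negative).
#' @param shell_depth shell thickness, um (> 0).
#' @param tau_ca decay time constant, ms (> 0).
#' @param ca_rest resting concentration, mM.
#' @param dt time step, ms.
#' @return updated concentration, mM (kept positive).
#' @export
update_calcium <- function(ca, i_ca_total, shell_depth = 0.1, tau_ca, ca_rest,
                           dt) {
  stopifnot(shell_depth > 0, tau_ca > 0, dt > 0)
  F <- 96485
  d_cm <- shell_depth * 1e-4
  # mA/cm^2 -> mM/ms: (1e-3 A/cm^2)/(2 F d_cm) mol/(cm^3 s) = 1/(2 F d_cm) mM/ms
  influx <- -i_ca_total / (2 * F * d_cm)
  ca_inf <- ca_rest + influx * tau_ca
  pmax(ca_inf + (ca - ca_inf) * exp(-dt / tau_ca), 1e-9)
}

#' Channel specification
#'
#' Bundles a named set of gates with per-region maximal conductances and the
#' reversal-potential rule.
#'
#' @param name channel name.
#' @param gates list of [gate_spec()] objects.
#' @param gbar_by_region named list mapping region tags to conductance
#'   (S/cm^2); a region may map to length-2 `c(proximal, distal)` for a linear
#'   density gradient along dendritic path distance.
#' @param reversal fixed value in mV, or the string `"nernst_calcium"`.
#' @param is_ca_source does the current feed the calcium shell (Ca channels)?
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(name, gates, gbar_by_region, reversal,
                         is_ca_source = identical(reversal, "nernst_calcium")) {
  stopifnot(all(vapply(gates, inherits, TRUE, "gate_spec")))
  stopifnot(all(unlist(gbar_by_region) >= 0))
  structure(list(name = name, gates = gates, gbar_by_region = gbar_by_region,
                 reversal = reversal, is_ca_source = is_ca_source),
            class = "channel_spec")
}

# gbar (S/cm^2) for a compartment given region and relative dendritic position
.gbar_for_compartment <- function(ch, region, frac_dist) {
  g <- ch$gbar_by_region
  val <- g[[region]]
  if (is.null(val)) {
    # generic "dendrite" entry covers all calibres
    if (startsWith(region, "dendrite")) val <- g[["dendrite"]]
    if (is.null(val)) return(0)
  }
  if (length(val) == 2L) val[1] + (val[2] - val[1]) * frac_dist else val
}
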