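#' Parameters of a cooperatively gating channel population
#'
#' Describes a population of sodium channels in which each channel is coupled
#' to \code{K} neighbours, the opening of each neighbour shifting the
#' channel's activation curve by \code{J} millivolts.  The single-channel
#' steady-state activation is a Boltzmann function
#' \deqn{m_\infty(V) = 1 / (1 + \exp(-(V - V_{1/2})/k)),}
#' raised to the exponent \code{q} to give the open probability, and
#' activation relaxes mono-exponentially with time constant \code{tau_m}.
#' The effective coupling strength is \code{mu = K * J} (mV): the voltage
#' shift experienced when all neighbours of an available channel are open.
#'
#' The default half-activation voltage and slope place the collective
#' threshold in the physiological range for an axon initial segment; all
#' values are configuration, not constants, and should be adjusted to the
#' channel population under study.
#'
#' @param v_half Boltzmann half-activation voltage (mV).
#' @param k Boltzmann slope factor (mV), must be positive.
#' @param q Activation exponent (positive integer; 1 gives mono-exponential
#'   activation, 3 the delayed activation of classical sodium-channel models).
#' @param tau_m Activation time constant (ms), must be positive.
#' @param K Number of coupled neighbour channels (non-negative integer).
#' @param J Coupling constant (mV per open neighbour, non-negative).
#' @return An object of class \code{coop_gate_params}.
#' @seealso [coop_mu()], [steady_gate()], [collective_activation_curve()]
#' @examples
#' cg <- coop_gate_params(K = 6, J = 8)  # mu = 48 mV, twice critical for k = 6
#' coop_mu(cg)
#' @export
coop_gate_params <- function(v_half = -30, k = 6, q = 1L, tau_m = 0.1,
                             K = 6L, J = 0) {
  stopifnot(is.numeric(v_half), length(v_half) == 1L, is.finite(v_half))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` (slope factor) must be a single positive number", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q))
    stop("`q` (activation exponent) must be a positive integer", call. = FALSE)
  if (!is.numeric(tau_m) || length(tau_m) != 1L || tau_m <= 0)
    stop("`tau_m` must be a single positive time constant (ms)", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K))
    stop("`K` (neighbour count) must be a non-negative integer", call. = FALSE)
  if (!is.numeric(J) || length(J) != 1L || J < 0)
    stop("`J` (coupling constant, mV) must be non-negative", call. = FALSE)
  structure(
    list(v_half = v_half, k = k, q = as.integer(q), tau_m = tau_m,
         K = as.integer(K), J = J),
    class = "coop_gate_params"
  )
}

#' Effective coupling strength of a cooperative gate
#'
#' @param params A [coop_gate_params()] object.
#' @return The effective coupling \code{mu = K * J} in mV.
#' @export
coop_mu <- function(params) {
  stopifnot(inherits(params, "coop_gate_params"))
  params$K * params$J
}

#' Replace the effective coupling of a gate parameter set
#'
#' Convenience for parameter sweeps over the effective coupling
#' \code{mu = K * J}: keeps \code{K} and adjusts \code{J = mu / K}.
#'
#' @param params A [coop_gate_params()] object.
#' @param mu Desired effective coupling (mV, non-negative).
#' @return The modified parameter object.
#' @export
set_coop_mu <- function(params, mu) {
  stopifnot(inherits(params, "coop_gate_params"), is.numeric(mu),
            length(mu) == 1L, mu >= 0)
  if (params$K == 0L && mu > 0)
    stop("cannot set mu > 0 with K = 0 neighbours", call. = FALSE)
  params$J <- if (params$K > 0L) mu / params$K else 0
  params
}

#' @export
print.coop_gate_params <- function(x, ...) {
  cat("Cooperative gate parameters\n")
  cat(sprintf("  Boltzmann: v_half = %g mV, k = %g mV, exponent q = %d\n",
              x$v_half, x$k, x$q))
  cat(sprintf("  kinetics:  tau_m = %g ms\n", x$tau_m))
  cat(sprintf("  coupling:  K = %d neighbours x J = %g mV  (mu = %g mV)\n",
              x$K, x$J, x$K * x$J))
  invisible(x)
}

#' Wang-Buzsaki membrane parameters
#'
#' Passive and active membrane parameters of the Wang-Buzsaki (WB)
#' fast-spiking interneuron model: maximal conductance densities, reversal
#' potentials, membrane capacitance and the temperature-like rate factor
#' \code{phi} that scales all gating kinetics.  Defaults are the standard
#' published values (C = 1 uF/cm2, gNa = 35, gK = 9, gL = 0.1 mS/cm2,
#' ENa = 55, EK = -90, EL = -65 mV, phi = 5), stored here as overridable
#' configuration.
#'
#' @param c_m Membrane capacitance (uF/cm2).
#' @param g_na,g_k,g_l Maximal sodium, potassium and leak conductance
#'   densities (mS/cm2).
#' @param e_na,e_k,e_l Reversal potentials (mV); must satisfy
#'   \code{e_k < e_l < e_na}.
#' @param phi Dimensionless rate factor applied to the h and n kinetics.
#' @return An object of class \code{wb_params}.
#' @export
wb_params <- function(c_m = 1, g_na = 35, g_k = 9, g_l = 0.1,
                      e_na = 55, e_k = -90, e_l = -65, phi = 5) {
  if (any(c(g_na, g_k, g_l) < 0))
    stop("conductance densities must be non-negative", call. = FALSE)
  if (c_m <= 0) stop("`c_m` must be positive", call. = FALSE)
  if (!(e_k < e_l && e_l < e_na))
    stop("reversal potentials must satisfy e_k < e_l < e_na", call. = FALSE)
  if (phi <= 0) stop("`phi` must be positive", call. = FALSE)
  structure(
    list(c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
         e_na = e_na, e_k = e_k, e_l = e_l, phi = phi),
    class = "wb_params"
  )
}

#' @export
print.wb_params <- function(x, ...) {
  cat("Wang-Buzsaki membrane parameters\n")
  cat(sprintf("  C = %g uF/cm2, gNa = %g, gK = %g, gL = %g mS/cm2\n",
              x$c_m, x$g_na, x$g_k, x$g_l))
  cat(sprintf("  ENa = %g, EK = %g, EL = %g mV, phi = %g\n",
              x$e_na, x$e_k, x$e_l, x$phi))
  invisible(x)
}

#' Cooperative Wang-Buzsaki neuron parameters
#'
#' Parameters of the single-compartment cooperative Wang-Buzsaki (cWB)
#' neuron, in which a fraction \code{p} of the sodium conductance is carried
#' by cooperatively gating channels (kinetics in \code{coop}) and the
#' remaining fraction \code{1 - p} by the standard WB sodium channel with
#' instantaneous activation \code{m_inf(V)^q_noncoop} and inactivation h.
#'
#' Inactivation of the cooperative fraction is channel-state dependent:
#' channels inactivate from the open state, so the closing rate of the
#' cooperative inactivation gate is multiplied by
#' \code{1 + kappa * m_c^q} — inactivation remains an independent,
#' first-order process but speeds up when the cooperative fraction opens.
#' \code{kappa = 0} recovers purely voltage-dependent WB inactivation.
#'
#' The steady-state activation of the cooperative fraction can follow either
#' the Boltzmann curve of \code{coop} (\code{coop_kinetics = "boltzmann"}) or
#' the WB sodium-channel \code{m_inf} evaluated at the shifted voltage
#' (\code{coop_kinetics = "wb"}); the collective phenomenology is robust to
#' this choice.
#'
#' The default cooperative gate of the neuron is a low-threshold,
#' delayed-activation sodium gate (Boltzmann midpoint -50 mV, slope 4 mV,
#' exponent 3, activation time constant 0.05 ms, 6 coupled neighbours),
#' i.e. the axon-initial-segment-like channel population the cooperative
#' fraction is meant to represent.  The delayed (cubed) activation keeps
#' the resting open probability of the cooperative fraction negligible, so
#' the neuron retains a quiescent resting state for any \code{p}; the
#' midpoint and slope place the collective all-or-none jump a few mV below
#' the activation threshold of the non-cooperative sodium current once the
#' coupling exceeds a few multiples of critical.
#'
#' @param wb A [wb_params()] object.
#' @param p Fraction of cooperative sodium channels, in [0, 1].
#' @param coop A [coop_gate_params()] object for the cooperative fraction.
#' @param kappa Non-negative gain of the open-state-dependent speed-up of
#'   cooperative-fraction inactivation.
#' @param q_noncoop Activation exponent of the non-cooperative fraction
#'   (WB default 3).
#' @param coop_kinetics Steady-state activation family for the cooperative
#'   fraction: \code{"boltzmann"} or \code{"wb"}.
#' @return An object of class \code{cwb_params}.
#' @examples
#' # 10% strongly coupled channels (mu = 6 x 24 = 144 mV)
#' prm <- cwb_params(p = 0.1, coop = coop_gate_params(
#'   v_half = -50, k = 4, q = 3, tau_m = 0.05, K = 6, J = 24))
#' @export
cwb_params <- function(wb = wb_params(), p = 0,
                       coop = coop_gate_params(v_half = -50, k = 4, q = 3,
                                               tau_m = 0.05, K = 6, J = 0),
                       kappa = 25, q_noncoop = 3L,
                       coop_kinetics = c("boltzmann", "wb")) {
  stopifnot(inherits(wb, "wb_params"), inherits(coop, "coop_gate_params"))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("`p` (cooperative fraction) must be in [0, 1]", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("`kappa` must be non-negative", call. = FALSE)
  if (q_noncoop < 1 || q_noncoop != round(q_noncoop))
    stop("`q_noncoop` must be a positive integer", call. = FALSE)
  coop_kinetics <- match.arg(coop_kinetics)
  structure(
    list(wb = wb, p = p, coop = coop, kappa = kappa,
         q_noncoop = as.integer(q_noncoop), coop_kinetics = coop_kinetics),
    class = "cwb_params"
  )
}

#' @export
print.cwb_params <- function(x, ...) {
  cat(sprintf("Cooperative Wang-Buzsaki neuron (p = %g, mu = %g mV, kappa = %g)\n",
              x$p, coop_mu(x$coop), x$kappa))
  cat(sprintf("  cooperative kinetics: %s, q = %d; non-cooperative exponent %d\n",
              x$coop_kinetics, x$coop$q, x$q_noncoop))
  print(x$wb)
  invisible(x)
}
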