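# Wang-Buzsaki gating rate functions (1/ms).  The x/(1-exp(-x/s)) forms are
# evaluated with a series expansion near their removable singularity so the
# R and compiled implementations agree to rounding.
.vtrap <- function(x, s) {
  ifelse(abs(x / s) < 1e-6, s * (1 - x / (2 * s)), x / (1 - exp(-x / s)))
}
.wb_rates <- function(v) {
  list(
    am = 0.1 * .vtrap(v + 35, 10),
    bm = 4 * exp(-(v + 60) / 18),
    ah = 0.07 * exp(-(v + 58) / 20),
    bh = 1 / (1 + exp(-0.1 * (v + 28))),
    an = 0.01 * .vtrap(v + 34, 10),
    bn = 0.125 * exp(-(v + 44) / 80)
  )
}

# steady-state activation of the cooperative fraction at a (shifted) voltage
.coop_minf <- function(v_shifted, params) {
  if (params$coop_kinetics == "wb") {
    r <- .wb_rates(v_shifted)
    r$am / (r$am + r$bm)
  } else {
    stats::plogis((v_shifted - params$coop$v_half) / params$coop$k)
  }
}

# flat parameter list handed to the compiled integrator
.cwb_par_list <- function(params) {
  stopifnot(inherits(params, "cwb_params"))
  wb <- params$wb; cg <- params$coop
  list(c_m = wb$c_m, g_na = wb$g_na, g_k = wb$g_k, g_l = wb$g_l,
       e_na = wb$e_na, e_k = wb$e_k, e_l = wb$e_l, phi = wb$phi,
       p = params$p, v_half = cg$v_half, k_slope = cg$k, q = as.numeric(cg$q),
       tau_m = cg$tau_m, mu = coop_mu(cg), kappa = params$kappa,
       q_noncoop = as.numeric(params$q_noncoop),
       coop_wb = as.integer(params$coop_kinetics == "wb"))
}

#' Right-hand side of the cooperative Wang-Buzsaki model
#'
#' Time derivatives of the state \code{(v, h, n, m_c, h_c)} of the
#' single-compartment cWB neuron.  The current balance is
#' \deqn{C \dot V = -g_{Na}\left[(1-p)\, m_\infty(V)^{q_{nc}} h
#'   + p\, m_c^{q} h_c\right](V - E_{Na}) - g_K n^4 (V - E_K)
#'   - g_L (V - E_L) + I_{ext},}
#' with standard WB kinetics for \code{h} and \code{n} (rates scaled by
#' \code{phi}), mean-field cooperative kinetics for \code{m_c} — relaxation
#' to the steady-state activation evaluated at
#' \eqn{V + \mu\, h_c\, m_c^q} with time constant \code{tau_m}, the
#' available fraction being the live \code{h_c} — and open-state-dependent
#' inactivation of the cooperative fraction:
#' \eqn{\dot h_c = \phi[\alpha_h(V)(1 - h_c)
#'   - \beta_h(V)(1 + \kappa m_c^q) h_c]}.
#'
#' With \code{p = 0} the derivative reduces exactly to the plain WB model.
#'
#' @param state Named numeric vector \code{c(v, h, n, m_c, h_c)}.
#' @param i_ext External current density (uA/cm2).
#' @param params A [cwb_params()] object.
#' @return Named numeric vector of time derivatives (mV/ms and 1/ms).
#' @export
cwb_rhs <- function(state, i_ext, params) {
  stopifnot(inherits(params, "cwb_params"))
  v <- state[["v"]]; h <- state[["h"]]; n <- state[["n"]]
  m_c <- state[["m_c"]]; h_c <- state[["h_c"]]
  wb <- params$wb; cg <- params$coop
  r <- .wb_rates(v)
  minf <- r$am / (r$am + r$bm)
  mcq <- m_c^cg$q
  i_na <- wb$g_na * ((1 - params$p) * minf^params$q_noncoop * h +
                       params$p * mcq * h_c) * (v - wb$e_na)
  i_k <- wb$g_k * n^4 * (v - wb$e_k)
  i_l <- wb$g_l * (v - wb$e_l)
  c(v = (-i_na - i_k - i_l + i_ext) / wb$c_m,
    h = wb$phi * (r$ah * (1 - h) - r$bh * h),
    n = wb$phi * (r$an * (1 - n) - r$bn * n),
    m_c = (.coop_minf(v + coop_mu(cg) * h_c * mcq, params) - m_c) / cg$tau_m,
    h_c = wb$phi * (r$ah * (1 - h_c) - r$bh * (1 + params$kappa * mcq) * h_c))
}

# state with all gating variables at their coupled steady values for a
# clamped voltage (m_c on the lower branch)
.state_at_voltage <- function(v, params) {
  r <- .wb_rates(v)
  h <- r$ah / (r$ah + r$bh)
  n <- r$an / (r$an + r$bn)
  cg <- params$coop; mu <- coop_mu(cg)
  m_c <- 0; h_c <- h
  for (i in 1:200) { # coupled (m_c, h_c) sub-fixed-point
    m_new <- .coop_minf(v + mu * h_c * m_c^cg$q, params)
    h_new <- r$ah / (r$ah + r$bh * (1 + params$kappa * m_new^cg$q))
    if (abs(m_new - m_c) < 1e-14 && abs(h_new - h_c) < 1e-14) break
    m_c <- m_new; h_c <- h_new
  }
  c(v = v, h = h, n = n, m_c = m_c, h_c = h_c)
}

#' Robust initial state for stimulus protocols
#'
#' The quiescent state at the given holding current when one exists;
#' otherwise the quiescent state at zero current; otherwise (for tonically
#' active cells, e.g. strongly increased sodium density) a hyperpolarized
#' state with all gates at their steady values for -70 mV.
#'
#' @param params A [cwb_params()] object.
#' @param i_ext Holding current density (uA/cm2).
#' @return Named state vector \code{c(v, h, n, m_c, h_c)}.
#' @export
initial_state <- function(params, i_ext = 0) {
  tryCatch(resting_state(params, i_ext = i_ext),
           error = function(e)
             tryCatch(resting_state(params, i_ext = 0),
                      error = function(e2) .state_at_voltage(-70, params)))
}

#' Resting state of the cWB neuron
#'
#' Solves the full right-hand side for a quiescent fixed point at a given
#' holding current: gating variables at their (coupled) steady states and
#' zero net membrane current, located by root finding on the steady-state
#' I-V relation over the subthreshold range.
#'
#' @param params A [cwb_params()] object.
#' @param i_ext Holding current density (uA/cm2).
#' @param v_range Voltage range (mV) scanned for the quiescent root.
#' @return Named state vector \code{c(v, h, n, m_c, h_c)}.
#' @export
resting_state <- function(params, i_ext = 0, v_range = c(-90, -40)) {
  stopifnot(inherits(params, "cwb_params"))
  gates_at <- function(v) .state_at_voltage(v, params)
  iv <- function(v) {
    st <- gates_at(v)
    cwb_rhs(st, i_ext, params)[["v"]]
  }
  # the quiescent state is the first downward zero crossing of dV/dt
  # scanning from hyperpolarized values
  vg <- seq(v_range[1], v_range[2], by = 0.25)
  ivg <- vapply(vg, iv, numeric(1))
  ch <- which(ivg[-length(ivg)] > 0 & ivg[-1] <= 0)
  if (!length(ch))
    stop("no quiescent state in [", v_range[1], ", ", v_range[2],
         "] mV at i_ext = ", i_ext, " (cell may be tonically active)",
         call. = FALSE)
  root <- stats::uniroot(iv, interval = c(vg[ch[1]], vg[ch[1] + 1]),
                         tol = 1e-10)
  gates_at(root$root)
}

#' Simulate the cooperative Wang-Buzsaki neuron
#'
#' Fixed-step 4th-order Runge-Kutta integration of the cWB model.  The
#' stimulus is held piecewise constant over each step.  Gating variables
#' are clipped to [0, 1] after every step and the number of clip events is
#' recorded (zero at the default step size).  The integration is
#' deterministic given the stimulus, parameters and step size.
#'
#' @param params A [cwb_params()] object.
#' @param stimulus External current: a single number (constant current), a
#'   numeric vector with one value per integration step, or a function of
#'   time \code{f(t_ms)} evaluated at step midpoints.
#' @param t_end Simulation length (ms).
#' @param dt Integration step (ms); default 0.01, small enough to resolve
#'   the sub-millisecond cooperative gate.
#' @param state0 Initial state: \code{"rest"} (the quiescent state at the
#'   first stimulus value) or a named state vector.
#' @param seed Optional integer recorded in the trajectory metadata (the
#'   integrator itself is deterministic; randomness lives in the stimulus).
#' @return An object of class \code{cwb_trajectory}: list with \code{t},
#'   \code{v}, \code{h}, \code{n}, \code{m_c}, \code{h_c} (all length
#'   \code{n_steps + 1}), \code{i_input} (length \code{n_steps}),
#'   \code{dt}, \code{clip_events}, \code{params}, \code{seed}.
#' @export
integrate_cwb <- function(params, stimulus, t_end, dt = 0.01,
                          state0 = "rest", seed = NULL) {
  stopifnot(inherits(params, "cwb_params"), t_end > 0, dt > 0)
  if (dt > params$coop$tau_m / 5 && params$p > 0)
    warning("dt exceeds tau_m / 5 of the cooperative gate; ",
            "the fast gate may be under-resolved")
  n_steps <- as.integer(round(t_end / dt))
  if (is.function(stimulus)) {
    i_input <- stimulus((seq_len(n_steps) - 0.5) * dt)
  } else if (length(stimulus) == 1L) {
    i_input <- rep(as.numeric(stimulus), n_steps)
  } else {
    if (length(stimulus) != n_steps)
      stop("stimulus vector must have length t_end/dt = ", n_steps,
           call. = FALSE)
    i_input <- as.numeric(stimulus)
  }
  if (identical(state0, "rest")) {
    state0 <- initial_state(params, i_ext = i_input[1])
  }
  stopifnot(is.numeric(state0), length(state0) == 5L)
  res <- .cwb_integrate_cpp(as.numeric(state0[c("v", "h", "n", "m_c", "h_c")]),
                            dt, n_steps, i_input, .cwb_par_list(params))
  if (res$bad_step >= 0)
    stop(sprintf("non-finite state at t = %.4f ms (step %d); reduce dt",
                 res$bad_step * dt, res$bad_step), call. = FALSE)
  structure(list(t = (0:n_steps) * dt, v = res$v, h = res$h, n = res$n,
                 m_c = res$m_c, h_c = res$h_c, i_input = i_input, dt = dt,
                 clip_events = res$clip_events, params = params, seed = seed),
            class = "cwb_trajectory")
}

#' @export
print.cwb_trajectory <- function(x, ...) {
  cat(sprintf("cWB trajectory: %.1f ms at dt = %g ms (%d samples)\n",
              max(x$t), x$dt, length(x$t)))
  cat(sprintf("  V range [%.1f, %.1f] mV; gating clip events: %d\n",
              min(x$v), max(x$v), x$clip_events))
  invisible(x)
}

#' @export
as.data.frame.cwb_trajectory <- function(x, ...) {
  data.frame(t_ms = x$t, v_mV = x$v, h = x$h, n = x$n,
             m_c = x$m_c, h_c = x$h_c,
             i_uA_cm2 = c(x$i_input, x$i_input[length(x$i_input)]))
}

#' Membrane-potential derivative along a trajectory
#'
#' Evaluates \eqn{dV/dt} from the model right-hand side at every stored
#' sample of a trajectory (using the recorded stimulus), rather than by
#' numerical differentiation of the sampled voltage.  This is the
#' noise-free phase-plot ordinate used by the AP metrics.
#'
#' @param traj A \code{cwb_trajectory}.
#' @param params Parameters; defaults to those stored in the trajectory.
#' @return Numeric vector of \eqn{dV/dt} (mV/ms), one value per sample.
#' @export
cwb_vdot <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "cwb_trajectory"))
  v <- traj$v; wb <- params$wb; cg <- params$coop
  r <- .wb_rates(v)
  minf <- r$am / (r$am + r$bm)
  mcq <- traj$m_c^cg$q
  i_na <- wb$g_na * ((1 - params$p) * minf^params$q_noncoop * traj$h +
                       params$p * mcq * traj$h_c) * (v - wb$e_na)
  i_k <- wb$g_k * traj$n^4 * (v - wb$e_k)
  i_l <- wb$g_l * (v - wb$e_l)
  n_in <- length(traj$i_input)
  i_ext <- c(traj$i_input, traj$i_input[n_in])
  (-i_na - i_k - i_l + i_ext) / wb$c_m
}

#' Detect spike times in a voltage trace
#'
#' Times of upward crossings of a voltage criterion, linearly interpolated
#' between samples, with a refractory constraint that discards crossings
#' closer than \code{refractory} to the previous accepted spike.
#'
#' @param traj A \code{cwb_trajectory} (or any list with \code{t} and
#'   \code{v} vectors).
#' @param v_cross Crossing voltage (mV), default 0.
#' @param refractory Minimum spike separation (ms), default 2.
#' @return Numeric vector of spike times (ms); empty if none.
#' @export
detect_spikes <- function(traj, v_cross = 0, refractory = 2) {
  v <- traj$v; tt <- traj$t
  i <- which(v[-length(v)] < v_cross & v[-1] >= v_cross)
  if (!length(i)) return(numeric(0))
  frac <- (v_cross - v[i]) / (v[i + 1] - v[i])
  times <- tt[i] + frac * (tt[i + 1] - tt[i])
  keep <- logical(length(times))
  last <- -Inf
  for (j in seq_along(times)) {
    if (times[j] - last >= refractory) { keep[j] <- TRUE; last <- times[j] }
  }
  times[keep]
}

#' Steady-state f-I curve
#'
#' Firing rate as a function of constant input current, from direct
#' simulation with an initial transient discarded.
#'
#' @param params A [cwb_params()] object.
#' @param i_grid Increasing vector of current densities (uA/cm2).
#' @param t_end Simulation length per current level (ms).
#' @param dt Integration step (ms).
#' @param transient Initial interval discarded before counting (ms).
#' @return Data frame with columns \code{i_uA_cm2} and \code{rate_Hz}.
#' @export
fi_curve <- function(params, i_grid, t_end = 1000, dt = 0.01,
                     transient = 200) {
  stopifnot(all(diff(i_grid) > 0) || length(i_grid) == 1L)
  rate <- vapply(i_grid, function(i0) {
    traj <- integrate_cwb(params, i0, t_end, dt)
    sp <- detect_spikes(traj)
    sp <- sp[sp > transient]
    1000 * length(sp) / (t_end - transient)
  }, numeric(1))
  data.frame(i_uA_cm2 = i_grid, rate_Hz = rate)
}
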