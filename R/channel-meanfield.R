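#' Single-channel steady-state activation (Boltzmann)
#'
#' Steady-state open probability of the activation gate of an isolated
#' channel, \eqn{m_\infty(V) = 1/(1 + \exp(-(V - V_{1/2})/k))}.
#'
#' @param v Membrane voltage (mV); vectorised.
#' @param params A [coop_gate_params()] object.
#' @return Gate open probability in (0, 1), strictly increasing in \code{v}.
#' @export
steady_gate <- function(v, params) {
  stopifnot(inherits(params, "coop_gate_params"))
  stats::plogis((v - params$v_half) / params$k)
}

#' Self-consistency map of the coupled channel population
#'
#' In the mean field of a population where each channel sees \code{K}
#' neighbours, a fraction \code{a} of channels is available (not
#' inactivated) and each open neighbour shifts the activation curve by
#' \code{J} mV, the activation variable at clamped voltage \code{v} must
#' satisfy \eqn{m = F(m)} with
#' \deqn{F(m) = m_\infty(v + \mu a m^q), \qquad \mu = K J.}
#' \code{a m^q} is the expected open fraction among the neighbours of an
#' available channel.  \code{F} is a continuous, non-decreasing self-map of
#' \eqn{[0,1]}; with \eqn{\mu = 0} it is constant and the population reduces
#' to independent channels.
#'
#' @param m Activation variable in [0, 1]; vectorised.
#' @param v Clamped voltage (mV).
#' @param a Available (non-inactivated) channel fraction in [0, 1].
#' @param params A [coop_gate_params()] object.
#' @return \code{F(m)}, a probability in (0, 1).
#' @export
self_consistency_map <- function(m, v, a, params) {
  stopifnot(inherits(params, "coop_gate_params"),
            all(m >= 0 & m <= 1), a >= 0, a <= 1)
  steady_gate(v + coop_mu(params) * a * m^params$q, params)
}

# analytic slope F'(m) of the self-consistency map
.map_slope <- function(m, v, a, params) {
  mu <- coop_mu(params)
  q <- params$q
  s <- steady_gate(v + mu * a * m^q, params)
  s * (1 - s) / params$k * mu * a * q * m^pmax(q - 1, 0)
}

#' Fixed points of the self-consistency map
#'
#' Finds all solutions of \eqn{F(m) = m} in \eqn{[0,1]} at a clamped
#' voltage: the steady states of the coupled population.  Because \code{F}
#' is a monotone sigmoidal self-map there are between one and three roots;
#' with three, the outer two are stable (map slope < 1) and the middle one
#' unstable.  Roots are located by a dense sign-change scan refined by
#' bisection; grid minima of \eqn{|F(m)-m|} are additionally polished so
#' that tangent (double) roots at a saddle-node are not missed.
#'
#' @param v Clamped voltage (mV).
#' @param a Available channel fraction in (0, 1].
#' @param params A [coop_gate_params()] object.
#' @param n_scan Number of scan points on [0, 1] (default 1e4).
#' @param tol Residual tolerance \eqn{|F(m)-m|} for accepted roots.
#' @return A list of class \code{fixed_point_set} with elements
#'   \code{voltage}, \code{roots} (increasing), \code{stability} (logical,
#'   per root).
#' @export
fixed_points <- function(v, a, params, n_scan = 1e4, tol = 1e-10) {
  stopifnot(inherits(params, "coop_gate_params"))
  g <- function(m) self_consistency_map(m, v, a, params) - m
  mg <- seq(0, 1, length.out = n_scan)
  gv <- g(mg)
  roots <- numeric(0)

  sgn <- sign(gv)
  # exact zeros on the grid
  hit <- which(gv == 0)
  roots <- c(roots, mg[hit])
  # sign changes -> bisection
  ch <- which(sgn[-1] * sgn[-n_scan] < 0)
  for (i in ch) {
    lo <- mg[i]; hi <- mg[i + 1]
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (abs(g(mid)) < tol) break
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  # interior |g| minima: candidate tangent roots without a sign change
  agv <- abs(gv)
  loc_min <- which(diff(sign(diff(agv))) > 0) + 1L
  for (i in loc_min) {
    if (agv[i] > 1e-4) next
    if (length(roots) && min(abs(roots - mg[i])) < 2 / n_scan) next
    opt <- stats::optimize(function(m) abs(g(m)),
                           lower = mg[max(i - 2L, 1L)],
                           upper = mg[min(i + 2L, n_scan)], tol = 1e-14)
    if (opt$objective < tol) roots <- c(roots, opt$minimum)
  }

  roots <- sort(unique(roots))
  # merge near-duplicates
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-7)
    roots <- roots[keep]
  }
  stability <- .map_slope(roots, v, a, params) < 1
  structure(list(voltage = v, roots = roots, stability = stability),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("Fixed points at V = %g mV:\n", x$voltage))
  for (i in seq_along(x$roots))
    cat(sprintf("  m* = %.8f (%s)\n", x$roots[i],
                if (x$stability[i]) "stable" else "unstable"))
  invisible(x)
}

# voltage at which m is a fixed point: v(m) = v_half + k logit(m) - mu a m^q
.fp_voltage <- function(m, a, params) {
  params$v_half + params$k * stats::qlogis(m) - coop_mu(params) * a * m^params$q
}

# derivative dv/dm of the fixed-point voltage curve
.fp_voltage_slope <- function(m, a, params) {
  params$k / (m * (1 - m)) -
    coop_mu(params) * a * params$q * m^pmax(params$q - 1, 0)
}

#' Critical coupling strength for all-or-none activation
#'
#' The smallest effective coupling \eqn{\mu = K J} at which the
#' self-consistency map acquires three fixed points at some voltage, i.e.
#' at which the collective activation curve develops a discontinuity.  For
#' the Boltzmann gate with exponent \eqn{q = 1} the tangency condition
#' \eqn{m(1-m) = k/(\mu a)} has solutions in (0, 1) iff \eqn{\mu a \ge 4k},
#' giving the closed form \eqn{\mu_c = 4k/a}.  For \eqn{q \ne 1} the onset
#' is located numerically by bisection on \eqn{\mu}, testing at each
#' \eqn{\mu} whether the fixed-point voltage curve
#' \eqn{v(m) = V_{1/2} + k\,\mathrm{logit}(m) - \mu a m^q} is non-monotone
#' on a dense grid (non-monotonicity is equivalent to the existence of a
#' voltage with three fixed points).
#'
#' @param a Available channel fraction, must be positive.
#' @param params A [coop_gate_params()] object.
#' @param rel_tol Relative tolerance of the numerical bisection.
#' @return The critical effective coupling \eqn{\mu_c} in mV.
#' @export
critical_coupling <- function(a, params, rel_tol = 1e-4) {
  stopifnot(inherits(params, "coop_gate_params"))
  if (a <= 0)
    stop("`a` must be positive: with no available channels coupling has no effect",
         call. = FALSE)
  if (params$q == 1L) return(4 * params$k / a)

  has_three <- function(mu) {
    prm <- set_coop_mu(params, mu)
    m <- seq(1e-6, 1 - 1e-6, length.out = 4e4)
    any(diff(.fp_voltage(m, a, prm)) < 0)
  }
  lo <- params$k / a          # far below any possible onset
  hi <- 8 * params$k / a * (params$q + 1)
  while (!has_three(hi)) hi <- hi * 2
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (has_three(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# location m_sn of the saddle-node terminating the lower stable branch:
# the smaller stationary point of v(m) (its local maximum)
.saddle_node_m <- function(mu, a, params) {
  k <- params$k; q <- params$q
  if (q == 1L) {
    disc <- 1 - 4 * k / (mu * a)
    if (disc < 0) return(NA_real_)
    return((1 - sqrt(disc)) / 2)
  }
  prm <- set_coop_mu(params, mu)
  m <- seq(1e-8, 1 - 1e-8, length.out = 4e4)
  sl <- .fp_voltage_slope(m, a, prm)
  ch <- which(sl[-1] * sl[-length(sl)] < 0)
  if (!length(ch)) return(NA_real_)
  i <- ch[1]  # first + -> - crossing: local maximum of v(m)
  stats::uniroot(function(mm) .fp_voltage_slope(mm, a, prm),
                 lower = m[i], upper = m[i + 1], tol = 1e-14)$root
}

#' Voltage threshold of the collective activation discontinuity
#'
#' Above the critical coupling the lower stable branch of the collective
#' activation curve terminates in a saddle-node bifurcation; \code{threshold_voltage}
#' returns the clamped voltage \eqn{V^*} at which this happens — the
#' location of the jump seen when voltage steps of increasing amplitude are
#' applied from rest.  For \eqn{q = 1}:
#' \deqn{m_{sn} = \frac{1 - \sqrt{1 - 4k/(\mu a)}}{2}, \quad
#'   V^* = V_{1/2} + k \ln\frac{m_{sn}}{1 - m_{sn}} - \mu a\, m_{sn};}
#' for general \eqn{q} the tangency system is solved numerically.
#'
#' @param mu Effective coupling (mV); overrides the \code{K * J} of
#'   \code{params}.
#' @param a Available channel fraction in (0, 1].
#' @param params A [coop_gate_params()] object.
#' @return The jump voltage \eqn{V^*} in mV.
#' @export
threshold_voltage <- function(mu, a, params) {
  # a may slightly exceed 1 here so that the log-derivative in
  # threshold_sensitivity() can straddle a = 1
  stopifnot(inherits(params, "coop_gate_params"), a > 0)
  m_sn <- .saddle_node_m(mu, a, params)
  if (is.na(m_sn))
    stop("no discontinuity below critical coupling (mu * a too small)",
         call. = FALSE)
  prm <- set_coop_mu(params, mu)
  .fp_voltage(m_sn, a, prm)
}

#' Sensitivity of the jump threshold to channel availability
#'
#' Central finite difference of [threshold_voltage()] with respect to
#' \eqn{\ln a}: how far the activation discontinuity (and hence the spike
#' threshold it imposes) moves when the available channel fraction changes
#' by a relative amount.  In the strong-coupling limit
#' \eqn{V^* \approx \mathrm{const} - k \ln(\mu a)}, so the sensitivity
#' approaches \eqn{-k} independently of the coupling strength: coupling
#' does not suppress inactivation-driven threshold variability.
#'
#' @inheritParams threshold_voltage
#' @param h Step in \eqn{\ln a} for the central difference.
#' @return \eqn{dV^*/d\ln a} in mV.
#' @export
threshold_sensitivity <- function(mu, a, params, h = 1e-4) {
  (threshold_voltage(mu, a * exp(h), params) -
     threshold_voltage(mu, a * exp(-h), params)) / (2 * h)
}

# steady state reached from m0 by the relaxation dynamics at clamped v:
# iterate the monotone map F; converges to the stable fixed point on the
# branch containing m0
.relax_to_steady <- function(m0, v, a, params, tol = 1e-13, max_iter = 100000L) {
  m <- m0
  for (i in seq_len(max_iter)) {
    m_new <- self_consistency_map(m, v, a, params)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Collective activation curve of a coupled channel population
#'
#' Steady-state open fraction \eqn{s(V) = a\, m^{*q}} of the coupled
#' population as a function of clamped voltage, following the voltage-clamp
#' protocol of steps of increasing amplitude applied from the same holding
#' state: at each grid voltage the steady state is obtained by relaxing
#' from the steady state of the previous grid point.  Above the critical
#' coupling the forward (ascending-voltage) branch jumps discontinuously at
#' the saddle-node voltage; the backward (descending) branch jumps at a
#' lower voltage, producing hysteresis between the two.
#'
#' @param params A [coop_gate_params()] object.
#' @param a Available channel fraction in (0, 1].
#' @param v_grid Strictly increasing voltage grid (mV).
#' @param direction \code{"forward"} (ascending continuation, the
#'   physiological protocol) or \code{"backward"}.
#' @param jump_tol Open-fraction difference between adjacent grid points
#'   that counts as a discontinuity (default 0.2).
#' @param v_refine Voltage resolution to which a detected jump location is
#'   refined by bisection (default 0.01 mV).
#' @return An object of class \code{activation_curve}: list with
#'   \code{v_grid}, \code{open_fraction}, \code{branch},
#'   \code{discontinuous}, and when discontinuous \code{v_threshold} and
#'   \code{jump_size}.
#' @export
collective_activation_curve <- function(params, a, v_grid,
                                        direction = c("forward", "backward"),
                                        jump_tol = 0.2, v_refine = 0.01) {
  stopifnot(inherits(params, "coop_gate_params"))
  if (a <= 0 || a > 1) stop("`a` must be in (0, 1]", call. = FALSE)
  if (length(v_grid) < 2 || any(diff(v_grid) <= 0))
    stop("`v_grid` must be strictly increasing", call. = FALSE)
  direction <- match.arg(direction)

  vs <- if (direction == "forward") v_grid else rev(v_grid)
  m <- if (direction == "forward") 0 else 1
  m_star <- numeric(length(vs))
  for (i in seq_along(vs)) {
    m <- .relax_to_steady(m, vs[i], a, params)
    m_star[i] <- m
  }
  s <- a * m_star^params$q
  if (direction == "backward") { s <- rev(s); m_star <- rev(m_star) }

  d <- diff(s)
  jumps <- which(abs(d) > jump_tol)
  discontinuous <- length(jumps) > 0
  v_threshold <- NA_real_
  jump_size <- NA_real_
  if (discontinuous) {
    j <- if (direction == "forward") jumps[1] else jumps[length(jumps)]
    jump_size <- abs(d[j])
    # bisect on voltage between the bracketing grid points, relaxing from
    # the pre-jump branch state
    if (direction == "forward") {
      lo <- v_grid[j]; hi <- v_grid[j + 1]; m_from <- m_star[j]
    } else {
      lo <- v_grid[j]; hi <- v_grid[j + 1]; m_from <- m_star[j + 1]
    }
    s_lo <- s[j]; s_hi <- s[j + 1]
    s_mid <- (s_lo + s_hi) / 2
    while (hi - lo > v_refine) {
      vm <- (lo + hi) / 2
      sm <- a * .relax_to_steady(m_from, vm, a, params)^params$q
      on_low_branch <- if (direction == "forward") sm < s_mid else sm > s_mid
      if (on_low_branch) {
        if (direction == "forward") lo <- vm else hi <- vm
      } else {
        if (direction == "forward") hi <- vm else lo <- vm
      }
    }
    v_threshold <- (lo + hi) / 2
  }
  structure(list(v_grid = v_grid, open_fraction = s, branch = direction,
                 discontinuous = discontinuous, v_threshold = v_threshold,
                 jump_size = jump_size, a = a, params = params),
            class = "activation_curve")
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("Collective activation curve (%s branch, a = %g, mu = %g mV)\n",
              x$branch, x$a, coop_mu(x$params)))
  if (x$discontinuous)
    cat(sprintf("  discontinuous: jump of %.3f at V* = %.2f mV\n",
                x$jump_size, x$v_threshold))
  else cat("  continuous\n")
  invisible(x)
}

#' @export
as.data.frame.activation_curve <- function(x, ...) {
  data.frame(voltage_mV = x$v_grid, open_fraction = x$open_fraction,
             branch = x$branch)
}

#' Voltage-clamp step responses of the coupled population
#'
#' Integrates the activation kinetics
#' \eqn{\tau_m\, dm/dt = m_\infty(v(t) + \mu a m^q) - m} for a family of
#' voltage steps from a common holding potential, mimicking a voltage-clamp
#' experiment.  The initial condition is the steady state at the holding
#' potential (lower branch).  Returns the open fraction
#' \eqn{s(t) = a\,m(t)^q} for each step.
#'
#' @param v_hold Holding potential (mV).
#' @param v_steps Vector of step potentials (mV).
#' @param a Available channel fraction in (0, 1].
#' @param params A [coop_gate_params()] object.
#' @param dt Integration step (ms); must satisfy \code{dt <= tau_m / 10}.
#' @param t_step Duration of each voltage step (ms).
#' @return An object of class \code{gate_step_family}: list with \code{t}
#'   (ms), \code{open_fraction} (matrix, one column per step),
#'   \code{v_steps}, \code{v_hold}.
#' @export
simulate_gate_step <- function(v_hold, v_steps, a, params,
                               dt = params$tau_m / 20, t_step = 20 * params$tau_m) {
  stopifnot(inherits(params, "coop_gate_params"), length(v_steps) >= 1)
  if (a <= 0 || a > 1) stop("`a` must be in (0, 1]", call. = FALSE)
  if (dt > params$tau_m / 10)
    stop("`dt` must not exceed tau_m / 10", call. = FALSE)
  m0 <- .relax_to_steady(0, v_hold, a, params)
  n <- floor(t_step / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  out <- matrix(NA_real_, n, length(v_steps))
  f <- function(m, v) (self_consistency_map(m, v, a, params) - m) / params$tau_m
  for (j in seq_along(v_steps)) {
    v <- v_steps[j]
    m <- m0
    out[1, j] <- m
    for (i in 2:n) {
      k1 <- f(m, v)
      k2 <- f(min(max(m + dt / 2 * k1, 0), 1), v)
      k3 <- f(min(max(m + dt / 2 * k2, 0), 1), v)
      k4 <- f(min(max(m + dt * k3, 0), 1), v)
      m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      m <- min(max(m, 0), 1)
      out[i, j] <- m
    }
  }
  structure(list(t = tt, open_fraction = a * out^params$q,
                 v_steps = v_steps, v_hold = v_hold, a = a, params = params),
            class = "gate_step_family")
}

#' @export
as.data.frame.gate_step_family <- function(x, ...) {
  data.frame(
    time_ms = rep(x$t, times = length(x$v_steps)),
    v_step_mV = rep(x$v_steps, each = length(x$t)),
    open_fraction = as.vector(x$open_fraction)
  )
}
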