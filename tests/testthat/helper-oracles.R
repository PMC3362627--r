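# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals.

# --- independently coded plain Wang-Buzsaki simulator (R, fixed-step RK4) ---
# Rates written from the published model equations; structured differently
# from the package implementation on purpose.
wb_oracle_rates <- function(v) {
  am <- if (abs(v + 35) < 1e-9) 1 else 0.1 * (v + 35) / (1 - exp(-(v + 35) / 10))
  bm <- 4 * exp(-(v + 60) / 18)
  ah <- 0.07 * exp(-(v + 58) / 20)
  bh <- 1 / (1 + exp(-(v + 28) / 10))
  an <- if (abs(v + 34) < 1e-9) 0.1 else 0.01 * (v + 34) / (1 - exp(-(v + 34) / 10))
  bn <- 0.125 * exp(-(v + 44) / 80)
  c(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

wb_oracle_deriv <- function(y, i_ext, phi = 5) {
  v <- y[1]; h <- y[2]; n <- y[3]
  r <- wb_oracle_rates(v)
  minf <- r["am"] / (r["am"] + r["bm"])
  ina <- 35 * minf^3 * h * (v - 55)
  ik <- 9 * n^4 * (v + 90)
  il <- 0.1 * (v + 65)
  unname(c(-ina - ik - il + i_ext,
           phi * (r["ah"] * (1 - h) - r["bh"] * h),
           phi * (r["an"] * (1 - n) - r["bn"] * n)))
}

# returns matrix with columns t, v
wb_oracle_simulate <- function(i_ext, t_end, dt, v0 = NULL) {
  if (is.null(v0)) {
    # quiescent point of the oracle by damped iteration on the I-V relation
    f <- function(v) {
      r <- wb_oracle_rates(v)
      y <- c(v, r["ah"] / (r["ah"] + r["bh"]), r["an"] / (r["an"] + r["bn"]))
      wb_oracle_deriv(y, 0)[1]
    }
    lo <- -80; hi <- -50
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    v0 <- (lo + hi) / 2
  }
  r <- wb_oracle_rates(v0)
  y <- c(v0, r["ah"] / (r["ah"] + r["bh"]), r["an"] / (r["an"] + r["bn"]))
  names(y) <- NULL
  n_steps <- round(t_end / dt)
  out_v <- numeric(n_steps + 1)
  out_v[1] <- y[1]
  for (i in seq_len(n_steps)) {
    k1 <- wb_oracle_deriv(y, i_ext)
    k2 <- wb_oracle_deriv(y + dt / 2 * k1, i_ext)
    k3 <- wb_oracle_deriv(y + dt / 2 * k2, i_ext)
    k4 <- wb_oracle_deriv(y + dt * k3, i_ext)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out_v[i + 1] <- y[1]
  }
  cbind(t = (0:n_steps) * dt, v = out_v)
}

# --- brute-force fixed-point counter for the self-consistency map ---
# counts roots of F(m) - m by sign changes on a dense grid
oracle_count_roots <- function(v, a, params, n = 40001) {
  m <- seq(0, 1, length.out = n)
  g <- self_consistency_map(m, v, a, params) - m
  sum(g[-1] * g[-n] < 0) + sum(g == 0)
}

# numerical detection of the onset of bistability: the smallest mu at which
# the voltage-of-fixed-point curve v(m) = v_half + k logit(m) - mu a m^q is
# non-monotone (equivalently, some voltage has three fixed points)
oracle_critical_mu <- function(a, params, rel_tol = 1e-6) {
  vm_decreasing <- function(mu) {
    m <- seq(1e-6, 1 - 1e-6, length.out = 2e5)
    v <- params$v_half + params$k * log(m / (1 - m)) - mu * a * m^params$q
    any(diff(v) < 0)
  }
  lo <- 1e-3; hi <- 1
  while (!vm_decreasing(hi)) hi <- hi * 2
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (vm_decreasing(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# standard cooperative test cell: small fraction of strongly coupled
# channels (used by several files)
coop_cell <- function(p = 0.1, mu = 240, ...) {
  prm <- cwb_params(p = p, ...)
  prm$coop <- set_coop_mu(prm$coop, mu)
  prm
}
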