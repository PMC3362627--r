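cg <- coop_gate_params()  # v_half = -30, k = 6, q = 1, tau_m = 0.1

test_that("single-channel Boltzmann activation has the right shape and values", {
  expect_equal(steady_gate(cg$v_half, cg), 0.5)
  expect_equal(steady_gate(cg$v_half + 20 * cg$k, cg), 1, tolerance = 1e-8)
  expect_equal(steady_gate(cg$v_half + cg$k, cg), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  v <- seq(-90, 30, by = 0.5)
  m <- steady_gate(v, cg)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 1))
})

test_that("self-consistency map reduces to the independent case and is monotone", {
  m <- seq(0, 1, by = 0.05)
  # decoupled limit: F(m) constant at m_inf(v)
  expect_equal(self_consistency_map(m, -40, 1, set_coop_mu(cg, 0)),
               rep(steady_gate(-40, cg), length(m)))
  # no open neighbours
  cg48 <- set_coop_mu(cg, 48)
  expect_equal(self_consistency_map(0, -40, 1, cg48), steady_gate(-40, cg))
  # frozen example: q = 1, k = 6, a = 1, mu = 48, v = v_half
  expect_equal(self_consistency_map(0.5, cg$v_half, 1, cg48),
               stats::plogis(4), tolerance = 1e-9)  # 0.982014
  # non-decreasing in m, stays inside (0, 1)
  Fm <- self_consistency_map(m, -45, 0.8, cg48)
  expect_true(all(diff(Fm) >= 0))
  expect_true(all(Fm > 0 & Fm < 1))
})

test_that("fixed points: count, ordering, stability across the bistable window", {
  # decoupled: unique stable root at m_inf
  fp0 <- fixed_points(-40, 1, set_coop_mu(cg, 0))
  expect_length(fp0$roots, 1)
  expect_true(fp0$stability)
  expect_equal(fp0$roots, steady_gate(-40, cg), tolerance = 1e-9)
  # tangency: mu a = 4k at the symmetric voltage gives a root at exactly 1/2
  fp_t <- fixed_points(cg$v_half - 12, 1, set_coop_mu(cg, 24))
  expect_true(any(abs(fp_t$roots - 0.5) < 1e-6))
  # strong coupling inside the window: 3 roots, outer stable, middle unstable
  fp3 <- fixed_points(-54, 1, set_coop_mu(cg, 48))
  expect_length(fp3$roots, 3)
  expect_true(all(diff(fp3$roots) > 0))
  expect_equal(fp3$stability, c(TRUE, FALSE, TRUE))
  # root count agrees with the brute-force scan over the window and beyond
  for (v in c(-70, -60, -54, -50, -44, -30)) {
    fp <- fixed_points(v, 1, set_coop_mu(cg, 48))
    expect_equal(length(fp$roots), oracle_count_roots(v, 1, set_coop_mu(cg, 48)),
                 info = paste("v =", v))
  }
})

test_that("critical coupling matches the closed form and the numeric oracle", {
  expect_equal(critical_coupling(1, cg), 24)
  expect_equal(critical_coupling(1, coop_gate_params(k = 3)), 12)
  expect_equal(critical_coupling(0.5, cg), 48)
  # numeric onset-of-bistability detection agrees with 4k/a
  expect_equal(oracle_critical_mu(1, cg), 24, tolerance = 1e-4)
  expect_equal(oracle_critical_mu(0.5, cg), 48, tolerance = 1e-4)
  # delayed activation (q = 3): numeric bisection against the independent
  # closed form mu_c = k (q+1)^(q+1) / (a q^(q+1))
  cg3 <- coop_gate_params(k = 6, q = 3)
  expect_equal(critical_coupling(1, cg3), 6 * 4^4 / 3^4, tolerance = 5e-4)
  expect_equal(critical_coupling(0.8, cg3), 6 * 4^4 / 3^4 / 0.8, tolerance = 5e-4)
  expect_error(critical_coupling(0, cg), "available")
})

test_that("jump threshold: closed form, ordering in mu, sub-critical error", {
  expect_equal(threshold_voltage(24, 1, cg), cg$v_half - 12)
  expect_equal(threshold_voltage(48, 1, cg), -47.60592, tolerance = 1e-5)
  v30 <- threshold_voltage(30, 1, cg)
  v36 <- threshold_voltage(36, 1, cg)
  v48 <- threshold_voltage(48, 1, cg)
  expect_true(v48 < v36 && v36 < v30)
  expect_error(threshold_voltage(20, 1, cg), "critical")
  # general q route against the q = 1 closed form evaluated the same way
  cg3 <- coop_gate_params(q = 3)
  vt <- threshold_voltage(120, 1, cg3)
  expect_true(is.finite(vt) && vt < cg$v_half)
})

test_that("threshold sensitivity approaches -k and is coupling-independent", {
  s20 <- threshold_sensitivity(20 * 24, 1, cg)
  s40 <- threshold_sensitivity(40 * 24, 1, cg)
  expect_equal(s20, -cg$k, tolerance = 0.05)
  expect_lt(abs(s20 - s40) / abs(s20), 0.02)
  # integrated sensitivity: shift between a = 0.9 and a = 1 equals -k ln(0.9)
  dv <- threshold_voltage(480, 0.9, cg) - threshold_voltage(480, 1, cg)
  expect_equal(dv, -cg$k * log(0.9), tolerance = 0.05 * abs(cg$k * log(0.9)))
})

test_that("collective activation curve: continuity below, a single jump above", {
  vg <- seq(-70, 0, by = 0.1)
  # independent channels: exactly a * m_inf^q
  cur0 <- collective_activation_curve(set_coop_mu(cg, 0), 1, vg)
  expect_false(cur0$discontinuous)
  expect_equal(cur0$open_fraction, steady_gate(vg, cg), tolerance = 1e-8)
  # sub-critical: continuous, strictly increasing
  cur_sub <- collective_activation_curve(set_coop_mu(cg, 0.9 * 24), 1, vg)
  expect_false(cur_sub$discontinuous)
  expect_true(all(diff(cur_sub$open_fraction) > 0))
  # super-critical forward branch: one jump at the tangency voltage
  cur_sup <- collective_activation_curve(set_coop_mu(cg, 1.5 * 24), 1, vg)
  expect_true(cur_sup$discontinuous)
  expect_gt(cur_sup$jump_size, 0.5)
  expect_equal(cur_sup$v_threshold, threshold_voltage(36, 1, cg),
               tolerance = 0.05)
  expect_equal(sum(abs(diff(cur_sup$open_fraction)) > 0.2), 1)
  # segments on either side of the jump are non-decreasing
  j <- which.max(abs(diff(cur_sup$open_fraction)))
  expect_true(all(diff(cur_sup$open_fraction[1:j]) >= 0))
  expect_true(all(diff(cur_sup$open_fraction[(j + 1):length(vg)]) >= -1e-12))
  expect_error(collective_activation_curve(cg, 1, c(-50, -50.1)), "increasing")
})

test_that("forward and backward branches show hysteresis only inside the window", {
  vg <- seq(-70, 0, by = 0.1)
  cg36 <- set_coop_mu(cg, 36)
  fwd <- collective_activation_curve(cg36, 1, vg)
  bwd <- collective_activation_curve(cg36, 1, vg, direction = "backward")
  expect_true(bwd$discontinuous)
  expect_lt(bwd$v_threshold, fwd$v_threshold)  # hysteresis loop orientation
  inside <- vg > bwd$v_threshold + 0.2 & vg < fwd$v_threshold - 0.2
  outside <- vg < bwd$v_threshold - 0.2 | vg > fwd$v_threshold + 0.2
  expect_true(all(abs(fwd$open_fraction[outside] - bwd$open_fraction[outside]) < 1e-6))
  # inside the window the backward (upper) branch exceeds the forward (lower)
  expect_gt(max(bwd$open_fraction[inside] - fwd$open_fraction[inside]), 0.5)
})

test_that("voltage-clamp step responses relax correctly", {
  # decoupled relaxation is mono-exponential with time constant tau_m
  st <- simulate_gate_step(-70, -40, 1, set_coop_mu(cg, 0),
                           dt = 0.005, t_step = 2)
  s <- st$open_fraction[, 1]
  m_inf <- steady_gate(-40, cg)
  sel <- s < 0.99 * m_inf & s > 0
  fit <- stats::lm(log(m_inf - s[sel]) ~ st$t[sel])
  expect_equal(-1 / unname(stats::coef(fit)[2]), cg$tau_m, tolerance = 0.01)
  # terminal value equals the stable fixed point (steps clear of the
  # saddle-node ghost, where relaxation is not critically slowed)
  cg36 <- set_coop_mu(cg, 36)
  for (v in c(-60, -40, -20)) {
    st2 <- simulate_gate_step(-70, v, 1, cg36, dt = 0.005, t_step = 4)
    fp <- fixed_points(v, 1, cg36)
    s_end <- st2$open_fraction[nrow(st2$open_fraction), 1]
    expect_equal(s_end, min(fp$roots[fp$stability])^cg36$q * 1,
                 tolerance = 1e-6, info = paste("v =", v))
  }
  # just above critical coupling a (small) discontinuity already separates
  # the step responses on either side of the threshold voltage
  mu <- 1.05 * 24
  vt <- threshold_voltage(mu, 1, cg)
  stc <- simulate_gate_step(-70, c(vt - 1, vt + 1), 1, set_coop_mu(cg, mu),
                            dt = 0.005, t_step = 15)
  s_end_c <- stc$open_fraction[nrow(stc$open_fraction), ]
  expect_gt(s_end_c[2] - s_end_c[1], 0.2)
  # well above critical the response is an all-or-none event
  mu <- 3 * 24
  vt <- threshold_voltage(mu, 1, cg)
  st3 <- simulate_gate_step(-70, c(vt - 1, vt + 1), 1, set_coop_mu(cg, mu),
                            dt = 0.005, t_step = 15)
  s_end <- st3$open_fraction[nrow(st3$open_fraction), ]
  expect_lt(s_end[1], 0.1)
  expect_gt(s_end[2], 0.9)
  # open fraction stays in [0, 1] throughout
  expect_true(all(st3$open_fraction >= 0 & st3$open_fraction <= 1))
  expect_error(simulate_gate_step(-70, -40, 1, cg, dt = cg$tau_m), "tau_m")
})

test_that("curves and step families export to tidy data frames", {
  vg <- seq(-60, -20, by = 1)
  df <- as.data.frame(collective_activation_curve(set_coop_mu(cg, 0), 1, vg))
  expect_named(df, c("voltage_mV", "open_fraction", "branch"))
  expect_equal(nrow(df), length(vg))
  st <- simulate_gate_step(-70, c(-50, -40), 1, set_coop_mu(cg, 0),
                           dt = 0.01, t_step = 1)
  dfs <- as.data.frame(st)
  expect_named(dfs, c("time_ms", "v_step_mV", "open_fraction"))
  expect_equal(nrow(dfs), 2 * length(st$t))
})
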