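# Phase-plane metrics validated on closed-form fixtures first, then on
# simulated action potentials.

test_that("linear phase-plot fixture gives exact threshold and rapidness", {
  for (cc in c(2, 4, 8)) {
    seg <- make_fixtures("linear_phase_segment", list(c = cc, v0 = -60))
    for (crit in c(5, 10, 20)) {
      expect_equal(ap_threshold(seg, crit), -60 + crit / cc, tolerance = 1e-3)
      expect_equal(onset_rapidness(seg, crit), cc, tolerance = 1e-6)
    }
  }
  seg <- make_fixtures("linear_phase_segment", list(c = 4))
  expect_error(ap_threshold(seg, 10 * max(seg$vdot)), "peak")
})

test_that("upstroke fixtures classify as mono/biphasic by acceleration count", {
  mono <- make_fixtures("logistic_upstroke")
  cl <- classify_waveform(mono, criterion_vdot = 10)
  expect_equal(cl$zero_crossings, 1L)
  expect_equal(cl$waveform_class, "monophasic")
  bi <- make_fixtures("double_logistic_upstroke")
  cl2 <- classify_waveform(bi, criterion_vdot = 10)
  expect_equal(cl2$zero_crossings, 3L)
  expect_equal(cl2$waveform_class, "biphasic")
  # crossing counts are odd on valid upstrokes
  expect_true(cl$zero_crossings %% 2 == 1 && cl2$zero_crossings %% 2 == 1)
})

test_that("segment extraction yields one consistent segment per spike", {
  prm <- cwb_params()
  traj <- integrate_cwb(prm, 1, 400, 0.01)
  sp <- detect_spikes(traj)
  sp_ok <- sp[sp > 100 & sp < 390]
  segs <- extract_spike_segments(traj, sp_ok)
  expect_length(segs, length(sp_ok))
  expect_length(extract_spike_segments(traj, numeric(0)), 0)
  # RHS-based vdot agrees with finite differences of the sampled voltage
  seg <- segs[[2]]
  fd <- c(NA, diff(seg$v, lag = 2) / (2 * seg$dt), NA)
  ok <- is.finite(fd)
  expect_lt(max(abs(seg$vdot[ok] - fd[ok])), 0.01 * max(seg$vdot))
  # windows that would out-run the trajectory are skipped
  segs_edge <- extract_spike_segments(traj, sp, pre_ms = 150)
  expect_lt(length(segs_edge), length(sp))
})

test_that("per-spike thresholds on a deterministic train are identical", {
  prm <- coop_cell(0.1, 144)
  # fine dt so grid-phase interpolation error sits below the tolerance
  traj <- integrate_cwb(prm, 1, 600, 0.005)
  sp <- detect_spikes(traj)
  segs <- extract_spike_segments(traj, sp[sp > 350])  # settled limit cycle
  th <- vapply(segs, ap_threshold, numeric(1))
  expect_gt(length(th), 3)
  expect_lt(max(th) - min(th), 1e-3)
})

test_that("onset metrics are stable under dt refinement", {
  prm <- coop_cell(0.1, 144)
  get_metrics <- function(dt) {
    traj <- integrate_cwb(prm, 1, 300, dt)
    sp <- detect_spikes(traj)
    segs <- extract_spike_segments(traj, sp[sp > 100])
    ap_metrics(segs[[length(segs)]])
  }
  m1 <- get_metrics(0.01)
  m2 <- get_metrics(0.005)
  expect_equal(m1$rapidness_per_ms, m2$rapidness_per_ms, tolerance = 0.1)
  expect_equal(m1$threshold_mV, m2$threshold_mV, tolerance = 0.05)
  expect_equal(m1$zero_crossings, m2$zero_crossings)
})

test_that("onset rapidness increases with coupling strength at fixed p", {
  rap <- vapply(c(0, 1.5, 4) * 60, function(mu) {
    prm <- coop_cell(0.1, mu)
    traj <- integrate_cwb(prm, 1, 300, 0.01)
    sp <- detect_spikes(traj)
    segs <- extract_spike_segments(traj, sp[sp > 100])
    onset_rapidness(segs[[length(segs)]])
  }, numeric(1))
  expect_true(rap[1] < rap[2] && rap[2] < rap[3])
})

test_that("threshold variability requires spikes and is seed-deterministic", {
  prm <- coop_cell(0.1, 60)
  ou <- ou_params(20, 1)
  eta <- ou_noise(ou, 0.01, 4000, seed = 5)
  traj <- integrate_cwb(prm, 0.5 + eta, 4000, 0.01)
  tv1 <- threshold_variability(traj, min_spikes = 50)
  expect_gt(tv1$n_spikes, 50)
  expect_gt(tv1$sd_threshold, 0)
  # identical seed, identical result
  traj2 <- integrate_cwb(prm, 0.5 + ou_noise(ou, 0.01, 4000, seed = 5),
                         4000, 0.01)
  expect_identical(threshold_variability(traj2, min_spikes = 50)$sd_threshold,
                   tv1$sd_threshold)
  # deterministic constant-current train has (near) zero variability
  traj3 <- integrate_cwb(prm, 1, 1500, 0.01)
  tv3 <- threshold_variability(traj3, min_spikes = 40)
  expect_lt(tv3$sd_threshold, 1e-3)
  expect_error(threshold_variability(traj3, min_spikes = 1e4), "spikes")
})

test_that("the (p, mu) sweep runs, checkpoints, and p is inert without coupling", {
  # with matched kinetics, no coupling and a near-instantaneous gate the
  # split is physically inert, so the mu = 0 column must not depend on p
  # (the WB channel activates instantaneously, so exact inertness is the
  # tau_m -> 0 limit; onset metrics are insensitive to the residual lag)
  base <- cwb_params(coop = coop_gate_params(q = 3, tau_m = 0.005, K = 6, J = 0),
                     kappa = 0, coop_kinetics = "wb")
  tab0 <- sweep_pJ(c(0.1, 0.9), 0, base_params = base, t_end = 250, dt = 0.001)
  expect_equal(tab0$rapidness_per_ms[1], tab0$rapidness_per_ms[2],
               tolerance = 0.02)
  expect_equal(tab0$threshold_mV[1], tab0$threshold_mV[2], tolerance = 0.005)
  # checkpoint resume reproduces the completed table without recomputation
  ck <- tempfile(fileext = ".csv")
  tab1 <- sweep_pJ(c(0.05, 0.1), c(60, 240), checkpoint = ck, t_end = 250)
  expect_true(file.exists(ck))
  tab2 <- sweep_pJ(c(0.05, 0.1), c(60, 240), checkpoint = ck, t_end = 250)
  expect_equal(tab1$rapidness_per_ms, tab2$rapidness_per_ms)
  expect_equal(nrow(tab1), 4)
  unlink(ck)
})

test_that("biphasic waveforms are confined to the small-fraction, strong-coupling corner", {
  tab <- sweep_pJ(p_grid = c(0.05, 0.2, 0.5), mu_grid = c(0, 144, 288),
                  i_amp = 1, t_end = 250, dt = 0.005)
  bi <- tab$waveform_class == "biphasic"
  expect_true(any(bi))
  expect_true(all(tab$p[bi] <= 0.05))
  expect_true(all(tab$mu[bi] >= 144))
})
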