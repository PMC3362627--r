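#' Ornstein-Uhlenbeck noise parameters
#'
#' Stationary Gaussian noise with exponential autocorrelation, used to
#' mimic background synaptic input current.
#'
#' @param tau_c Correlation time constant (ms), positive.
#' @param sigma Stationary standard deviation (uA/cm2), non-negative.
#' @return An object of class \code{ou_params}.
#' @export
ou_params <- function(tau_c = 20, sigma = 0.3) {
  if (!is.numeric(tau_c) || tau_c <= 0)
    stop("`tau_c` must be positive", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative", call. = FALSE)
  structure(list(tau_c = tau_c, sigma = sigma), class = "ou_params")
}

#' Sample an Ornstein-Uhlenbeck process
#'
#' Exact discretization of the stationary OU process:
#' \deqn{\eta_{t+dt} = \eta_t e^{-dt/\tau_c}
#'   + \sigma\sqrt{1 - e^{-2 dt/\tau_c}}\, z,}
#' with \eqn{z} standard normal and \eqn{\eta_0 \sim N(0, \sigma^2)}.  The
#' update is exact for any step size, so the sampled process has the
#' stationary variance \eqn{\sigma^2} and autocorrelation
#' \eqn{e^{-\Delta t/\tau_c}} at all lags.
#'
#' @param ou An [ou_params()] object.
#' @param dt Sample step (ms); must be below \code{tau_c}.
#' @param t_end Duration (ms).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Numeric vector of length \code{round(t_end/dt)} (uA/cm2).
#' @export
ou_noise <- function(ou, dt, t_end, seed) {
  stopifnot(inherits(ou, "ou_params"))
  if (dt >= ou$tau_c)
    stop("`dt` must be smaller than the correlation time tau_c", call. = FALSE)
  n <- as.integer(round(t_end / dt))
  if (ou$sigma == 0) return(numeric(n))
  rho <- exp(-dt / ou$tau_c)
  s_innov <- ou$sigma * sqrt(1 - rho^2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- stats::rnorm(n)
  eta <- numeric(n)
  eta[1] <- ou$sigma * z[1]
  for (i in 2:n) eta[i] <- eta[i - 1] * rho + s_innov * z[i]
  eta
}

#' Calibrate the baseline current to a target mean firing rate
#'
#' Bisection on the constant current \code{i0} such that the mean firing
#' rate under OU background noise matches a target.  The rate at each
#' candidate \code{i0} is estimated by averaging over independent noise
#' seeds.
#'
#' @param params A [cwb_params()] object.
#' @param target_rate Target mean rate (Hz).
#' @param ou An [ou_params()] object for the background noise.
#' @param tol Acceptable rate error (Hz).
#' @param t_sim Simulated time per seed (ms), transient excluded on top.
#' @param seeds Integer vector of noise seeds used at every candidate
#'   \code{i0} (common random numbers keep the bracket monotone).
#' @param i_range Initial current bracket (uA/cm2).
#' @param dt Integration step (ms).
#' @param transient Discarded initial interval (ms).
#' @return List with \code{i0}, the achieved \code{rate}, and the number of
#'   bisection iterations.
#' @export
calibrate_baseline <- function(params, target_rate, ou, tol = 0.25,
                               t_sim = 4000, seeds = 1:2,
                               i_range = c(-2, 4), dt = 0.01,
                               transient = 200) {
  est_rate <- function(i0) {
    n_sp <- 0
    for (s in seeds) {
      eta <- ou_noise(ou, dt, t_sim, seed = s)
      rest <- initial_state(params, i_ext = min(i0, 0.1))
      traj <- integrate_cwb(params, i0 + eta, t_sim, dt, state0 = rest)
      sp <- detect_spikes(traj)
      n_sp <- n_sp + sum(sp > transient)
    }
    1000 * n_sp / (length(seeds) * (t_sim - transient))
  }
  lo <- i_range[1]; hi <- i_range[2]
  r_lo <- est_rate(lo); r_hi <- est_rate(hi)
  if (r_lo > target_rate || r_hi < target_rate)
    stop(sprintf(
      "target rate %.2f Hz not bracketed: observed %.2f Hz at i0 = %g and %.2f Hz at i0 = %g",
      target_rate, r_lo, lo, r_hi, hi), call. = FALSE)
  iter <- 0L; rate <- NA_real_
  while (iter < 30L) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    rate <- est_rate(mid)
    if (abs(rate - target_rate) <= tol) { lo <- hi <- mid; break }
    if (rate < target_rate) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  list(i0 = (lo + hi) / 2, rate = rate, iterations = iter)
}

#' Firing-rate modulation at one stimulus frequency
#'
#' Simulates a population of statistically independent neurons (one OU
#' realisation per trial) driven by
#' \eqn{I(t) = i_0 + i_1 \sin(2\pi f t) + \eta(t)}, pools the spike times,
#' and extracts the amplitude and phase of the firing-rate modulation at
#' the stimulus frequency by Fourier projection:
#' \deqn{\nu_1 e^{i\varphi} = \frac{2}{T}\sum_j e^{-2\pi i f t_j},}
#' equivalent to the fundamental of the cycle-averaged histogram but free
#' of binning bias.  The standard error of \eqn{\nu_1} is obtained by
#' bootstrap over trials.
#'
#' @param params A [cwb_params()] object.
#' @param i0 Baseline current (uA/cm2), typically from
#'   [calibrate_baseline()].
#' @param i1 Signal amplitude (uA/cm2).
#' @param f Signal frequency (Hz).
#' @param ou An [ou_params()] object.
#' @param n_trials Number of independent trials (population size).
#' @param t_trial Trial length (ms), transient included.
#' @param seed Base seed; per-trial noise seeds are derived from it.
#' @param dt Integration step (ms).
#' @param transient Discarded initial interval per trial (ms).
#' @param n_boot Bootstrap resamples for the standard error.
#' @return List with \code{nu1} (Hz), \code{phase} (radians), \code{se_nu1}
#'   (Hz), \code{nu0} (Hz, pooled mean rate), \code{n_spikes}.
#' @export
rate_modulation <- function(params, i0, i1, f, ou, n_trials = 20,
                            t_trial = 2200, seed = 1, dt = 0.01,
                            transient = 200, n_boot = 200) {
  stopifnot(f >= 0, i1 >= 0)
  if (f > 0 && f * (t_trial - transient) < 10 * 1000)
    warning("fewer than 10 signal cycles per trial at f = ", f, " Hz")
  rest <- initial_state(params, i_ext = min(i0, 0.1))
  t_eff <- (t_trial - transient) / 1000     # s
  trial_spikes <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    eta <- ou_noise(ou, dt, t_trial, seed = expand_seed(seed, tr))
    tt <- (seq_along(eta) - 0.5) * dt
    stim <- i0 + i1 * sin(2 * pi * f * tt / 1000) + eta
    traj <- integrate_cwb(params, stim, t_trial, dt, state0 = rest)
    sp <- detect_spikes(traj)
    trial_spikes[[tr]] <- sp[sp > transient]
  }
  if (sum(lengths(trial_spikes)) == 0)
    stop("no spikes emitted; raise i0 or sigma", call. = FALSE)
  spike_modulation(trial_spikes, f, t_eff, n_boot = n_boot,
                   seed = expand_seed(seed, 0L))
}

#' Firing-rate modulation from pooled spike trains
#'
#' Fourier projection of a set of spike-time trains onto a stimulus
#' frequency: \eqn{\nu_1 e^{i\varphi} = (2/T)\sum_j e^{-2\pi i f t_j}}
#' with \eqn{T} the total observation time.  The standard error of
#' \eqn{\nu_1} is estimated by bootstrap over trains.  Spike times must be
#' measured from the start of the (common) stimulus cycle of each train.
#'
#' @param trains List of numeric vectors of spike times (ms).
#' @param f Stimulus frequency (Hz).
#' @param t_eff Observation time per train (s).
#' @param n_boot Bootstrap resamples (0 skips the standard error).
#' @param seed Seed for the bootstrap resampling.
#' @return List with \code{nu1}, \code{phase}, \code{se_nu1}, \code{nu0},
#'   \code{n_spikes}.
#' @export
spike_modulation <- function(trains, f, t_eff, n_boot = 200, seed = 1) {
  stopifnot(is.list(trains), t_eff > 0)
  n_trials <- length(trains)
  proj <- function(idx) {
    ts <- unlist(trains[idx]) / 1000  # s
    2 * sum(exp(-2i * pi * f * ts)) / (length(idx) * t_eff)
  }
  z_all <- proj(seq_len(n_trials))
  se <- NA_real_
  if (n_trials > 1 && n_boot > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      Mod(proj(sample.int(n_trials, replace = TRUE)))
    }, numeric(1))
    se <- stats::sd(boots)
  }
  list(nu1 = Mod(z_all), phase = Arg(z_all), se_nu1 = se,
       nu0 = sum(lengths(trains)) / (n_trials * t_eff),
       n_spikes = sum(lengths(trains)))
}

#' Population frequency-response curve
#'
#' Firing-rate modulation \eqn{\nu_1(f)} across a list of stimulus
#' frequencies at a fixed baseline, signal amplitude and background noise:
#' the frequency response function of the model population.  Frequencies
#' whose measurement fails are reported as gaps.
#'
#' @param params A [cwb_params()] object.
#' @param f_list Stimulus frequencies (Hz).
#' @param i0 Baseline current; when \code{NULL} it is calibrated to
#'   \code{target_rate} first.
#' @param i1 Signal amplitude (uA/cm2).
#' @param ou An [ou_params()] object.
#' @param target_rate Target mean rate (Hz) for calibration when \code{i0}
#'   is missing.
#' @param seed Base seed.
#' @param ... Further arguments passed to [rate_modulation()].
#' @return An object of class \code{frequency_response}: data frame with
#'   columns \code{f_Hz}, \code{nu0_Hz}, \code{nu1_Hz}, \code{phase_rad},
#'   \code{se_Hz}, \code{n_spikes}; the baseline current is attached as
#'   attribute \code{i0}.
#' @export
frequency_response_curve <- function(params, f_list, i0 = NULL, i1 = 0.2,
                                     ou = ou_params(), target_rate = 5,
                                     seed = 1, ...) {
  stopifnot(length(f_list) >= 1)
  if (is.null(i0)) {
    i0 <- calibrate_baseline(params, target_rate, ou,
                             seeds = expand_seed(seed, 9001:9004))$i0
  }
  rows <- lapply(seq_along(f_list), function(i) {
    f <- f_list[i]
    res <- tryCatch(
      rate_modulation(params, i0, i1, f, ou,
                      seed = expand_seed(seed, 100L + i), ...),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(f_Hz = f, nu0_Hz = NA_real_, nu1_Hz = NA_real_,
                        phase_rad = NA_real_, se_Hz = NA_real_,
                        n_spikes = NA_integer_))
    data.frame(f_Hz = f, nu0_Hz = res$nu0, nu1_Hz = res$nu1,
               phase_rad = res$phase, se_Hz = res$se_nu1,
               n_spikes = res$n_spikes)
  })
  out <- do.call(rbind, rows)
  attr(out, "i0") <- i0
  class(out) <- c("frequency_response", class(out))
  out
}
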