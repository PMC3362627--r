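# Synthetic test fixtures with known analytic properties: idealized AP
# upstrokes for the phase-plane metrics and inhomogeneous Poisson spike
# trains for the rate-modulation estimator.

#' Generate a synthetic fixture
#'
#' Produces objects with analytically known properties, used to validate
#' the analysis operations independently of the neuron simulator:
#' \describe{
#'   \item{\code{"logistic_upstroke"}}{A single logistic voltage rise
#'     (one acceleration phase; monophasic, one second-derivative zero
#'     crossing).  Params: \code{v0}, \code{amp}, \code{t_mid}, \code{width},
#'     \code{t_end}, \code{dt}.}
#'   \item{\code{"double_logistic_upstroke"}}{Sum of a fast and a slower,
#'     later logistic rise (two acceleration phases; biphasic, three zero
#'     crossings).  Params: \code{v0}, \code{amp1}, \code{t_mid1},
#'     \code{width1}, \code{amp2}, \code{t_mid2}, \code{width2},
#'     \code{t_end}, \code{dt}.}
#'   \item{\code{"linear_phase_segment"}}{Exponential voltage rise, so the
#'     phase plot is exactly the line \code{vdot = c (v - v0)}: threshold
#'     at criterion \code{cr} is \code{v0 + cr/c} and onset rapidness is
#'     \code{c}.  Params: \code{v0}, \code{c}, \code{v_start_offset},
#'     \code{t_end}, \code{dt}.}
#'   \item{\code{"poisson_train"}}{Spike times of an inhomogeneous Poisson
#'     process with rate \eqn{\nu_0 + \nu_1 \sin(2\pi f t)} (thinning
#'     algorithm).  Params: \code{nu0}, \code{nu1}, \code{f}, \code{t_end}
#'     (ms), and for pooled-population fixtures \code{n_trials}.}
#' }
#' Upstroke fixtures are returned as \code{spike_segment} objects with the
#' analytic \eqn{dV/dt}; the Poisson fixture as a list of per-trial spike
#' time vectors (ms).
#'
#' @param kind Fixture kind (see Details).
#' @param params Named list of fixture parameters; missing entries take
#'   the defaults documented above.
#' @param seed Integer seed (used by the stochastic fixtures).
#' @return A \code{spike_segment} or a list of spike-time vectors.
#' @export
make_fixtures <- function(kind, params = list(), seed = 1) {
  p <- params
  g <- function(name, default) p[[name]] %||% default
  logistic <- function(t, t_mid, width) stats::plogis((t - t_mid) / width)

  if (kind == "logistic_upstroke") {
    dt <- g("dt", 0.005); t_end <- g("t_end", 4)
    v0 <- g("v0", -65); amp <- g("amp", 90)
    t_mid <- g("t_mid", 2); width <- g("width", 0.15)
    tt <- seq(0, t_end, by = dt)
    s <- logistic(tt, t_mid, width)
    structure(list(t = tt, v = v0 + amp * s,
                   vdot = amp / width * s * (1 - s), dt = dt, t_spike = t_mid),
              class = "spike_segment")

  } else if (kind == "double_logistic_upstroke") {
    dt <- g("dt", 0.005); t_end <- g("t_end", 6)
    v0 <- g("v0", -65)
    a1 <- g("amp1", 25); t1 <- g("t_mid1", 2);   w1 <- g("width1", 0.08)
    a2 <- g("amp2", 70); t2 <- g("t_mid2", 3.2); w2 <- g("width2", 0.35)
    tt <- seq(0, t_end, by = dt)
    s1 <- logistic(tt, t1, w1); s2 <- logistic(tt, t2, w2)
    structure(list(t = tt, v = v0 + a1 * s1 + a2 * s2,
                   vdot = a1 / w1 * s1 * (1 - s1) + a2 / w2 * s2 * (1 - s2),
                   dt = dt, t_spike = t1),
              class = "spike_segment")

  } else if (kind == "linear_phase_segment") {
    dt <- g("dt", 0.002); t_end <- g("t_end", 3)
    v0 <- g("v0", -60); cc <- g("c", 4); off <- g("v_start_offset", 0.5)
    tt <- seq(0, t_end, by = dt)
    v <- v0 + off * exp(cc * tt)
    structure(list(t = tt, v = v, vdot = cc * (v - v0), dt = dt,
                   t_spike = t_end),
              class = "spike_segment")

  } else if (kind == "poisson_train") {
    nu0 <- g("nu0", 5); nu1 <- g("nu1", 2); f <- g("f", 10)
    t_end <- g("t_end", 10000); n_trials <- g("n_trials", 1)
    if (nu1 > nu0) stop("need nu1 <= nu0 for a non-negative rate",
                        call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    lapply(seq_len(n_trials), function(tr) {
      set.seed(expand_seed(seed, tr))
      rate_max <- (nu0 + nu1) / 1000      # spikes per ms
      n_cand <- stats::rpois(1, rate_max * t_end)
      tc <- sort(stats::runif(n_cand, 0, t_end))
      lam <- (nu0 + nu1 * sin(2 * pi * f * tc / 1000)) / 1000
      tc[stats::runif(n_cand) < lam / rate_max]
    })

  } else {
    stop("unknown fixture kind: ", kind, call. = FALSE)
  }
}
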