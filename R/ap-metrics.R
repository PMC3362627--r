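#' Extract single-spike segments from a trajectory
#'
#' Cuts one window per detected spike, carrying the voltage trace and the
#' phase-plot ordinate \eqn{dV/dt} evaluated from the model right-hand side
#' along the stored states (see [cwb_vdot()]); windows that would extend
#' beyond the trajectory are skipped.
#'
#' @param traj A \code{cwb_trajectory}.
#' @param spikes Spike times (ms), e.g. from [detect_spikes()].
#' @param pre_ms,post_ms Window extent before/after each spike time (ms).
#' @param vdot Optional precomputed \eqn{dV/dt} vector for the whole
#'   trajectory; computed from the model RHS when missing.  Supply a
#'   finite-difference estimate here to analyse externally recorded traces.
#' @return List of \code{spike_segment} objects, each with \code{t},
#'   \code{v}, \code{vdot} and \code{dt}.
#' @export
extract_spike_segments <- function(traj, spikes, pre_ms = 5, post_ms = 3,
                                   vdot = NULL) {
  stopifnot(pre_ms > 0, post_ms >= 0)
  if (!length(spikes)) return(list())
  if (is.null(vdot)) vdot <- cwb_vdot(traj)
  dt <- traj$dt
  n <- length(traj$t)
  out <- list()
  for (ts in spikes) {
    i0 <- floor((ts - pre_ms) / dt) + 1L
    i1 <- ceiling((ts + post_ms) / dt) + 1L
    if (i0 < 1L || i1 > n) next
    idx <- i0:i1
    out[[length(out) + 1L]] <- structure(
      list(t = traj$t[idx], v = traj$v[idx], vdot = vdot[idx], dt = dt,
           t_spike = ts),
      class = "spike_segment")
  }
  out
}

# index of the voltage peak within a segment
.seg_peak <- function(seg) which.max(seg$v)

# first upward crossing of vdot = criterion before the voltage peak;
# returns list(i = index before crossing, frac = interpolation fraction)
.criterion_crossing <- function(seg, criterion_vdot) {
  ip <- .seg_peak(seg)
  vd <- seg$vdot[1:ip]
  i <- which(vd[-length(vd)] < criterion_vdot & vd[-1] >= criterion_vdot)
  if (!length(i)) return(NULL)
  i <- i[1]
  list(i = i, frac = (criterion_vdot - vd[i]) / (vd[i + 1] - vd[i]))
}

#' Spike threshold from the phase plot
#'
#' Voltage at which \eqn{dV/dt} first crosses a fixed criterion on the
#' upstroke (linear interpolation between samples).
#'
#' @param seg A \code{spike_segment}.
#' @param criterion_vdot Phase-plot criterion (mV/ms), default 10.
#' @return Threshold voltage (mV).
#' @export
ap_threshold <- function(seg, criterion_vdot = 10) {
  stopifnot(inherits(seg, "spike_segment"))
  if (criterion_vdot >= max(seg$vdot))
    stop("criterion_vdot (", criterion_vdot,
         ") is not below the peak dV/dt (", signif(max(seg$vdot), 4), ")",
         call. = FALSE)
  cr <- .criterion_crossing(seg, criterion_vdot)
  if (is.null(cr))
    stop("dV/dt never crosses the criterion on the upstroke", call. = FALSE)
  seg$v[cr$i] + cr$frac * (seg$v[cr$i + 1] - seg$v[cr$i])
}

#' AP onset rapidness
#'
#' Slope of the phase plot (\eqn{dV/dt} against \eqn{V}) at the criterion
#' crossing, estimated by a least-squares line over the upstroke arc whose
#' \eqn{dV/dt} lies within \code{criterion_vdot +/- fit_halfwidth}.  Fast,
#' cooperativity-driven AP onsets show up as a large phase slope.
#'
#' @inheritParams ap_threshold
#' @param fit_halfwidth Half-width of the \eqn{dV/dt} fit window (mV/ms);
#'   default \code{criterion_vdot / 2}.
#' @return Onset rapidness (1/ms).
#' @export
onset_rapidness <- function(seg, criterion_vdot = 10,
                            fit_halfwidth = criterion_vdot / 2) {
  stopifnot(inherits(seg, "spike_segment"))
  cr <- .criterion_crossing(seg, criterion_vdot)
  if (is.null(cr))
    stop("dV/dt never crosses the criterion on the upstroke", call. = FALSE)
  ip <- .seg_peak(seg)
  # contiguous upstroke arc around the crossing, within the vdot window
  lo <- criterion_vdot - fit_halfwidth; hi <- criterion_vdot + fit_halfwidth
  idx <- seq_len(ip)
  inwin <- idx[seg$vdot[idx] >= lo & seg$vdot[idx] <= hi & idx <= ip]
  # keep the run containing the crossing (the upstroke passes once)
  if (length(inwin)) {
    runs <- split(inwin, cumsum(c(1, diff(inwin) != 1)))
    containing <- vapply(runs, function(r) cr$i %in% r || (cr$i + 1L) %in% r,
                         logical(1))
    inwin <- if (any(containing)) runs[[which(containing)[1]]]
             else runs[[length(runs)]]
  }
  if (length(inwin) < 5)
    stop("fewer than 5 samples in the phase-plot fit window; ",
         "use a smaller dt or a wider fit_halfwidth", call. = FALSE)
  stats::coef(stats::lm(seg$vdot[inwin] ~ seg$v[inwin]))[[2]]
}

#' Classify an AP upstroke as monophasic or biphasic
#'
#' Counts sign changes of the second time derivative of the membrane
#' potential between the threshold crossing and the voltage peak.  The
#' second derivative is obtained by differentiating the RHS-based
#' \eqn{dV/dt} along the trajectory.  A single acceleration phase gives one
#' zero crossing (monophasic); an upstroke driven first by the cooperative
#' fraction and then by the remaining channels shows two acceleration
#' phases and three zero crossings (biphasic).  Sign changes whose flanking
#' excursions stay below \code{excursion_tol} are ignored as numerical
#' ripple.
#'
#' @inheritParams ap_threshold
#' @param excursion_tol Minimum second-derivative excursion (mV/ms^2) for a
#'   sign lobe to count; default 1\% of the maximum absolute second
#'   derivative in the upstroke window.
#' @return List with \code{waveform_class} (\code{"monophasic"} or
#'   \code{"biphasic"}) and \code{zero_crossings} (integer).
#' @export
classify_waveform <- function(seg, criterion_vdot = 10, excursion_tol = NULL) {
  stopifnot(inherits(seg, "spike_segment"))
  cr <- .criterion_crossing(seg, criterion_vdot)
  if (is.null(cr))
    stop("no threshold crossing in segment", call. = FALSE)
  ip <- .seg_peak(seg)
  # second derivative by central differences of the RHS-based vdot
  vddot <- c(NA, diff(seg$vdot, lag = 2) / (2 * seg$dt), NA)
  win <- (cr$i + 1L):ip
  x <- vddot[win]
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty upstroke window", call. = FALSE)
  if (is.null(excursion_tol)) excursion_tol <- 0.01 * max(abs(x))
  xs <- x[abs(x) >= excursion_tol]
  zc <- if (length(xs) < 2) 0L else sum(diff(sign(xs)) != 0)
  list(waveform_class = if (zc >= 3) "biphasic" else "monophasic",
       zero_crossings = as.integer(zc))
}

#' Full metric set for one spike
#'
#' @inheritParams onset_rapidness
#' @return A one-row data frame with \code{threshold_mV},
#'   \code{rapidness_per_ms}, \code{peak_vdot}, \code{waveform_class},
#'   \code{zero_crossings}.
#' @export
ap_metrics <- function(seg, criterion_vdot = 10,
                       fit_halfwidth = criterion_vdot / 2) {
  cls <- classify_waveform(seg, criterion_vdot)
  data.frame(
    threshold_mV = ap_threshold(seg, criterion_vdot),
    rapidness_per_ms = onset_rapidness(seg, criterion_vdot, fit_halfwidth),
    peak_vdot = max(seg$vdot),
    waveform_class = cls$waveform_class,
    zero_crossings = cls$zero_crossings
  )
}

#' Spike-threshold variability under fluctuating input
#'
#' Standard deviation across spikes of the phase-plot threshold, for a
#' trajectory driven by fluctuating (e.g. Ornstein-Uhlenbeck) current.
#'
#' @param traj A \code{cwb_trajectory} under fluctuating input.
#' @param criterion_vdot Phase-plot threshold criterion (mV/ms).
#' @param min_spikes Minimum number of usable spikes required (default 50).
#' @param transient Initial interval discarded (ms).
#' @param ... Passed to [extract_spike_segments()].
#' @return List with \code{sd_threshold} (mV), \code{mean_threshold} (mV),
#'   \code{n_spikes}, and the per-spike \code{thresholds}.
#' @export
threshold_variability <- function(traj, criterion_vdot = 10, min_spikes = 50,
                                  transient = 200, ...) {
  sp <- detect_spikes(traj)
  sp <- sp[sp > transient]
  segs <- extract_spike_segments(traj, sp, ...)
  th <- vapply(segs, function(s) {
    tryCatch(ap_threshold(s, criterion_vdot), error = function(e) NA_real_)
  }, numeric(1))
  th <- th[is.finite(th)]
  if (length(th) < min_spikes)
    stop("only ", length(th), " usable spikes (need ", min_spikes,
         "); lengthen the simulation", call. = FALSE)
  list(sd_threshold = stats::sd(th), mean_threshold = mean(th),
       n_spikes = length(th), thresholds = th)
}

#' Sweep AP metrics over cooperative fraction and coupling strength
#'
#' Runs a standardized constant-current protocol for every combination of
#' cooperative fraction \code{p} and effective coupling \code{mu}, measures
#' the last AP of the train, and tabulates onset rapidness, peak
#' \eqn{dV/dt} and waveform class.  Cells whose simulation or metric
#' extraction fails are recorded as missing.
#'
#' @param p_grid Cooperative fractions to test.
#' @param mu_grid Effective couplings (mV) to test.
#' @param base_params Template [cwb_params()]; \code{p} and the coupling of
#'   its gate are overridden per cell.
#' @param i_amp Step-current amplitude (uA/cm2).
#' @param t_end,dt Protocol length and integration step (ms).
#' @param criterion_vdot Phase-plot criterion (mV/ms).
#' @param checkpoint Optional path to a CSV checkpoint; finished cells are
#'   appended as the sweep runs and are not recomputed when the sweep is
#'   restarted with the same path.
#' @return Data frame with one row per grid cell: \code{p}, \code{mu},
#'   \code{rapidness_per_ms}, \code{peak_vdot}, \code{threshold_mV},
#'   \code{waveform_class}, \code{zero_crossings}.
#' @export
sweep_pJ <- function(p_grid, mu_grid, base_params = cwb_params(),
                     i_amp = 1, t_end = 300, dt = 0.01,
                     criterion_vdot = 10, checkpoint = NULL) {
  stopifnot(length(p_grid) >= 1, length(mu_grid) >= 1)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
  }
  rows <- list()
  for (p in p_grid) for (mu in mu_grid) {
    if (!is.null(done) &&
        any(abs(done$p - p) < 1e-12 & abs(done$mu - mu) < 1e-9)) {
      rows[[length(rows) + 1L]] <-
        done[abs(done$p - p) < 1e-12 & abs(done$mu - mu) < 1e-9, ][1, ]
      next
    }
    prm <- base_params
    prm$p <- p
    prm$coop <- set_coop_mu(prm$coop, mu)
    row <- tryCatch({
      traj <- integrate_cwb(prm, i_amp, t_end, dt)
      sp <- detect_spikes(traj)
      sp <- sp[sp > 100]           # settle onto the limit cycle
      segs <- extract_spike_segments(traj, sp)
      if (!length(segs)) stop("no analysable spike")
      m <- ap_metrics(segs[[length(segs)]], criterion_vdot)
      cbind(data.frame(p = p, mu = mu), m)
    }, error = function(e) {
      data.frame(p = p, mu = mu, threshold_mV = NA_real_,
                 rapidness_per_ms = NA_real_, peak_vdot = NA_real_,
                 waveform_class = NA_character_, zero_crossings = NA_integer_)
    })
    rows[[length(rows) + 1L]] <- row
    if (!is.null(checkpoint)) {
      utils::write.table(row, checkpoint, sep = ",", row.names = FALSE,
                         col.names = !file.exists(checkpoint), append = file.exists(checkpoint))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
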