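#' Acceleration time history of a vehicle or body region
#'
#' Container for a uniformly sampled acceleration record. Vehicle-frame
#' records carry the three component channels `ax`, `ay`, `az`
#' (longitudinal, transverse, vertical, m/s^2); body-region records (head,
#' chest) may carry only the resultant magnitude channel. A resultant is
#' derived from the components when not supplied.
#'
#' @param time Sample times in seconds; strictly increasing, uniform step.
#' @param ax,ay,az Component accelerations in m/s^2 (vehicle records).
#' @param resultant Resultant acceleration magnitude in m/s^2 (may be the
#'   only channel for head/chest records).
#' @param role One of `"vehicle"`, `"head"`, `"chest"`.
#' @return An object of class `acceleration_trace`: a data frame of the
#'   channels with attributes `role` and `step` (sampling step, s).
#' @examples
#' t <- seq(0, 0.1, by = 1e-3)
#' tr <- acceleration_trace(t, ax = 50 * sin(pi * t / 0.1), ay = 0, az = 0)
#' @export
acceleration_trace <- function(time, ax = NULL, ay = NULL, az = NULL,
                               resultant = NULL,
                               role = c("vehicle", "head", "chest")) {
  role <- match.arg(role)
  time <- as.numeric(time)
  if (length(time) < 2L)
    stop("acceleration trace needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  step <- dt[1L]
  if (any(abs(dt - step) > 1e-6 * step))
    stop("`time` must be uniformly sampled", call. = FALSE)

  n <- length(time)
  recycle <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n)
      stop("channel `", what, "` must match the length of `time`", call. = FALSE)
    if (!all(is.finite(x)))
      stop("channel `", what, "` contains non-finite values", call. = FALSE)
    x
  }
  ax <- recycle(ax, "ax"); ay <- recycle(ay, "ay"); az <- recycle(az, "az")
  resultant <- recycle(resultant, "resultant")

  has_components <- !is.null(ax) && !is.null(ay) && !is.null(az)
  if (!has_components && is.null(resultant))
    stop("supply either the three component channels or a resultant channel",
         call. = FALSE)
  if (is.null(resultant) && has_components)
    resultant <- sqrt(ax^2 + ay^2 + az^2)

  out <- data.frame(time = time)
  if (has_components) { out$ax <- ax; out$ay <- ay; out$az <- az }
  out$resultant <- resultant
  structure(out, class = c("acceleration_trace", "data.frame"),
            role = role, step = step)
}

#' @export
print.acceleration_trace <- function(x, ...) {
  cat(sprintf("<acceleration_trace: %s, %d samples @ %.4g ms, %.3g s>\n",
              attr(x, "role"), nrow(x), attr(x, "step") * 1000,
              x$time[nrow(x)] - x$time[1L]))
  invisible(x)
}

#' Read an acceleration trace from CSV
#'
#' Expects the header `time,ax,ay,az` (vehicle) or `time,resultant`
#' (body region); time in seconds, acceleration in m/s^2.
#'
#' @param path CSV file path.
#' @param role Channel role, see [acceleration_trace()].
#' @return An [acceleration_trace()].
#' @export
read_trace_csv <- function(path, role = c("vehicle", "head", "chest")) {
  role <- match.arg(role)
  d <- utils::read.csv(path)
  if (!"time" %in% names(d))
    stop("trace file must have a `time` column: ", path, call. = FALSE)
  acceleration_trace(d$time,
                     ax = d[["ax"]], ay = d[["ay"]], az = d[["az"]],
                     resultant = d[["resultant"]], role = role)
}

#' Configuration of the occupant injury indices
#'
#' Directional acceleration limits and averaging windows used by the index
#' calculators. Defaults are the values used for restrained occupants:
#' component limits 12/9/10 g (longitudinal/transverse/vertical), a 50-ms
#' ASI averaging window, a 15-ms maximum HIC window, a 3-ms chest window,
#' and g = 9.8 m/s^2.
#'
#' @param asi_limits Length-3 positive vector, component limits in g.
#' @param asi_window ASI moving-average window, seconds.
#' @param hic_window Maximum HIC window length, seconds.
#' @param cra_window Chest averaging window, seconds.
#' @param g_value Standard gravity, m/s^2.
#' @param lowpass_cutoff_hz Optional low-pass cutoff (Hz) applied to the
#'   trace before index evaluation; `NULL` (default) disables filtering.
#' @return A list of class `index_config`.
#' @export
index_config <- function(asi_limits = c(12, 9, 10),
                         asi_window = 0.050,
                         hic_window = 0.015,
                         cra_window = 0.003,
                         g_value = 9.8,
                         lowpass_cutoff_hz = NULL) {
  stopifnot(length(asi_limits) == 3L, all(asi_limits > 0),
            asi_window > 0, hic_window > 0, cra_window > 0, g_value > 0,
            is.null(lowpass_cutoff_hz) || lowpass_cutoff_hz > 0)
  structure(list(asi_limits = asi_limits, asi_window = asi_window,
                 hic_window = hic_window, cra_window = cra_window,
                 g_value = g_value, lowpass_cutoff_hz = lowpass_cutoff_hz),
            class = "index_config")
}

# Window length in samples for a duration `window` at sampling step `step`.
# Windows align to sample boundaries; no fractional-sample interpolation.
window_samples <- function(window, step, n) {
  wn <- as.integer(round(window / step))
  if (wn < 1L)
    stop("window is shorter than the sampling step", call. = FALSE)
  if (wn >= n)
    stop("window is longer than the record", call. = FALSE)
  wn
}

#' Moving average of an acceleration channel
#'
#' Trapezoidal mean of the channel over every window `[t, t + window]`
#' that fits inside the record: value `i` is
#' `1/window * integral of x over [t_i, t_i + window]`.
#'
#' @param x Numeric channel, uniformly sampled.
#' @param step Sampling step, seconds.
#' @param window Averaging window, seconds; must be at least one step and
#'   shorter than the record.
#' @return Numeric vector of length `length(x) - round(window/step)`.
#' @export
moving_average <- function(x, step, window) {
  n <- length(x)
  wn <- window_samples(window, step, n)
  # cumulative trapezoid of x; cum[i] = integral over [t_1, t_i]
  cum <- c(0, cumsum((x[-1L] + x[-n]) / 2)) * step
  idx <- seq_len(n - wn)
  (cum[idx + wn] - cum[idx]) / (wn * step)
}

# Optionally low-pass filter a trace per the config.
maybe_filter <- function(trace, config) {
  if (is.null(config$lowpass_cutoff_hz)) return(trace)
  lowpass_filter(trace, config$lowpass_cutoff_hz)
}

#' Acceleration severity index (ASI)
#'
#' Maximum over time of the root-sum-of-squares of the 50-ms moving
#' averages of the three vehicle acceleration components, each normalised
#' by its occupant tolerance limit (12/9/10 g by default). ASI is
#' dimensionless; values above 1 exceed what a restrained occupant is
#' assumed to tolerate.
#'
#' @param trace A vehicle [acceleration_trace()] with `ax`, `ay`, `az`.
#' @param config An [index_config()].
#' @return ASI value (non-negative scalar).
#' @export
compute_asi <- function(trace, config = index_config()) {
  if (!all(c("ax", "ay", "az") %in% names(trace)))
    stop("ASI requires the three component channels ax, ay, az", call. = FALSE)
  trace <- maybe_filter(trace, config)
  step <- attr(trace, "step")
  lim <- config$asi_limits * config$g_value
  mx <- moving_average(trace$ax, step, config$asi_window) / lim[1L]
  my <- moving_average(trace$ay, step, config$asi_window) / lim[2L]
  mz <- moving_average(trace$az, step, config$asi_window) / lim[3L]
  max(sqrt(mx^2 + my^2 + mz^2))
}

#' Head injury criterion (HIC)
#'
#' Maximises `(t2 - t1) * mean(a)^2.5` over all sample-aligned windows
#' `(t1, t2)` with `0 < t2 - t1 <= hic_window` (15 ms by default), where
#' `mean(a)` is the trapezoidal mean of the head resultant acceleration in
#' g over the window.
#'
#' @param trace A head [acceleration_trace()] with a resultant channel.
#' @param config An [index_config()].
#' @return HIC value (non-negative scalar).
#' @export
compute_hic <- function(trace, config = index_config()) {
  trace <- maybe_filter(trace, config)
  step <- attr(trace, "step")
  a_g <- trace$resultant / config$g_value
  n <- length(a_g)
  wn <- window_samples(config$hic_window, step, n)
  cum <- c(0, cumsum((a_g[-1L] + a_g[-n]) / 2)) * step
  best <- 0
  for (w in seq_len(wn)) {
    idx <- seq_len(n - w)
    dur <- w * step
    m <- (cum[idx + w] - cum[idx]) / dur
    m <- pmax(m, 0)
    best <- max(best, dur * max(m)^2.5)
  }
  best
}

#' Chest resultant acceleration (CRA)
#'
#' Maximum chest resultant acceleration sustained over a 3-ms window,
#' expressed in g: the peak of the 3-ms moving average of the chest
#' resultant channel divided by g. 60 g is the conventional safety limit.
#'
#' @param trace A chest [acceleration_trace()] with a resultant channel.
#' @param config An [index_config()].
#' @return CRA in g (non-negative scalar).
#' @export
compute_cra <- function(trace, config = index_config()) {
  trace <- maybe_filter(trace, config)
  step <- attr(trace, "step")
  m <- moving_average(trace$resultant, step, config$cra_window)
  max(m) / config$g_value
}

#' Zero-phase low-pass filter of a trace
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase), channel by channel. Constant (DC) signals pass unchanged.
#'
#' @param trace An [acceleration_trace()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency of the record.
#' @return A filtered [acceleration_trace()] with the same time base.
#' @export
lowpass_filter <- function(trace, cutoff_hz) {
  step <- attr(trace, "step")
  nyquist <- 1 / (2 * step)
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyquist), call. = FALSE)
  bf <- signal::butter(4, cutoff_hz / nyquist, type = "low")
  out <- trace
  for (ch in setdiff(names(trace), "time")) {
    x <- trace[[ch]]
    # filtfilt is exact for DC; remove the mean first to limit edge transients
    mu <- mean(x)
    out[[ch]] <- as.numeric(signal::filtfilt(bf, x - mu)) + mu
  }
  out
}

#' All applicable injury indices of a trace
#'
#' Convenience dispatcher: vehicle traces yield the ASI, head traces the
#' HIC, chest traces the CRA.
#'
#' @param trace An [acceleration_trace()].
#' @param config An [index_config()].
#' @return Named numeric vector of the applicable indices.
#' @export
compute_indices <- function(trace, config = index_config()) {
  switch(attr(trace, "role"),
         vehicle = c(asi = compute_asi(trace, config)),
         head    = c(hic = compute_hic(trace, config)),
         chest   = c(cra = compute_cra(trace, config)))
}
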