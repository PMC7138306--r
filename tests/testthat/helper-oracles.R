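# Independent oracles and small trace builders used across the tests.

# Trapezoidal integral of y over uniformly spaced samples.
trapz <- function(y, dt) sum((y[-1] + y[-length(y)]) / 2) * dt

# Exhaustive HIC oracle: enumerates every sample-aligned window (t1, t2)
# with 0 < t2 - t1 <= window; for each start t1 the integral is
# accumulated over the admissible end points.
hic_oracle <- function(resultant_ms2, dt, window = 0.015, g = 9.8) {
  a <- resultant_ms2 / g
  n <- length(a)
  wn <- round(window / dt)
  best <- 0
  for (i in seq_len(n - 1)) {
    jmax <- min(n, i + wn)
    seg <- cumsum((a[i:(jmax - 1)] + a[(i + 1):jmax]) / 2 * dt)
    dur <- seq_along(seg) * dt
    best <- max(best, dur * pmax(seg / dur, 0)^2.5)
  }
  best
}

# Windowed-mean oracle: trapezoidal mean of x over [t_i, t_i + window] for
# every full window, via direct slicing.
moving_average_oracle <- function(x, dt, window) {
  wn <- round(window / dt)
  vapply(seq_len(length(x) - wn),
         function(i) trapz(x[i:(i + wn)], dt) / (wn * dt),
         numeric(1))
}

make_half_sine <- function(peak, duration, dt = 1e-4) {
  t <- seq(0, duration, by = dt)
  list(time = t, a = peak * sin(pi * t / duration))
}

# A straight-segment and a curved-segment car case as one-row tables.
case_row <- function(speed, road_type, radius, diameter, spacing,
                     vehicle = "car") {
  data.frame(speed_kmh = speed, road_type = road_type, radius_m = radius,
             diameter_cm = diameter, spacing_m = spacing, vehicle = vehicle,
             stringsAsFactors = FALSE)
}
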