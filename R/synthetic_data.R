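#' Simulation parameter grid
#'
#' The factorial design of the collision simulations: horizontal radius
#' (unbounded = straight segment, then 700 down to 100 m), departure
#' speed 40-100 km/h in steps of 10, tree diameter 10-32 cm in steps of
#' 2, tree spacing 2-7 m, and the two vehicle types.
#'
#' @param radii Horizontal radii in m; `Inf` marks the straight segment.
#' @param speeds Departure speeds, km/h.
#' @param diameters Tree diameters, cm.
#' @param spacings Tree spacings, m.
#' @param vehicles Vehicle types.
#' @return A list of class `parameter_grid`.
#' @export
parameter_grid <- function(radii = c(Inf, 700, 600, 500, 400, 300, 200, 100),
                           speeds = seq(40, 100, by = 10),
                           diameters = seq(10, 32, by = 2),
                           spacings = 2:7,
                           vehicles = c("car", "truck")) {
  stopifnot(all(radii > 0), all(speeds > 0), all(diameters > 0),
            all(spacings > 0),
            all(vehicles %in% c("car", "truck")))
  structure(list(radii = radii, speeds = speeds, diameters = diameters,
                 spacings = spacings, vehicles = vehicles),
            class = "parameter_grid")
}

#' Synthetic crash pulse
#'
#' Generates an idealised longitudinal crash pulse (half-sine or
#' triangular) whose time integral equals the stated speed change, the
#' constraint that ties pulse severity to impact speed. The sampled pulse
#' is rescaled so its trapezoidal integral matches `delta_v` exactly;
#' optional Gaussian noise is added afterwards.
#'
#' @param delta_v_kmh Speed change of the collision, km/h (> 0).
#' @param duration_ms Pulse duration, ms (> 0).
#' @param shape `"half_sine"` or `"triangular"`.
#' @param noise_sd Standard deviation of additive Gaussian noise, m/s^2.
#' @param seed Optional integer seed (same seed, same trace).
#' @param dt Sampling step, seconds.
#' @param role Channel role of the returned trace.
#' @return An [acceleration_trace()] with the pulse on `ax` (vehicle role)
#'   or on the resultant channel (head/chest roles).
#' @export
generate_pulse <- function(delta_v_kmh, duration_ms,
                           shape = c("half_sine", "triangular"),
                           noise_sd = 0, seed = NULL, dt = 1e-4,
                           role = c("vehicle", "head", "chest")) {
  shape <- match.arg(shape)
  role <- match.arg(role)
  if (!is.finite(delta_v_kmh) || delta_v_kmh <= 0)
    stop("`delta_v_kmh` must be positive", call. = FALSE)
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("`duration_ms` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  T <- duration_ms / 1000
  time <- seq(0, T, by = dt)
  u <- time / T
  a <- switch(shape,
              half_sine = sin(pi * u),
              triangular = 1 - abs(2 * u - 1))
  dv <- delta_v_kmh / 3.6  # m/s
  n <- length(a)
  trapz <- sum((a[-1L] + a[-n]) / 2) * dt
  a <- a * dv / trapz
  if (noise_sd > 0) a <- a + stats::rnorm(n, 0, noise_sd)
  if (role == "vehicle") {
    acceleration_trace(time, ax = a, ay = 0, az = 0, role = role)
  } else {
    acceleration_trace(time, resultant = pmax(a, 0), role = role)
  }
}

# Default per-radius subsample: the simulation campaign sizes reconcile as
# 282 records per radius level (282 straight + 7 x 282 = 1974 curved).
.default_n_per_radius <- 282L

#' Synthetic simulation-grid dataset
#'
#' Emulates the collision-simulation campaign: for each sampled design
#' point the CRA (cars only) and ASI responses are drawn as the published
#' model value plus homoscedastic Gaussian noise, with negative draws
#' truncated at zero. By default, noise is calibrated per model so the
#' refit attains the published coefficient of determination:
#' `sigma = sd(mu) * sqrt((1 - R2) / R2)` on the realised design.
#'
#' The default design samples 282 of the 1008 speed x diameter x spacing
#' x vehicle combinations at each radius level, reproducing the campaign
#' totals (282 straight + 1974 curved = 2256 records); `full_grid = TRUE`
#' keeps the complete factorial.
#'
#' @param grid A [parameter_grid()].
#' @param noise_sd Optional named vector of noise SDs per response
#'   (`cra`, `asi`); overrides the R2 calibration.
#' @param target_r2 Named vector of target R2 per model key (defaults to
#'   the published fits; see [published_model()]).
#' @param n_per_radius Design points sampled per radius level.
#' @param full_grid Keep the full factorial instead of subsampling.
#' @param truncate Clip negative response draws at zero (physical injury
#'   indices are non-negative)? Clipped records are flagged in the
#'   `censored` column. Disable for estimator-validation experiments,
#'   where the uncensored linear-Gaussian draws are the relevant model.
#' @param seed Integer seed; the same seed yields the identical dataset.
#' @return Data frame with columns `id`, `speed_kmh`, `road_type`,
#'   `radius_m`, `diameter_cm`, `spacing_m`, `vehicle`, `cra`, `asi`,
#'   `censored`, plus attributes `seed`, `noise_sd` (per model) and
#'   `n_truncated`.
#' @export
generate_simulation_dataset <- function(grid = parameter_grid(),
                                        noise_sd = NULL,
                                        target_r2 = NULL,
                                        n_per_radius = .default_n_per_radius,
                                        full_grid = FALSE,
                                        truncate = TRUE,
                                        seed = 1L) {
  set.seed(seed)
  cells <- expand.grid(speed_kmh = grid$speeds,
                       diameter_cm = grid$diameters,
                       spacing_m = grid$spacings,
                       vehicle = grid$vehicles,
                       stringsAsFactors = FALSE)
  design <- do.call(rbind, lapply(grid$radii, function(r) {
    d <- cells
    if (!full_grid) {
      if (n_per_radius > nrow(cells))
        stop("`n_per_radius` exceeds the ", nrow(cells),
             " combinations per radius level", call. = FALSE)
      d <- cells[sort(sample.int(nrow(cells), n_per_radius)), ]
    }
    d$radius_m <- r
    d
  }))
  design$road_type <- ifelse(is.infinite(design$radius_m), "straight", "curve")
  design$id <- seq_len(nrow(design))
  rownames(design) <- NULL

  if (is.null(target_r2)) target_r2 <- .published_r2
  model_key <- function(resp, veh, rt) paste(resp, veh, rt, sep = "_")
  sigmas <- c()
  censored <- rep(FALSE, nrow(design))
  draw <- function(resp) {
    out <- rep(NA_real_, nrow(design))
    for (rt in c("straight", "curve")) for (veh in grid$vehicles) {
      if (resp == "cra" && veh != "car") next
      sel <- design$road_type == rt & design$vehicle == veh
      if (!any(sel)) next
      key <- model_key(resp, veh, rt)
      mu <- eval_model(published_model(resp, veh, rt),
                       design$speed_kmh[sel], design$diameter_cm[sel],
                       design$spacing_m[sel], design$radius_m[sel])
      sigma <- if (!is.null(noise_sd)) {
        unname(noise_sd[[resp]])
      } else {
        r2 <- target_r2[[key]]
        stats::sd(mu) * sqrt((1 - r2) / r2)
      }
      sigmas[key] <<- sigma
      y <- mu + stats::rnorm(length(mu), 0, sigma)
      if (truncate) {
        clipped <- y < 0
        censored[which(sel)[clipped]] <<- TRUE
        y <- pmax(y, 0)
      }
      out[sel] <- y
    }
    out
  }
  design$cra <- draw("cra")
  design$asi <- draw("asi")
  design$censored <- censored
  design <- design[, c("id", "speed_kmh", "road_type", "radius_m",
                       "diameter_cm", "spacing_m", "vehicle", "cra", "asi",
                       "censored")]
  attr(design, "seed") <- seed
  attr(design, "noise_sd") <- sigmas
  attr(design, "n_truncated") <- sum(censored)
  design
}

#' Synthetic clustered ordered sample
#'
#' Draws Gaussian clusters with known membership and pools them into an
#' [ordered_sample()] — ground truth for segmentation boundary-recovery
#' experiments. Defaults plant three well-separated clusters (means 0, 6,
#' 12; unit SD, a 6-SD gap) of 50 draws each.
#'
#' @param cluster_means Strictly increasing cluster means.
#' @param cluster_sds Cluster standard deviations (>= 0).
#' @param cluster_sizes Cluster sizes (>= 1).
#' @param seed Optional integer seed.
#' @return An [ordered_sample()] whose `labels` are the true cluster
#'   memberships of the sorted values, with attribute `true_starts`: the
#'   rank at which each cluster starts under the planted sizes.
#' @export
generate_segmentable_sample <- function(cluster_means = c(0, 6, 12),
                                        cluster_sds = c(1, 1, 1),
                                        cluster_sizes = c(50, 50, 50),
                                        seed = NULL) {
  k <- length(cluster_means)
  stopifnot(length(cluster_sds) == k, length(cluster_sizes) == k,
            all(cluster_sizes >= 1), all(cluster_sds >= 0))
  if (any(diff(cluster_means) <= 0))
    stop("`cluster_means` must be strictly increasing", call. = FALSE)
  if (any(cluster_sds == 0 & duplicated(cluster_means)))
    stop("degenerate overlapping clusters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  values <- unlist(lapply(seq_len(k), function(h)
    stats::rnorm(cluster_sizes[h], cluster_means[h], cluster_sds[h])))
  labels <- rep(seq_len(k), cluster_sizes)
  s <- ordered_sample(values, labels = labels)
  attr(s, "true_starts") <- c(1L, cumsum(cluster_sizes)[-k] + 1L)
  s
}
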