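# Published occupant-injury regression models.
#
# Six linear models predict injury indices from departure speed V (km/h),
# natural log of tree diameter D (cm), and either tree spacing L (m) on
# straight segments or the ratio L/R (R = horizontal radius, m) on curves.
# CRA models exist for cars only; ASI models for cars and trucks.
.published_models <- list(
  cra_car_straight  = c(speed = 1.417, lnD = 8.100, spacing = -3.288,
                        intercept = -57.099),
  cra_car_curve     = c(speed = 1.382, lnD = 9.854, spacing_over_radius = -513.613,
                        intercept = -63.195),
  asi_car_straight  = c(speed = 0.035, lnD = 0.233, spacing = -0.026,
                        intercept = -1.726),
  asi_truck_straight = c(speed = 0.034, lnD = 0.298, spacing = -0.014,
                         intercept = -1.904),
  asi_car_curve     = c(speed = 0.035, lnD = 0.241, spacing_over_radius = -5.442,
                        intercept = -1.751),
  asi_truck_curve   = c(speed = 0.034, lnD = 0.293, spacing_over_radius = -4.990,
                        intercept = -1.884)
)

# Reported goodness of fit of the published models (coefficient of
# determination of the original simulation-data regressions); used as the
# default noise calibration target by the synthetic-data generator.
.published_r2 <- c(cra_car_straight = 0.925, cra_car_curve = 0.941,
                   asi_car_straight = 0.988, asi_truck_straight = 0.963,
                   asi_car_curve = 0.992, asi_truck_curve = 0.968)

#' Published injury-model coefficients
#'
#' @param response `"cra"` or `"asi"`.
#' @param vehicle `"car"` or `"truck"`.
#' @param road_type `"straight"` or `"curve"`.
#' @return A named numeric vector of class `model_coefficients` with
#'   elements `speed`, `lnD`, `spacing` (straight) or
#'   `spacing_over_radius` (curve), and `intercept`, plus attributes
#'   `response`, `vehicle`, `road_type` and `r2` (reported fit).
#' @export
published_model <- function(response = c("cra", "asi"),
                            vehicle = c("car", "truck"),
                            road_type = c("straight", "curve")) {
  response <- match.arg(response)
  vehicle <- match.arg(vehicle)
  road_type <- match.arg(road_type)
  key <- paste(response, vehicle, road_type, sep = "_")
  coefs <- .published_models[[key]]
  if (is.null(coefs))
    stop("no published ", toupper(response), " model for vehicle type '",
         vehicle, "'", call. = FALSE)
  structure(coefs, class = "model_coefficients", response = response,
            vehicle = vehicle, road_type = road_type,
            r2 = unname(.published_r2[key]))
}

# Evaluate one linear injury model on case columns (vectorised).
eval_model <- function(coefs, speed, diameter, spacing, radius) {
  geom <- if ("spacing" %in% names(coefs)) {
    coefs[["spacing"]] * spacing
  } else {
    coefs[["spacing_over_radius"]] * spacing / radius
  }
  coefs[["speed"]] * speed + coefs[["lnD"]] * log(diameter) + geom +
    coefs[["intercept"]]
}

check_case_cols <- function(cases) {
  need <- c("speed_kmh", "road_type", "diameter_cm", "spacing_m", "vehicle")
  miss <- setdiff(need, names(cases))
  if (length(miss))
    stop("case table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cases$road_type == "curve" &
          (!is.finite(cases$radius_m) | cases$radius_m <= 0)))
    stop("curve cases must carry a finite positive `radius_m`", call. = FALSE)
  invisible(cases)
}

# Dispatch one response over a case table, row-blocked by road type.
predict_index <- function(cases, response, vehicle_override = NULL) {
  check_case_cols(cases)
  out <- rep(NA_real_, nrow(cases))
  for (rt in c("straight", "curve")) {
    sel <- cases$road_type == rt
    if (!any(sel)) next
    veh <- if (is.null(vehicle_override)) cases$vehicle[sel] else
      rep(vehicle_override, sum(sel))
    for (v in unique(veh)) {
      s <- sel
      s[sel] <- veh == v
      coefs <- published_model(response, v, rt)
      out[s] <- eval_model(coefs, cases$speed_kmh[s], cases$diameter_cm[s],
                           cases$spacing_m[s],
                           if (rt == "curve") cases$radius_m[s] else Inf)
    }
  }
  out
}

#' Predict chest resultant acceleration for crash cases
#'
#' Evaluates the published CRA regression for car cases: the
#' straight-segment model uses tree spacing L, the curved-segment model
#' the ratio L/R. The CRA is reported to the nearest integer g
#' (`round = TRUE`, the published convention); the raw model value is
#' available with `round = FALSE`.
#'
#' @param cases Data frame with columns `speed_kmh`, `road_type`
#'   (`"straight"`/`"curve"`), `radius_m` (finite for curves), `diameter_cm`,
#'   `spacing_m`, `vehicle` (must be `"car"`; no published CRA model exists
#'   for trucks).
#' @param round Round to the nearest integer g?
#' @return Numeric vector of CRA values in g.
#' @export
predict_cra <- function(cases, round = TRUE) {
  check_case_cols(cases)
  if (any(cases$vehicle != "car"))
    stop("the published CRA models cover cars only; truck cases are ",
         "unsupported (use `predict_asi()` for trucks)", call. = FALSE)
  raw <- predict_index(cases, "cra")
  if (round) base::round(raw) else raw
}

#' Predict the acceleration severity index for crash cases
#'
#' Evaluates the published ASI regressions, selecting the model by vehicle
#' type and road type. Reported values are rounded to two decimals
#' (`round = TRUE`, the published convention).
#'
#' @inheritParams predict_cra
#' @param round Round to two decimals?
#' @return Numeric vector of ASI values.
#' @export
predict_asi <- function(cases, round = TRUE) {
  raw <- predict_index(cases, "asi")
  if (round) base::round(raw, 2L) else raw
}

#' Predict the mixed-traffic ASI
#'
#' Blends the car and truck ASI models by the truck proportion `w` of the
#' traffic mix: `ASI = (1 - w) ASI_car + w ASI_truck`, evaluated at the
#' same geometry and speed. At `w = 0` this is the car model, at `w = 1`
#' the truck model.
#'
#' @inheritParams predict_cra
#' @param w Truck proportion in `[0, 1]`.
#' @param round Round to two decimals?
#' @return Numeric vector of blended ASI values.
#' @export
predict_asi_mixed <- function(cases, w, round = TRUE) {
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1)
    stop("truck proportion `w` must be a single value in [0, 1]",
         call. = FALSE)
  raw <- (1 - w) * predict_index(cases, "asi", vehicle_override = "car") +
    w * predict_index(cases, "asi", vehicle_override = "truck")
  if (round) base::round(raw, 2L) else raw
}

#' Roadside tree height from trunk diameter
#'
#' Height-diameter allometry `H = 32.7008 * exp(-8.7297 / D)` with H in
#' metres and D the trunk diameter in centimetres; strictly increasing in
#' D and bounded above by 32.7008 m.
#'
#' @param diameter_cm Trunk diameter(s), cm, positive.
#' @return Height(s) in metres.
#' @examples
#' round(tree_height(24)) # 23 m
#' @export
tree_height <- function(diameter_cm) {
  if (any(!is.finite(diameter_cm) & diameter_cm != Inf) ||
      any(diameter_cm <= 0))
    stop("`diameter_cm` must be positive", call. = FALSE)
  32.7008 * exp(-8.7297 / diameter_cm)
}

# Tabulated departure speed (km/h) -> departure angle (degrees) pairs from
# European run-off-road accident statistics.
.departure_angle_table <- data.frame(
  speed_kmh = c(40, 50, 60, 70, 80, 90, 100),
  angle_deg = c(12, 11, 9, 9, 8, 7, 6)
)

#' Departure angle of an errant vehicle
#'
#' Angle (degrees) at which a vehicle leaving the travel lane departs, as
#' a function of its departure speed: exact at the tabulated speeds
#' (40-100 km/h in steps of 10), linearly interpolated between them, and
#' clamped (with a warning) outside the tabulated range.
#'
#' @param speed_kmh Departure speed(s), km/h.
#' @return Departure angle(s) in degrees.
#' @export
departure_angle <- function(speed_kmh) {
  tab <- .departure_angle_table
  if (any(speed_kmh < min(tab$speed_kmh) | speed_kmh > max(tab$speed_kmh)))
    warning("departure speed outside the tabulated range [40, 100] km/h; ",
            "angle clamped to the nearest tabulated value", call. = FALSE)
  stats::approx(tab$speed_kmh, tab$angle_deg, xout = speed_kmh,
                method = "linear", rule = 2)$y
}

#' Refit an injury model on indexed crash data
#'
#' Ordinary least squares fit of an injury index on departure speed,
#' log tree diameter, and tree spacing (straight segments) or the
#' spacing/radius ratio (curved segments) — the functional form of the
#' published models.
#'
#' @param data Data frame of cases with the case columns of
#'   [predict_cra()] plus the response column.
#' @param response Name of the response column (e.g. `"cra"`, `"asi"`).
#' @param road_type `"straight"` or `"curve"`; the fit is restricted to
#'   cases of this road type.
#' @return A list of class `injury_model_fit`: `coefficients` (named as in
#'   [published_model()]), `r_squared`, `sigma` (residual SD),
#'   `std_errors`, `n`, and the underlying `lm` fit.
#' @export
fit_injury_model <- function(data, response, road_type = c("straight", "curve")) {
  road_type <- match.arg(road_type)
  check_case_cols(data)
  if (!response %in% names(data))
    stop("response column `", response, "` not found", call. = FALSE)
  d <- data[data$road_type == road_type & !is.na(data[[response]]), ]
  if (nrow(d) < 10L)
    stop("need at least 10 cases of road type '", road_type, "'", call. = FALSE)
  d$.y <- d[[response]]
  d$.lnD <- log(d$diameter_cm)
  fml <- if (road_type == "straight") {
    d$.geom <- d$spacing_m
    .y ~ speed_kmh + .lnD + .geom
  } else {
    d$.geom <- d$spacing_m / d$radius_m
    .y ~ speed_kmh + .lnD + .geom
  }
  fit <- stats::lm(fml, data = d)
  if (fit$rank < 4L || any(is.na(stats::coef(fit))))
    stop("singular design: predictors are collinear", call. = FALSE)
  sm <- summary(fit)
  geom_name <- if (road_type == "straight") "spacing" else "spacing_over_radius"
  nm <- c("intercept", "speed", "lnD", geom_name)
  coefs <- stats::setNames(stats::coef(fit), nm)
  ses <- stats::setNames(sm$coefficients[, "Std. Error"], nm)
  ord <- c("speed", "lnD", geom_name, "intercept")
  structure(list(coefficients = coefs[ord], std_errors = ses[ord],
                 r_squared = sm$r.squared, sigma = sm$sigma, n = nrow(d),
                 road_type = road_type, response = response, fit = fit),
            class = "injury_model_fit")
}

#' @export
print.injury_model_fit <- function(x, ...) {
  cat(sprintf("Injury model fit: %s ~ V + ln(D) + %s  [%s, n = %d]\n",
              x$response,
              if (x$road_type == "straight") "L" else "L/R",
              x$road_type, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("R^2 = %.3f, residual SD = %.3f\n", x$r_squared, x$sigma))
  invisible(x)
}
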