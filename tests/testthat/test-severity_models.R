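test_that("published CRA model reproduces documented validation cases", {
  # curved segment, case: V=114, R=1260, D=28, L=12
  expect_equal(predict_cra(case_row(114, "curve", 1260, 28, 12)), 122)
  # straight segment, case: V=101, D=40, L=5
  expect_equal(predict_cra(case_row(101, "straight", Inf, 40, 5)), 99)
  # raw (unrounded) value of the curved model at V=60, R=2300, D=11, L=3
  expect_equal(predict_cra(case_row(60, "curve", 2300, 11, 3), round = FALSE),
               42.68, tolerance = 1e-3)
})

test_that("published ASI models reproduce documented validation cases", {
  expect_equal(predict_asi(case_row(95, "curve", 3160, 33, 6)), 2.41)
  expect_equal(predict_asi(case_row(70, "curve", 560, 31, 6, "truck")), 1.45)
  expect_equal(predict_asi(case_row(86, "straight", Inf, 32, 5, "truck")),
               1.98)
})

test_that("CRA prediction rejects trucks and bad geometry", {
  expect_error(predict_cra(case_row(70, "curve", 560, 31, 6, "truck")),
               "cars only")
  expect_error(predict_cra(case_row(70, "curve", NA, 31, 6)),
               "radius_m")
  expect_error(predict_cra(case_row(70, "curve", 560, 31, 6)[, -1]),
               "speed_kmh")
})

test_that("mixed-traffic ASI is the w-blend of the two vehicle models", {
  cs <- case_row(80, "straight", Inf, 25, 5)
  expect_equal(predict_asi_mixed(cs, 0, round = FALSE),
               predict_asi(cs, round = FALSE))
  expect_equal(predict_asi_mixed(cs, 1, round = FALSE),
               predict_asi(case_row(80, "straight", Inf, 25, 5, "truck"),
                           round = FALSE))
  half <- predict_asi_mixed(cs, 0.5, round = FALSE)
  car <- predict_asi(cs, round = FALSE)
  truck <- predict_asi(case_row(80, "straight", Inf, 25, 5, "truck"),
                       round = FALSE)
  expect_equal(half, (car + truck) / 2)
  # affine in w and bracketed by the single-type predictions
  w <- seq(0, 1, 0.25)
  vals <- vapply(w, function(wi) predict_asi_mixed(cs, wi, round = FALSE),
                 numeric(1))
  expect_equal(vals, (1 - w) * car + w * truck)
  expect_true(all(vals >= min(car, truck) & vals <= max(car, truck)))
  expect_error(predict_asi_mixed(cs, 1.2), "\\[0, 1\\]")
})

test_that("tree height allometry is increasing, bounded, and matches field values", {
  expect_equal(round(tree_height(24)), 23)
  expect_equal(round(tree_height(10)), 14)
  d <- seq(5, 80, by = 5)
  expect_true(all(diff(tree_height(d)) > 0))
  expect_lt(tree_height(1e6), 32.7008)
  expect_equal(tree_height(Inf), 32.7008)
  expect_error(tree_height(-3), "positive")
})

test_that("departure angle interpolates the tabulated speeds", {
  expect_equal(departure_angle(40), 12)
  expect_equal(departure_angle(100), 6)
  expect_equal(departure_angle(45), 11.5)
  expect_equal(departure_angle(c(60, 70)), c(9, 9))
  expect_warning(out <- departure_angle(120), "clamped")
  expect_equal(out, 6)
})

test_that("injury predictions are monotone in speed, diameter and geometry", {
  base <- list(V = 80, D = 25, L = 5, R = 800)
  grid <- function(par, vals, rt) {
    d <- do.call(rbind, lapply(vals, function(v) {
      p <- base; p[[par]] <- v
      case_row(p$V, rt, if (rt == "curve") p$R else Inf, p$D, p$L)
    }))
    d
  }
  for (rt in c("straight", "curve")) {
    expect_true(all(diff(predict_cra(grid("V", 60:90, rt),
                                     round = FALSE)) > 0))
    expect_true(all(diff(predict_cra(grid("D", 10:32, rt),
                                     round = FALSE)) > 0))
    expect_true(all(diff(predict_cra(grid("L", 2:7, rt), round = FALSE)) < 0))
    expect_true(all(diff(predict_asi(grid("V", 60:90, rt),
                                     round = FALSE)) > 0))
  }
  # shallower curves (larger R) are worse at fixed spacing
  expect_true(all(diff(predict_cra(grid("R", c(100, 300, 700, 2000), "curve"),
                                   round = FALSE)) > 0))
})

test_that("refitting on noiseless model-generated data recovers the coefficients", {
  set.seed(7)
  n <- 60
  for (rt in c("straight", "curve")) {
    d <- data.frame(
      speed_kmh = runif(n, 40, 100),
      road_type = rt,
      radius_m = if (rt == "curve") runif(n, 100, 700) else Inf,
      diameter_cm = runif(n, 10, 32),
      spacing_m = runif(n, 2, 7),
      vehicle = "car")
    d$asi <- predict_asi(d, round = FALSE)
    fit <- fit_injury_model(d, "asi", rt)
    truth <- published_model("asi", "car", rt)
    expect_equal(unclass(fit$coefficients), unclass(truth)[names(fit$coefficients)],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("rank-deficient refit designs are rejected", {
  set.seed(8)
  d <- data.frame(speed_kmh = runif(30, 40, 100), road_type = "straight",
                  radius_m = Inf, diameter_cm = 20, spacing_m = 5,
                  vehicle = "car")
  d$asi <- predict_asi(d, round = FALSE)
  # diameter and spacing are constant: ln(D) and L are collinear with 1
  expect_error(fit_injury_model(d, "asi", "straight"), "singular|collinear")
  expect_error(fit_injury_model(d[1:5, ], "asi", "straight"), "at least 10")
})
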