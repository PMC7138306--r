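test_that("moving average matches the trapezoidal integration oracle", {
  dt <- 1e-4
  # constant and zero channels are fixed points of the averaging
  expect_equal(moving_average(rep(3.2, 100), dt, 0.005), rep(3.2, 50))
  expect_equal(moving_average(rep(0, 100), dt, 0.005), rep(0, 50))
  # half-sine pulse against direct slicing
  hs <- make_half_sine(120, 0.08, dt)
  got <- moving_average(hs$a, dt, 0.05)
  expect_equal(got, moving_average_oracle(hs$a, dt, 0.05), tolerance = 1e-9)
  expect_length(got, length(hs$a) - round(0.05 / dt))
})

test_that("invalid averaging windows are rejected", {
  expect_error(moving_average(rnorm(100), 1e-3, 1e-5), "shorter than")
  expect_error(moving_average(rnorm(10), 1e-3, 1), "longer than")
})

test_that("ASI closed forms hold for constant acceleration", {
  t <- seq(0, 0.2, by = 1e-3)
  zero <- acceleration_trace(t, ax = 0, ay = 0, az = 0)
  expect_equal(compute_asi(zero), 0)
  # longitudinal channel exactly at its 12 g limit -> ASI = 1
  at_limit <- acceleration_trace(t, ax = 12 * 9.8, ay = 0, az = 0)
  expect_equal(compute_asi(at_limit), 1)
  # all three channels at their limits -> sqrt(3) by symmetry
  all_limits <- acceleration_trace(t, ax = 12 * 9.8, ay = 9 * 9.8,
                                   az = 10 * 9.8)
  expect_equal(compute_asi(all_limits), sqrt(3))
})

test_that("ASI requires the three component channels", {
  t <- seq(0, 0.2, by = 1e-3)
  head_only <- acceleration_trace(t, resultant = 100, role = "head")
  expect_error(compute_asi(head_only), "component channels")
})

test_that("HIC matches its closed form and the exhaustive window oracle", {
  t <- seq(0, 0.05, by = 1e-4)
  # constant 100 g held longer than the window: 0.015 * 100^2.5
  const <- acceleration_trace(t, resultant = 100 * 9.8, role = "head")
  expect_equal(compute_hic(const), 0.015 * 100^2.5)
  expect_equal(compute_hic(acceleration_trace(t, resultant = 0,
                                              role = "head")), 0)
  # triangular pulse, peak 80 g, base 30 ms
  dt <- 2e-4
  tt <- seq(0, 0.03, by = dt)
  tri <- 80 * 9.8 * (1 - abs(2 * tt / 0.03 - 1))
  trace <- acceleration_trace(tt, resultant = tri, role = "head")
  expect_equal(compute_hic(trace), hic_oracle(tri, dt), tolerance = 1e-9)
})

test_that("CRA is the peak 3-ms mean of the chest resultant, in g", {
  t <- seq(0, 0.02, by = 1e-4)
  expect_equal(compute_cra(acceleration_trace(t, resultant = 588,
                                              role = "chest")), 60)
  expect_equal(compute_cra(acceleration_trace(t, resultant = 0,
                                              role = "chest")), 0)
  # a transient peak is averaged down: CRA < peak / g
  dt <- 1e-4
  hs <- make_half_sine(766, 0.08, dt)
  trace <- acceleration_trace(hs$time, resultant = hs$a, role = "chest")
  cra <- compute_cra(trace)
  expect_lt(cra, 766 / 9.8)
  expect_equal(cra, max(moving_average_oracle(hs$a, dt, 0.003)) / 9.8,
               tolerance = 1e-9)
  expect_error(
    compute_cra(acceleration_trace(c(0, 1e-3), resultant = c(1, 1),
                                   role = "chest")),
    "longer than")
})

test_that("indices are non-negative and strictly scale-monotone", {
  for (seed in 1:5) {
    hs <- make_half_sine(300 + 50 * seed, 0.06 + 0.005 * seed)
    vt <- acceleration_trace(hs$time, ax = hs$a, ay = 0.3 * hs$a,
                             az = 0.1 * hs$a)
    bt <- acceleration_trace(hs$time, resultant = hs$a, role = "head")
    ct <- acceleration_trace(hs$time, resultant = hs$a, role = "chest")
    scale_up <- function(tr) {
      out <- tr
      for (ch in setdiff(names(tr), "time")) out[[ch]] <- 1.5 * tr[[ch]]
      out
    }
    expect_gt(compute_asi(scale_up(vt)), compute_asi(vt))
    expect_gt(compute_hic(scale_up(bt)), compute_hic(bt))
    expect_gt(compute_cra(scale_up(ct)), compute_cra(ct))
    expect_gte(compute_asi(vt), 0)
  }
})

test_that("ASI is invariant to zero-padded time shifts of the pulse", {
  dt <- 1e-4
  hs <- make_half_sine(200, 0.06, dt)
  pad <- rep(0, 600)  # 60 ms of padding, longer than the 50-ms window
  t_long <- seq(0, by = dt, length.out = length(pad) * 2 + length(hs$a))
  shifted <- acceleration_trace(t_long, ax = c(pad, hs$a, pad), ay = 0, az = 0)
  padded <- acceleration_trace(
    seq(0, by = dt, length.out = length(hs$a) + 2 * length(pad)),
    ax = c(hs$a, pad, pad), ay = 0, az = 0)
  expect_equal(compute_asi(shifted), compute_asi(padded), tolerance = 1e-12)
})

test_that("constant-resultant identities tie CRA and HIC together", {
  t <- seq(0, 0.1, by = 1e-3)
  for (a_g in c(20, 60, 110)) {
    tr_chest <- acceleration_trace(t, resultant = a_g * 9.8, role = "chest")
    tr_head <- acceleration_trace(t, resultant = a_g * 9.8, role = "head")
    expect_equal(compute_cra(tr_chest), a_g)
    expect_equal(compute_hic(tr_head), 0.015 * a_g^2.5)
  }
})

test_that("low-pass filter passes DC, kills far-above-cutoff tones", {
  t <- seq(0, 0.5, by = 1e-4)
  const <- acceleration_trace(t, ax = 42, ay = 42, az = 42)
  filt <- lowpass_filter(const, 100)
  expect_equal(filt$ax, const$ax, tolerance = 1e-8)
  zero <- acceleration_trace(t, ax = 0, ay = 0, az = 0)
  expect_equal(lowpass_filter(zero, 100)$ax, zero$ax, tolerance = 1e-12)
  # 2 kHz tone against a 100 Hz cutoff: >= 99% attenuation in the interior
  tone <- acceleration_trace(t, ax = sin(2 * pi * 2000 * t), ay = 0, az = 0)
  ft <- lowpass_filter(tone, 100)
  interior <- seq(500, length(t) - 500)
  expect_lt(max(abs(ft$ax[interior])), 0.01)
  expect_error(lowpass_filter(tone, 5000), "Nyquist")
})

test_that("trace construction validates sampling and channels", {
  expect_error(acceleration_trace(c(0, 1e-3, 3e-3), ax = 1, ay = 1, az = 1),
               "uniformly sampled")
  expect_error(acceleration_trace(c(0, -1e-3), ax = 1, ay = 1, az = 1),
               "strictly increasing")
  expect_error(acceleration_trace(seq(0, 1, 0.1)), "resultant")
  expect_error(acceleration_trace(seq(0, 1, 0.1), ax = c(1, NA), ay = 0,
                                  az = 0), "ax")
})
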