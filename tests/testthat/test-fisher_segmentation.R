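test_that("category diameters are within-class sums of squared deviations", {
  s <- ordered_sample(c(-1, 0, 1))
  # already mean 0, sd 1 -> standardization maps {-1,0,1} to itself
  expect_equal(category_diameter(s, 1, 3), 2)
  expect_equal(category_diameter(s, 2, 2), 0)
  expect_equal(category_diameter(ordered_sample(rep(4, 5)), 1, 5), 0)
  expect_error(category_diameter(s, 3, 1), "bounds")
})

test_that("the DP finds the obvious splits of small samples", {
  s <- ordered_sample(c(1, 1.1, 5, 5.1))
  p <- optimal_partition(s, 2)
  expect_equal(p$boundaries, c(1L, 3L))
  expect_equal(p$min_error, brute_force_partition(s, 2)$min_error)

  s3 <- ordered_sample(c(0, 10, 20))
  p3 <- optimal_partition(s3, 2)
  # exhaustive enumeration over the two possible splits
  errs <- c(category_diameter(s3, 1, 1) + category_diameter(s3, 2, 3),
            category_diameter(s3, 1, 2) + category_diameter(s3, 3, 3))
  expect_equal(p3$min_error, min(errs))

  # k = m: every class a singleton, zero error
  s4 <- ordered_sample(c(2, 3, 9, 11))
  p4 <- optimal_partition(s4, 4)
  expect_equal(p4$boundaries, 1:4)
  expect_equal(p4$min_error, 0)
})

test_that("DP equals the brute-force oracle on random small samples", {
  set.seed(42)
  for (rep in 1:60) {
    m <- sample(4:12, 1)
    x <- rnorm(m, sd = sample(c(0.5, 1, 5), 1)) +
      sample(c(0, 10), m, replace = TRUE)
    s <- ordered_sample(x)
    for (k in 2:4) {
      if (k > m) next
      dp <- optimal_partition(s, k)
      bf <- brute_force_partition(s, k)
      expect_equal(dp$min_error, bf$min_error, tolerance = 1e-10)
      expect_equal(dp$boundaries, bf$boundaries)
    }
  }
})

test_that("per-k errors are non-increasing and partitions order-preserving", {
  set.seed(11)
  x <- c(rnorm(40, 0), rnorm(40, 4), rnorm(40, 9))
  s <- ordered_sample(x)
  seg <- fisher_segmentation(s, k_max = 6)
  expect_true(all(diff(seg$per_k_errors) <= 1e-12))
  # classes are contiguous runs of the sorted values
  ends <- c(seg$boundaries[-1] - 1L, s$m)
  for (h in seq_len(seg$k - 1)) {
    expect_lte(max(s$values[seg$boundaries[h]:ends[h]]),
               min(s$values[seg$boundaries[h + 1]:ends[h + 1]]))
  }
  expect_equal(sum(seg$sizes), s$m)
})

test_that("segmentation is invariant to positive affine rescaling", {
  set.seed(3)
  x <- c(rnorm(30, 0), rnorm(30, 6))
  s1 <- fisher_segmentation(ordered_sample(x), k_max = 5)
  s2 <- fisher_segmentation(ordered_sample(3.7 * x + 11), k_max = 5)
  expect_equal(s1$boundaries, s2$boundaries)
  # and standardized vs raw diameters give the same boundaries
  s_raw <- optimal_partition(ordered_sample(x), 3, standardized = FALSE)
  s_std <- optimal_partition(ordered_sample(x), 3, standardized = TRUE)
  expect_equal(s_raw$boundaries, s_std$boundaries)
})

test_that("beta ratios reproduce the published classification arithmetic", {
  cra_errors <- c(`2` = 156.005, `3` = 65.023, `4` = 45.785, `5` = 33.321)
  b <- beta_ratios(cra_errors)
  expect_equal(round(unname(b[c("2", "3", "4")]), 2), c(2.40, 1.42, 1.37))
  asic_errors <- c(`2` = 188.453, `3` = 107.125, `4` = 56.679, `5` = 40.092)
  expect_equal(round(unname(beta_ratios(asic_errors)["3"]), 2), 1.89)
  asit_errors <- c(`2` = 144.095, `3` = 45.462, `4` = 30.890, `5` = 23.236)
  expect_equal(round(unname(beta_ratios(asit_errors)["3"]), 2), 1.47)

  expect_equal(unname(beta_ratios(c(`2` = 5, `3` = 5, `4` = 5))), c(1, 1))
  zero_den <- beta_ratios(c(`2` = 1, `3` = 0))
  expect_true(is.infinite(zero_den[["2"]]))
  expect_true(isTRUE(attr(zero_den, "zero_denominator")))
})

test_that("choose_k picks the candidate with the largest error ratio", {
  cra_errors <- c(`2` = 156.005, `3` = 65.023, `4` = 45.785, `5` = 33.321)
  expect_equal(choose_k(cra_errors), 3L)
  asit_errors <- c(`2` = 144.095, `3` = 45.462, `4` = 30.890, `5` = 23.236)
  expect_equal(choose_k(asit_errors), 3L)
  # exact tie breaks toward the smaller class count
  tied <- c(`2` = 8, `3` = 4, `4` = 2, `5` = 1)
  expect_equal(choose_k(tied), 3L)
  expect_error(choose_k(cra_errors, integer(0)), "empty")
  expect_error(choose_k(c(`2` = 1, `3` = 0.5), k_candidates = 3), "extend")
})

test_that("brute force is guarded and enumerates all partitions", {
  expect_error(brute_force_partition(ordered_sample(rnorm(20)), 3),
               "m <= 15")
  s <- ordered_sample(c(1, 2, 30))
  expect_equal(brute_force_partition(s, 3)$min_error, 0)
})
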