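#' Ordered sample for Fisher optimal segmentation
#'
#' Sorts a numeric sample ascending and attaches a z-scored copy.
#' Segmentation operates on the standardized values by default; because
#' standardization is a positive affine map, class boundaries are
#' unchanged relative to segmenting the raw values.
#'
#' @param values Numeric vector, length >= 2, finite.
#' @param labels Optional identifiers carried along with the sort.
#' @return An object of class `ordered_sample`: list with `values`
#'   (sorted raw), `standardized`, `labels`, `m`.
#' @export
ordered_sample <- function(values, labels = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("an ordered sample needs at least 2 values", call. = FALSE)
  if (!all(is.finite(values)))
    stop("ordered sample values must be finite", call. = FALSE)
  ord <- order(values)
  values <- values[ord]
  if (!is.null(labels)) {
    if (length(labels) != length(values))
      stop("`labels` must match `values` in length", call. = FALSE)
    labels <- labels[ord]
  }
  s <- stats::sd(values)
  standardized <- if (s > 0) (values - mean(values)) / s else values * 0
  structure(list(values = values, standardized = standardized,
                 labels = labels, m = length(values)),
            class = "ordered_sample")
}

#' @export
print.ordered_sample <- function(x, ...) {
  cat(sprintf("<ordered_sample: m = %d, range [%.4g, %.4g]>\n",
              x$m, x$values[1L], x$values[x$m]))
  invisible(x)
}

# Prefix sums of x and x^2 (length m + 1, leading 0) for O(1) diameters.
prefix_sums <- function(x) {
  list(s = c(0, cumsum(x)), q = c(0, cumsum(x^2)))
}

# D(i, j) for vectors of i at fixed j: within-class sum of squared
# deviations of x[i..j] about its mean.
diameter_from_prefix <- function(ps, i, j) {
  n <- j - i + 1
  pmax(ps$q[j + 1] - ps$q[i] - (ps$s[j + 1] - ps$s[i])^2 / n, 0)
}

sample_vector <- function(sample, standardized = TRUE) {
  if (standardized) sample$standardized else sample$values
}

#' Category diameter of a contiguous class
#'
#' Sum of squared deviations of the class `{x_i, ..., x_j}` about the
#' class mean — the within-class dispersion that Fisher segmentation
#' minimises over all contiguous partitions.
#'
#' @param sample An [ordered_sample()].
#' @param i,j Class bounds, `1 <= i <= j <= m`.
#' @param standardized Use the z-scored values (default) or the raw values.
#' @return Non-negative scalar.
#' @export
category_diameter <- function(sample, i, j, standardized = TRUE) {
  if (i > j || i < 1L || j > sample$m)
    stop("invalid class bounds: need 1 <= i <= j <= m", call. = FALSE)
  x <- sample_vector(sample, standardized)[i:j]
  sum((x - mean(x))^2)
}

# Full DP over k = 1..k_max: returns the error table E[k, j] (min error of
# partitioning x[1..j] into k classes) and split table for backtracking.
# Arg-min ties break toward the smallest split index.
fisher_dp <- function(x, k_max) {
  m <- length(x)
  ps <- prefix_sums(x)
  E <- matrix(Inf, nrow = k_max, ncol = m)
  SPLIT <- matrix(NA_integer_, nrow = k_max, ncol = m)
  E[1L, ] <- diameter_from_prefix(ps, rep(1L, m), seq_len(m))
  if (k_max >= 2L) {
    for (k in 2:k_max) {
      for (j in k:m) {
        i <- k:j  # start index of the last class
        cand <- E[k - 1L, i - 1L] + diameter_from_prefix(ps, i, j)
        b <- which.min(cand)  # first minimum -> smallest split index
        E[k, j] <- cand[b]
        SPLIT[k, j] <- i[b]
      }
    }
  }
  list(E = E, SPLIT = SPLIT, m = m)
}

backtrack_splits <- function(dp, k) {
  starts <- integer(k)
  j <- dp$m
  for (h in k:2L) {
    starts[h] <- dp$SPLIT[h, j]
    j <- starts[h] - 1L
  }
  starts[1L] <- 1L
  starts
}

new_segmentation_result <- function(k, starts, min_error, m,
                                    per_k_errors = NULL, beta = NULL,
                                    chosen_k = NULL) {
  sizes <- diff(c(starts, m + 1L))
  structure(list(k = k, boundaries = starts, sizes = sizes,
                 min_error = min_error, per_k_errors = per_k_errors,
                 beta = beta, chosen_k = chosen_k, m = m),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  ends <- c(x$boundaries[-1L] - 1L, x$m)
  cls <- paste(sprintf("{%d~%d}", x$boundaries, ends), collapse = " ")
  cat(sprintf("<segmentation: k = %d, error = %.4g, classes %s>\n",
              x$k, x$min_error, cls))
  if (!is.null(x$chosen_k)) cat(sprintf("  chosen k = %d\n", x$chosen_k))
  invisible(x)
}

#' Optimal contiguous partition of an ordered sample
#'
#' Dynamic-programming solution of Fisher optimal segmentation for a fixed
#' class count `k`: the contiguous partition of the ordered sample into
#' `k` non-empty classes minimising the sum of category diameters, with
#' backtracking through the arg-min split points.
#'
#' @param sample An [ordered_sample()].
#' @param k Number of classes, `2 <= k <= m`.
#' @param standardized Segment the z-scored values (default) or raw values.
#' @return A `segmentation_result`: `k`, `boundaries` (start index of each
#'   class), `sizes`, `min_error`.
#' @export
optimal_partition <- function(sample, k, standardized = TRUE) {
  if (k < 2L || k > sample$m)
    stop("need 2 <= k <= m (k = ", k, ", m = ", sample$m, ")", call. = FALSE)
  x <- sample_vector(sample, standardized)
  dp <- fisher_dp(x, k)
  new_segmentation_result(k, backtrack_splits(dp, k), dp$E[k, sample$m],
                          sample$m)
}

#' Ratios of adjacent minimum classification errors
#'
#' `beta(k) = e[p(m,k)] / e[p(m,k+1)]`: how much the minimum classification
#' error shrinks when one more class is allowed.
#'
#' @param per_k_errors Named numeric vector of minimum errors `e[p(m,k)]`,
#'   names the class counts k (consecutive).
#' @return Named vector `beta(k)` for each k with a successor in the
#'   input; infinite ratios (zero denominator) are flagged with the
#'   attribute `zero_denominator`.
#' @export
beta_ratios <- function(per_k_errors) {
  ks <- as.integer(names(per_k_errors))
  if (is.null(names(per_k_errors)) || any(is.na(ks)))
    stop("`per_k_errors` must be named by class count k", call. = FALSE)
  if (length(ks) < 2L || any(diff(ks) != 1L))
    stop("`per_k_errors` must cover consecutive class counts", call. = FALSE)
  num <- per_k_errors[-length(per_k_errors)]
  den <- per_k_errors[-1L]
  beta <- num / den
  names(beta) <- ks[-length(ks)]
  if (any(den == 0)) attr(beta, "zero_denominator") <- TRUE
  beta
}

#' Select the classification number from error ratios
#'
#' Among the candidate class counts, returns the one whose ratio
#' `beta(k) = e[p(m,k)] / e[p(m,k+1)]` is largest (the larger the ratio,
#' the more distinct the curvature change of the error curve at that k).
#' Ties break toward the smaller k. The default candidates `{3, 4}` are
#' the class counts compared when the error curve's curvature visibly
#' changes there, the usage under which the published thresholds were
#' derived.
#'
#' @param per_k_errors Named numeric vector of minimum errors, as in
#'   [beta_ratios()].
#' @param k_candidates Candidate class counts; each needs `beta(k)`
#'   computable from `per_k_errors`.
#' @return The chosen k (integer).
#' @export
choose_k <- function(per_k_errors, k_candidates = c(3L, 4L)) {
  if (length(k_candidates) == 0L)
    stop("empty candidate set", call. = FALSE)
  beta <- beta_ratios(per_k_errors)
  k_candidates <- sort(as.integer(k_candidates))
  if (!all(as.character(k_candidates) %in% names(beta)))
    stop("beta not computable for all candidates; extend `per_k_errors`",
         call. = FALSE)
  b <- beta[as.character(k_candidates)]
  k_candidates[which.max(b)]  # first maximum -> smaller k on ties
}

#' Fisher optimal segmentation with class-count selection
#'
#' Runs the segmentation DP once up to `k_max`, collects the minimum
#' error for every class count `k = 2..k_max`, forms the adjacent-error
#' ratios `beta(k)`, selects the class count among `k_candidates` by
#' [choose_k()], and returns the optimal partition at the chosen k.
#'
#' @inheritParams optimal_partition
#' @param k_max Largest class count evaluated (>= 3).
#' @param k_candidates Candidates passed to [choose_k()].
#' @return A `segmentation_result` for the chosen k, with `per_k_errors`,
#'   `beta` and `chosen_k` filled in.
#' @export
fisher_segmentation <- function(sample, k_max = 5L, k_candidates = c(3L, 4L),
                                standardized = TRUE) {
  k_max <- as.integer(k_max)
  if (k_max < 3L || k_max > sample$m)
    stop("need 3 <= k_max <= m", call. = FALSE)
  x <- sample_vector(sample, standardized)
  dp <- fisher_dp(x, k_max)
  per_k <- stats::setNames(dp$E[2:k_max, sample$m], 2:k_max)
  beta <- beta_ratios(per_k)
  kc <- choose_k(per_k, k_candidates)
  new_segmentation_result(kc, backtrack_splits(dp, kc), dp$E[kc, sample$m],
                          sample$m, per_k_errors = per_k, beta = beta,
                          chosen_k = kc)
}

#' Brute-force optimal partition (test oracle)
#'
#' Exhaustively enumerates every contiguous partition of the ordered
#' sample into `k` classes and returns the one with minimal summed
#' category diameter. Combinatorial; guarded to `m <= 15`. Intended as an
#' independent oracle for [optimal_partition()].
#'
#' @inheritParams optimal_partition
#' @return A `segmentation_result`.
#' @export
brute_force_partition <- function(sample, k, standardized = TRUE) {
  m <- sample$m
  if (m > 15L)
    stop("brute force is guarded to m <= 15", call. = FALSE)
  if (k < 2L || k > m)
    stop("need 2 <= k <= m", call. = FALSE)
  x <- sample_vector(sample, standardized)
  ps <- prefix_sums(x)
  splits <- utils::combn(2:m, k - 1L)
  best <- Inf
  best_starts <- NULL
  for (col in seq_len(ncol(splits))) {
    starts <- c(1L, splits[, col])
    ends <- c(starts[-1L] - 1L, m)
    err <- sum(diameter_from_prefix(ps, starts, ends))
    if (err < best - 1e-12) {
      best <- err
      best_starts <- starts
    }
  }
  new_segmentation_result(k, best_starts, best, m)
}
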