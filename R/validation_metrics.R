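#' Confusion summary of observed vs predicted severity grades
#'
#' Tabulates observed against predicted grades on the four-level severity
#' scale. Pairs whose predicted grade is `NA` (e.g. truck cases under the
#' car-only CRA model) are dropped pairwise and counted.
#'
#' @param observed,predicted Grade vectors (factors or characters with
#'   levels [severity_levels]), equal length.
#' @return A list of class `confusion_summary`: `counts` (4x4 matrix,
#'   rows observed, columns predicted), `TN` (diagonal sum), `total`,
#'   `dropped` (pairs excluded for `NA` prediction), `misclassified`
#'   (indices of mismatching pairs in the input order).
#' @export
confusion <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  obs <- factor(as.character(observed), levels = severity_levels)
  prd <- factor(as.character(predicted), levels = severity_levels)
  keep <- !is.na(prd)
  dropped <- sum(!keep)
  obs <- obs[keep]; prd <- prd[keep]
  if (any(is.na(obs)))
    stop("observed grades contain missing or invalid values", call. = FALSE)
  counts <- table(observed = obs, predicted = prd)
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(observed = severity_levels,
                                   predicted = severity_levels))
  structure(list(counts = counts, TN = sum(diag(counts)),
                 total = sum(counts), dropped = dropped,
                 misclassified = which(keep)[as.integer(obs) != as.integer(prd)]),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  print(x$counts)
  cat(sprintf("correct %d / %d (%.1f%%), %d pair(s) dropped\n",
              x$TN, x$total, 100 * x$TN / x$total, x$dropped))
  invisible(x)
}

#' Classification error rate
#'
#' Share of graded cases whose predicted severity differs from the
#' observed injury grade.
#'
#' @param summary A [confusion()] summary.
#' @return Fraction in `[0, 1]`.
#' @export
error_rate <- function(summary) {
  if (summary$total <= 0L)
    stop("empty confusion summary", call. = FALSE)
  (summary$total - summary$TN) / summary$total
}

#' Degree of misclassification
#'
#' Grade-distance-weighted misclassification index
#' `alpha = sum(eta_ij FN_ij) / (TN + sum(eta_ij FN_ij))` over the
#' off-diagonal cells, with weights `eta_ij = |j - i| / n` and `n = 4`
#' severity grades: misgrading by two levels counts twice as much as
#' misgrading by one.
#'
#' @param summary A [confusion()] summary.
#' @return Fraction in `[0, 1)`.
#' @export
misclassification_degree <- function(summary) {
  if (summary$total <= 0L)
    stop("empty confusion summary", call. = FALSE)
  n <- nrow(summary$counts)
  eta <- abs(outer(seq_len(n), seq_len(n), "-")) / n
  weighted <- sum(eta * summary$counts)
  weighted / (summary$TN + weighted)
}
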