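#' Severity grade levels
#'
#' Accident severity is graded I-IV: I non/minor injury, II moderate,
#' III disabling, IV fatal.
#' @export
severity_levels <- c("I", "II", "III", "IV")

#' Severity thresholds for one injury index
#'
#' Three cut points partition an injury index into the four severity
#' grades: values at or below the safety limit `b1` are grade I, `(b1,
#' b2]` grade II, `(b2, b3]` grade III, and above `b3` grade IV
#' (right-closed intervals; the safety limit itself belongs to grade I).
#'
#' @param index_kind One of `"cra"`, `"asi_car"`, `"asi_truck"`,
#'   `"asi_mixed"`.
#' @param b1 Safety limit (grade I upper bound).
#' @param b2,b3 Upper bounds of grades II and III; `b1 < b2 < b3`.
#' @param truck_proportion Truck proportion for the mixed kind, else `NA`.
#' @return A list of class `severity_thresholds`.
#' @export
severity_thresholds <- function(index_kind, b1, b2, b3,
                                truck_proportion = NA_real_) {
  if (!(b1 < b2 && b2 < b3))
    stop("thresholds must satisfy b1 < b2 < b3", call. = FALSE)
  structure(list(index_kind = index_kind, b1 = b1, b2 = b2, b3 = b3,
                 truck_proportion = truck_proportion),
            class = "severity_thresholds")
}

#' @export
print.severity_thresholds <- function(x, ...) {
  cat(sprintf(
    "<severity_thresholds [%s]: I <= %g < II <= %g < III <= %g < IV>\n",
    x$index_kind, x$b1, x$b2, x$b3))
  invisible(x)
}

# Versioned published threshold sets, shipped as YAML under extdata.
read_threshold_config <- function() {
  path <- system.file("extdata", "severity_thresholds.yaml",
                      package = "treecrash")
  yaml::read_yaml(path)
}

#' Published severity thresholds
#'
#' The published cut points: CRA (60, 73, 96) g for cars, ASI
#' (1, 1.78, 2.21) for cars and (1, 1.54, 2.02) for trucks, read from the
#' packaged versioned YAML config.
#'
#' @param index_kind `"cra"`, `"asi_car"` or `"asi_truck"`.
#' @return A [severity_thresholds()] object.
#' @export
published_thresholds <- function(index_kind = c("cra", "asi_car", "asi_truck")) {
  index_kind <- match.arg(index_kind)
  cfg <- read_threshold_config()$fixed[[index_kind]]
  severity_thresholds(index_kind, cfg$b1, cfg$b2, cfg$b3)
}

#' Mixed-traffic ASI thresholds
#'
#' ASI cut points for a traffic mix with truck proportion `w`, linear in
#' `w` between the car thresholds (`w = 0`) and the truck thresholds
#' (`w = 1`): `(1, 1.78 - 0.24 w, 2.21 - 0.19 w)`.
#'
#' @param w Truck proportion in `[0, 1]`.
#' @return A [severity_thresholds()] object of kind `"asi_mixed"`.
#' @export
mixed_thresholds <- function(w) {
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1)
    stop("truck proportion `w` must be a single value in [0, 1]",
         call. = FALSE)
  cfg <- read_threshold_config()$mixed
  severity_thresholds("asi_mixed", cfg$b1,
                      cfg$b2_intercept + cfg$b2_slope * w,
                      cfg$b3_intercept + cfg$b3_slope * w,
                      truck_proportion = w)
}

#' Screen the safe group and build the ordered sample
#'
#' Cases with index values at or below the safety limit are screened out
#' as grade I; the remaining values are sorted ascending into an
#' [ordered_sample()] for segmentation.
#'
#' @param values Injury index values (finite).
#' @param safety_limit Grade-I upper bound (inclusive).
#' @param ids Optional case identifiers.
#' @return A list with `grade1_ids`, `grade1_values`, and `sample` (an
#'   [ordered_sample()], or `NULL` with a warning when fewer than two
#'   values exceed the limit).
#' @export
build_ordered_sample <- function(values, safety_limit, ids = NULL) {
  if (!all(is.finite(values)))
    stop("index values must be finite", call. = FALSE)
  if (is.null(ids)) ids <- seq_along(values)
  safe <- values <= safety_limit
  rest <- values[!safe]
  sample <- NULL
  if (length(rest) >= 2L) {
    sample <- ordered_sample(rest, labels = ids[!safe])
  } else {
    warning("fewer than two values above the safety limit; ",
            "segmentation skipped", call. = FALSE)
  }
  list(grade1_ids = ids[safe], grade1_values = values[safe], sample = sample)
}

#' Severity thresholds from a 3-class segmentation
#'
#' Converts a 3-class optimal partition of the above-limit ordered sample
#' into severity cut points: `b1` is the safety limit, `b2` and `b3` the
#' maxima (raw index units) of the first and second classes, so the grade
#' intervals are `(b1, b2]`, `(b2, b3]`, `(b3, Inf)`.
#'
#' @param sample The [ordered_sample()] that was segmented.
#' @param partition A `segmentation_result` with `k = 3`.
#' @param safety_limit Grade-I upper bound.
#' @param index_kind Passed to [severity_thresholds()].
#' @return A [severity_thresholds()] object.
#' @export
thresholds_from_partition <- function(sample, partition, safety_limit,
                                      index_kind = "cra") {
  if (partition$k != 3L)
    stop("threshold derivation needs a 3-class partition (got k = ",
         partition$k, ")", call. = FALSE)
  ends <- c(partition$boundaries[-1L] - 1L, partition$m)
  severity_thresholds(index_kind, safety_limit,
                      sample$values[ends[1L]], sample$values[ends[2L]])
}

#' Assign severity grades to index values
#'
#' Right-closed interval classification: values at or below `b1` are I,
#' `(b1, b2]` II, `(b2, b3]` III, above `b3` IV. `NA` values yield `NA`
#' grades.
#'
#' @param values Injury index values.
#' @param thresholds A [severity_thresholds()] object.
#' @return Factor of grades with levels [severity_levels].
#' @export
assign_grade <- function(values, thresholds) {
  cut(values,
      breaks = c(-Inf, thresholds$b1, thresholds$b2, thresholds$b3, Inf),
      labels = severity_levels, right = TRUE)
}

#' Severity grade from an observed injury label
#'
#' Maps recorded driver injury descriptions to the four severity grades:
#' non- or minor injury to I, moderate to II, disabling to III, fatal to
#' IV. Case-insensitive.
#'
#' @param label Character vector of labels among `"non"`, `"minor"`,
#'   `"moderate"`, `"disabling"`, `"fatal"`.
#' @return Factor of grades with levels [severity_levels].
#' @export
injury_grade_from_label <- function(label) {
  map <- c(non = "I", minor = "I", moderate = "II",
           disabling = "III", fatal = "IV")
  key <- tolower(trimws(label))
  unknown <- !is.na(key) & !key %in% names(map)
  if (any(unknown))
    stop("unknown injury label(s): ",
         paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
  factor(unname(map[key]), levels = severity_levels)
}
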