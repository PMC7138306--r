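#' Load a crash-case table from CSV
#'
#' Reads and validates a case table. Required columns: `id`, `speed_kmh`,
#' `road_type` (`straight`/`curve`), `radius_m` (`+inf`, `inf` or blank
#' for straight segments), `diameter_cm`, `spacing_m`, `vehicle`
#' (`car`/`truck`). Optional columns: `observed_injury` (driver injury
#' label, normalised to a grade via [injury_grade_from_label()]), plus
#' any precomputed index/grade columns, carried through untouched.
#'
#' @param path CSV file (comma-separated, UTF-8, `.` decimal).
#' @return A validated data frame of class `case_table`; an
#'   `observed_grade` factor column is added when `observed_injury` is
#'   present. The attribute `source` records the file path.
#' @export
load_cases <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "speed_kmh", "road_type", "radius_m", "diameter_cm",
                "spacing_m", "vehicle")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("case file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$id))
    stop("case ids must be unique", call. = FALSE)

  fail <- function(row, msg)
    stop(sprintf("row %d (id %s): %s", row, d$id[row], msg), call. = FALSE)

  d$road_type <- tolower(trimws(d$road_type))
  d$vehicle <- tolower(trimws(d$vehicle))
  rad <- tolower(trimws(as.character(d$radius_m)))
  rad[rad %in% c("+inf", "inf", "+∞", "")] <- "Inf"
  d$radius_m <- suppressWarnings(as.numeric(rad))

  for (r in seq_len(nrow(d))) {
    if (!d$road_type[r] %in% c("straight", "curve"))
      fail(r, paste0("unknown road_type '", d$road_type[r], "'"))
    if (!d$vehicle[r] %in% c("car", "truck"))
      fail(r, paste0("unknown vehicle '", d$vehicle[r], "'"))
    for (col in c("speed_kmh", "diameter_cm", "spacing_m")) {
      v <- d[[col]][r]
      if (!is.finite(v) || v <= 0)
        fail(r, paste0("`", col, "` must be a positive number"))
    }
    if (d$road_type[r] == "curve" &&
        (is.na(d$radius_m[r]) || !is.finite(d$radius_m[r]) ||
         d$radius_m[r] <= 0))
      fail(r, "curve cases need a finite positive `radius_m`")
    if (is.na(d$radius_m[r])) d$radius_m[r] <- Inf
  }
  if ("observed_injury" %in% names(d))
    d$observed_grade <- injury_grade_from_label(d$observed_injury)
  class(d) <- c("case_table", "data.frame")
  attr(d, "source") <- path
  d
}

#' Write a case table to CSV
#'
#' Inverse of [load_cases()]: unbounded radii are written as `+inf` so a
#' write/read round trip is the identity on the case columns.
#'
#' @param cases A case table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- as.data.frame(cases)
  out$observed_grade <- NULL
  out$radius_m <- ifelse(is.infinite(out$radius_m), "+inf",
                         as.character(out$radius_m))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' The packaged validation case table
#'
#' Fifty documented tree-collision accident cases (45 cars, 5 trucks)
#' with departure speed, road geometry, tree dimensions, the recorded
#' driver injury grade and the published index values and severity
#' grades, shipped as `extdata/table7_cases.csv`.
#'
#' @return A `case_table` (see [load_cases()]).
#' @export
table7_cases <- function() {
  load_cases(system.file("extdata", "table7_cases.csv",
                         package = "treecrash"))
}

#' Run the full severity-assessment pipeline on a case table
#'
#' For every case, evaluates the published injury models (CRA for cars,
#' ASI for all vehicles, reported with the published rounding), assigns
#' severity grades from the published thresholds, and — when observed
#' injury grades are present — scores each index's grading against them
#' with the confusion summary, error rate and degree of
#' misclassification. Truck cases receive no CRA-based grade (the
#' published CRA model covers cars only) and are dropped from the
#' CRA-based validation.
#'
#' @param cases A case table (see [load_cases()]).
#' @param truck_proportion Optional truck proportion `w`; when given, a
#'   mixed-traffic ASI column and grade (thresholds from
#'   [mixed_thresholds()]) are added.
#' @return A list of class `severity_report`: `cases` (the per-case table
#'   with `cra_pred`, `asi_pred`, `grade_cra_pred`, `grade_asi_pred`),
#'   and, when observed grades exist, `metrics$cra` and `metrics$asi`,
#'   each with `confusion`, `error_rate`, `alpha`, `misclassified_ids`.
#' @export
run_full_pipeline <- function(cases, truck_proportion = NULL) {
  check_case_cols(cases)
  out <- as.data.frame(cases)
  is_car <- out$vehicle == "car"
  out$cra_pred <- NA_real_
  if (any(is_car)) out$cra_pred[is_car] <- predict_cra(out[is_car, ])
  out$asi_pred <- predict_asi(out)
  out$grade_cra_pred <- assign_grade(out$cra_pred, published_thresholds("cra"))
  asi_thr <- ifelse(is_car, "asi_car", "asi_truck")
  out$grade_asi_pred <- factor(NA_character_, levels = severity_levels)
  for (kind in unique(asi_thr)) {
    sel <- asi_thr == kind
    out$grade_asi_pred[sel] <-
      assign_grade(out$asi_pred[sel], published_thresholds(kind))
  }
  if (!is.null(truck_proportion)) {
    out$asi_mixed_pred <- predict_asi_mixed(out, truck_proportion)
    out$grade_asi_mixed_pred <-
      assign_grade(out$asi_mixed_pred, mixed_thresholds(truck_proportion))
  }

  metrics <- NULL
  if ("observed_grade" %in% names(out)) {
    score <- function(pred) {
      cm <- confusion(out$observed_grade, pred)
      list(confusion = cm,
           error_rate = error_rate(cm),
           alpha = misclassification_degree(cm),
           misclassified_ids = out$id[cm$misclassified])
    }
    metrics <- list(cra = score(out$grade_cra_pred),
                    asi = score(out$grade_asi_pred))
  }
  structure(list(cases = out, metrics = metrics,
                 truck_proportion = truck_proportion),
            class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("Severity report: %d case(s)\n", nrow(x$cases)))
  if (!is.null(x$metrics)) {
    for (idx in names(x$metrics)) {
      m <- x$metrics[[idx]]
      cat(sprintf(
        "  %s-based grading: error rate %.1f%%, misclassification degree %.2f%%",
        toupper(idx), 100 * m$error_rate, 100 * m$alpha))
      if (length(m$misclassified_ids))
        cat(" (cases ", paste(m$misclassified_ids, collapse = ", "), ")",
            sep = "")
      cat("\n")
    }
  }
  invisible(x)
}

#' Serialise a severity report to JSON
#'
#' @param report A [run_full_pipeline()] report.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(cases = report$cases)
  if (!is.null(report$metrics)) {
    payload$metrics <- lapply(report$metrics, function(m) list(
      confusion = m$confusion$counts,
      dropped = m$confusion$dropped,
      error_rate = m$error_rate,
      alpha = m$alpha,
      misclassified_ids = m$misclassified_ids))
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
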