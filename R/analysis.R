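#' Summary statistics for an error series
#'
#' Cohort-style summary: arithmetic mean, sample standard deviation (n-1
#' denominator, 0 for a single value), maximum, and count.
#'
#' @param values Non-empty numeric vector (mm).
#' @return List with `n`, `mean`, `sd`, `max`.
#' @export
summarize_errors <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot summarize an empty error series")
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) == 1L) 0 else sd(values),
       max = max(values))
}

#' Threshold sensitivity of automated distances
#'
#' For each contact x tract group measured at several candidate thresholds,
#' the spread is the max minus min automated distance over the thresholds at
#' which the tract mask was non-empty — the per-measurement footprint of the
#' threshold choice. Groups with fewer than two measurable thresholds cannot
#' be assessed and are counted separately.
#'
#' @param sweep Data.frame with columns `patient_id`, `hemisphere`, `tract`,
#'   `contact_index`, `p`, `d_auto_mm` (`NA` where the mask was empty), one
#'   row per group x threshold.
#' @return List with `records` (one row per group: ids, `n_thresholds`,
#'   `spread_mm`, `assessable`), `stats` ([summarize_errors()] of assessable
#'   spreads) and `n_unassessable`.
#' @export
threshold_sensitivity <- function(sweep) {
  required <- c("patient_id", "hemisphere", "tract", "contact_index",
                "p", "d_auto_mm")
  missing <- setdiff(required, names(sweep))
  if (length(missing)) {
    stop("sensitivity input is missing columns: ",
         paste(missing, collapse = ", "))
  }
  key <- interaction(sweep$patient_id, sweep$hemisphere, sweep$tract,
                     sweep$contact_index, drop = TRUE)
  groups <- split(sweep, key)
  records <- do.call(rbind, lapply(groups, function(g) {
    d <- g$d_auto_mm[!is.na(g$d_auto_mm)]
    data.frame(patient_id = g$patient_id[1], hemisphere = g$hemisphere[1],
               tract = g$tract[1], contact_index = g$contact_index[1],
               n_thresholds = length(d),
               spread_mm = if (length(d) >= 2L) max(d) - min(d) else NA_real_,
               assessable = length(d) >= 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  ok <- records$spread_mm[records$assessable]
  list(records = records,
       stats = if (length(ok)) summarize_errors(ok) else NULL,
       n_unassessable = sum(!records$assessable))
}

#' Manual-versus-automated measurement differences
#'
#' Absolute differences between the emulated manual axial measurement and
#' the automated 3D distance-map measurement, over the records where the
#' manual measurement was possible. Records whose tract was not visible on
#' the contact's axial slice are counted as unmeasurable and drop out, as in
#' manual practice.
#'
#' @param measurements Data.frame of [measure_contact()] rows.
#' @return List with `differences` (mm), `stats` ([summarize_errors()]),
#'   `n_unmeasurable` and `n_measured`.
#' @export
manual_vs_auto <- function(measurements) {
  measurable <- measurements$manual_measurable & !is.na(measurements$d_auto_mm)
  diffs <- abs(measurements$d_manual_mm[measurable] -
                 measurements$d_auto_mm[measurable])
  list(differences = diffs,
       stats = if (length(diffs)) summarize_errors(diffs) else NULL,
       n_unmeasurable = sum(!measurable),
       n_measured = nrow(measurements) - sum(!measurable))
}

#' Assemble the three-source error report
#'
#' One row per investigated error source — binarization-threshold choice,
#' measurement technique (manual axial vs. automated 3D), and normalization
#' into the standard space — each carrying the count, mean, sample SD and
#' maximum of its error series in mm.
#'
#' @param sensitivity,manual,normalization [summarize_errors()] lists for
#'   the three sources.
#' @return A `tractgap_report`: list of three row lists
#'   (`source`, `n`, `mean_mm`, `sd_mm`, `max_mm`).
#' @export
build_report <- function(sensitivity, manual, normalization) {
  sections <- list(`threshold choice` = sensitivity,
                   `measurement technique` = manual,
                   normalization = normalization)
  for (nm in names(sections)) {
    s <- sections[[nm]]
    if (is.null(s) || !all(c("n", "mean", "sd", "max") %in% names(s))) {
      stop("missing or incomplete report section: ", nm)
    }
  }
  rows <- Map(function(nm, s) {
    list(source = nm, n = s$n, mean_mm = s$mean, sd_mm = s$sd, max_mm = s$max)
  }, names(sections), sections)
  structure(unname(rows), class = "tractgap_report")
}

#' Write a report as JSON
#'
#' @param report A `tractgap_report` from [build_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), identity), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a report back from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return A `tractgap_report`.
#' @export
read_report <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(rows, class = "tractgap_report")
}

#' @export
print.tractgap_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a report as text
#'
#' @param report A `tractgap_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  lines <- c("Summary of measured errors",
             sprintf("%-24s %6s %18s %12s", "source", "n",
                     "mean +/- sd (mm)", "max (mm)"))
  for (r in report) {
    lines <- c(lines, sprintf("%-24s %6d %9.2f +/- %.2f %12.2f",
                              r$source, as.integer(r$n), r$mean_mm, r$sd_mm,
                              r$max_mm))
  }
  lines
}
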