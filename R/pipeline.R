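#' Measure all contacts of a phantom cohort
#'
#' Per patient: selects the whole-brain discrimination threshold from the
#' candidate list, sweeps every contact x tract over ALL candidate
#' thresholds (the threshold-sensitivity export), and produces the primary
#' measurement records at the selected threshold with the step-down rule
#' applied. Masks and distance maps are computed once per
#' hemisphere/tract/threshold and shared across that patient's contacts.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @return List with `measurements` (primary [measure_contact()] records),
#'   `sweep` (long data.frame: one row per contact x tract x threshold with
#'   `d_auto_mm`, `NA` for empty masks) and `selection` (per patient:
#'   `patient_id`, `p_selected`, `feasible`).
#' @export
measure_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  cfg <- cohort$config
  meas <- list()
  sweep_rows <- list()
  selection <- list()
  for (p in cohort$patients) {
    sel <- select_discrimination_threshold(
      p$volumes$left[["c-DRTT"]], p$volumes$right[["c-DRTT"]],
      p$volumes$left[["nd-DRTT"]], p$volumes$right[["nd-DRTT"]],
      candidates = cfg$percents,
      nonzero_only = cfg$robust_range_nonzero_only)
    selection[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id, p_selected = sel$p, feasible = sel$feasible,
      stringsAsFactors = FALSE)
    for (hemi in c("left", "right")) {
      vols <- p$volumes[[hemi]]
      cache <- new.env(parent = emptyenv())
      hc <- p$contacts[p$contacts$hemisphere == hemi, , drop = FALSE]
      # threshold sweep: automated distance at every candidate
      for (label in names(vols)) {
        rng <- robust_range(vols[[label]],
                            nonzero_only = cfg$robust_range_nonzero_only)
        for (pc in cfg$percents) {
          m <- binarize_thrp(vols[[label]], pc, range = rng,
                             source_id = paste(p$patient_id, hemi, label))
          dmap <- if (m$provenance$empty) NULL else compute_distance_map(m)
          key <- paste0(label, "@", pc)
          assign(key, list(mask = m, dmap = dmap), envir = cache)
          d <- if (is.null(dmap)) {
            rep(NA_real_, nrow(hc))
          } else {
            vapply(seq_len(nrow(hc)), function(r) {
              distance_at_point(dmap, c(hc$x_mm[r], hc$y_mm[r], hc$z_mm[r]))
            }, numeric(1))
          }
          sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
            patient_id = p$patient_id, hemisphere = hemi, tract = label,
            contact_index = hc$contact_index, p = pc, d_auto_mm = d,
            stringsAsFactors = FALSE)
        }
      }
      # primary measurements at the selected threshold (cache shared)
      for (r in seq_len(nrow(hc))) {
        jseed <- if (cfg$jitter_mm > 0) {
          patient_seed(cohort$seed, 7919L + 31L * r +
                         match(p$patient_id, vapply(cohort$patients,
                                                    `[[`, "", "patient_id")))
        } else {
          NULL
        }
        meas[[length(meas) + 1L]] <- measure_contact(
          vols, hc[r, , drop = FALSE], p_selected = sel$p,
          candidates = cfg$percents,
          step_cutoff_mm = cfg$step_down_cutoff_mm,
          jitter_mm = cfg$jitter_mm, seed = jseed,
          nonzero_only = cfg$robust_range_nonzero_only, cache = cache)
      }
    }
  }
  list(measurements = do.call(rbind, meas),
       sweep = do.call(rbind, sweep_rows),
       selection = do.call(rbind, unname(selection)))
}

#' Landmark normalization errors for a phantom cohort
#'
#' Applies the landmark protocol to every patient — tip of the (right) lead
#' to the red-nucleus landmark, native versus normalized space — and flags
#' outliers above the exclusion cutoff.
#'
#' @param cohort A `phantom_cohort`.
#' @param cutoff_mm Exclusion cutoff in mm (default from the cohort config).
#' @return [exclude_outliers()] result; `flagged` carries one row per
#'   patient with the `excluded` column.
#' @export
normalization_cohort <- function(cohort,
                                 cutoff_mm = cohort$config$outlier_cutoff_mm) {
  rows <- lapply(cohort$patients, function(p) {
    tipc <- p$contacts[p$contacts$hemisphere == "right" &
                         p$contacts$contact_index == 0L, , drop = FALSE]
    tip <- c(tipc$x_mm, tipc$y_mm, tipc$z_mm)
    landmark_error(tip, p$rn_native, p$transform, p$rn_atlas,
                   patient_id = p$patient_id)
  })
  exclude_outliers(do.call(rbind, rows), cutoff_mm = cutoff_mm)
}

#' Run the full error-assessment pipeline on a phantom cohort
#'
#' simulate -> threshold selection -> distance measurement (automated +
#' emulated manual, with the step-down rule) -> threshold-sensitivity sweep
#' -> landmark normalization error -> three-source report. All stages are
#' deterministic given `(config, seed)`; every output file gets a
#' provenance sidecar (`<file>.prov.json` with config hash, seed and
#' package version). Progress is logged to standard error; machine outputs
#' go only to files.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any computation.
#' @param seed Master integer seed.
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output.
#' @param write_volumes Also write the phantom NIfTI volumes and transforms
#'   (large; default FALSE).
#' @return List with `report`, `measurements`, `sweep`, `selection`,
#'   `sensitivity`, `manual`, `normalization`, `config`, `seed`, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL,
                         write_volumes = FALSE) {
  config <- validate_config(config)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    message(sprintf("[tractgap] %s ...", name))
    out <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[tractgap] %s done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), s, units = "secs"))))
    out
  }
  cohort <- stage("simulate", generate_cohort(config, seed))
  measured <- stage("measure", measure_cohort(cohort))
  norm <- stage("normalization", normalization_cohort(cohort))
  sens <- stage("sensitivity", threshold_sensitivity(measured$sweep))
  mva <- manual_vs_auto(measured$measurements)
  norm_stats <- summarize_errors(norm$retained$error_mm)
  report <- build_report(sens$stats, mva$stats, norm_stats)
  result <- list(report = report, measurements = measured$measurements,
                 sweep = measured$sweep, selection = measured$selection,
                 sensitivity = sens, manual = mva,
                 normalization = norm, config = config, seed = seed)
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      prov <- provenance_info(config, seed)
      emit <- function(writer, obj, fn) {
        path <- file.path(out_dir, fn)
        writer(obj, path)
        jsonlite::write_json(prov, paste0(path, ".prov.json"),
                             auto_unbox = TRUE, digits = NA)
        path
      }
      wcsv <- function(obj, path) write.csv(obj, path, row.names = FALSE,
                                            quote = FALSE)
      emit(wcsv, measured$measurements, "measurements.csv")
      emit(wcsv, measured$sweep, "sensitivity_sweep.csv")
      emit(wcsv, measured$selection, "threshold_selection.csv")
      emit(wcsv, sens$records, "sensitivity_records.csv")
      emit(wcsv, norm$flagged, "normerror.csv")
      emit(write_report, report, "report.json")
      writeLines(format_report(report), file.path(out_dir, "report.txt"))
      if (write_volumes) write_cohort(cohort, file.path(out_dir, "cohort"))
    })
  }
  message(sprintf("[tractgap] pipeline finished (%.1fs total)",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(result)
}

provenance_info <- function(config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(x, collapse = ","), ""),
                   sep = "="), tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = seed,
       package_version = as.character(packageVersion("tractgap")))
}
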