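#' Run the full quantification-to-summary pipeline
#'
#' Reads plate exports, fits a standard curve per plate on duplicate-mean
#' percent bound, applies the QC cascade, quantifies every sample to ng/g
#' dry feces, resolves re-runs, then runs the longitudinal analysis
#' (baselines, peaks, dual-metabolite stress events, note matching) and
#' writes all artifacts to `out_dir`. The pipeline itself draws no random
#' numbers, so identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param input_dir directory holding `layout.csv`, `od.csv`,
#'   `extractions.csv` (the plate layer) and/or a ready-made `series.csv`
#'   (`animal_id, date, assay, conc_ng_g`); `notes.csv` is optional (a
#'   warning is issued and events stay unannotated without it).
#' @param out_dir output directory, created if missing. Artifacts:
#'   `measurements.csv`, `qc.csv`, `curves.json` (when plates were
#'   quantified), `summary.csv`, `events.csv`, `totals.json`.
#' @param config an [fgm_config()].
#' @return Invisibly, a list with `measurements`, `qc`, `analysis` (the
#'   [analyze_study()] result) and the paths written.
#' @export
run_pipeline <- function(input_dir, out_dir, config = fgm_config()) {
  paths <- function(d, f) file.path(d, f)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  measurements <- NULL
  qc_tab <- NULL
  curves <- list()
  have_plates <- file.exists(paths(input_dir, "layout.csv")) &&
    file.exists(paths(input_dir, "od.csv"))
  if (have_plates) {
    layout <- utils::read.csv(paths(input_dir, "layout.csv"),
                              stringsAsFactors = FALSE)
    od <- utils::read.csv(paths(input_dir, "od.csv"),
                          stringsAsFactors = FALSE)
    extractions <- read_extractions(paths(input_dir, "extractions.csv"))
    plates <- plates_from_tables(layout, od)
    meas <- list(); qc <- list()
    for (pid in names(plates)) {
      plate <- plates[[pid]]
      dup <- plate_duplicates(plate)
      std <- dup[dup$role == "STANDARD", ]
      nsb <- dup$mean_od[dup$role == "NSB"]
      b0 <- dup$mean_od[dup$role == "B0"]
      curve <- fit_4pl(std$standard_conc_pg_ml,
                       percent_bound(std$mean_od, nsb, b0),
                       plate_id = pid)
      curves[[pid]] <- c(curve$params,
                         list(residual_sse = curve$residual_sse,
                              range_low = curve$range_low,
                              range_high = curve$range_high))
      rep <- apply_qc(plate, config)
      qc[[pid]] <- data.frame(
        plate_id = pid, assay = plate$assay,
        n_sample_fail = rep$n_sample_fail,
        frac_sample_fail = rep$frac_sample_fail,
        standards_cv_fail = rep$standards_cv_fail,
        plate_rerun_required = rep$plate_rerun_required,
        intra_assay_cv = rep$intra_assay_cv)
      meas[[pid]] <- quantify_plate(plate, curve, extractions, config)
    }
    measurements <- supersede_measurements(do.call(rbind, meas))
    rownames(measurements) <- NULL
    qc_tab <- do.call(rbind, qc)
    rownames(qc_tab) <- NULL
  }

  if (file.exists(paths(input_dir, "series.csv"))) {
    series <- utils::read.csv(paths(input_dir, "series.csv"),
                              stringsAsFactors = FALSE)
  } else if (!is.null(measurements)) {
    series <- measurements_to_series(measurements)
  } else {
    stop("pipeline input error: need layout.csv+od.csv+extractions.csv ",
         "or series.csv under ", input_dir, call. = FALSE)
  }

  notes <- NULL
  if (file.exists(paths(input_dir, "notes.csv"))) {
    notes <- read_notes(paths(input_dir, "notes.csv"))
  } else {
    warning("no notes.csv found; stress events will be unannotated",
            call. = FALSE)
  }

  analysis <- analyze_study(series, notes, config)

  written <- character()
  if (!is.null(measurements)) {
    utils::write.csv(measurements, paths(out_dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(qc_tab, paths(out_dir, "qc.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    jsonlite::write_json(curves, paths(out_dir, "curves.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, "measurements.csv", "qc.csv", "curves.json")
  }
  utils::write.csv(format_summary(analysis$per_animal),
                   paths(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(events_table(analysis$events),
                   paths(out_dir, "events.csv"),
                   row.names = FALSE, quote = TRUE, na = "")
  jsonlite::write_json(analysis$totals, paths(out_dir, "totals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, "summary.csv", "events.csv", "totals.json")

  invisible(list(measurements = measurements, qc = qc_tab,
                 analysis = analysis,
                 paths = file.path(out_dir, written)))
}

format_summary <- function(per_animal) {
  out <- per_animal
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 4))
  out
}

#' Flatten stress events into a table
#'
#' @param events list of `stress_event`s (with or without matched notes).
#' @return Data frame with one row per event: animal, span, kind, peak
#'   magnitudes and matched-note summary.
#' @export
events_table <- function(events) {
  if (!length(events)) {
    return(data.frame(animal_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), kind = character(),
                      n_dates = integer(), max_cortisol_ng_g = numeric(),
                      max_corticosterone_ng_g = numeric(),
                      n_notes = integer(), note_categories = character()))
  }
  rows <- lapply(events, function(ev) {
    data.frame(
      animal_id = ev$animal_id,
      start_date = min(ev$dates), end_date = max(ev$dates),
      kind = ev$kind, n_dates = length(ev$dates),
      max_cortisol_ng_g = max(ev$metabolite_values$cortisol_ng_g),
      max_corticosterone_ng_g =
        max(ev$metabolite_values$corticosterone_ng_g),
      n_notes = NROW(ev$matched_notes),
      note_categories = if (NROW(ev$matched_notes)) {
        paste(sort(unique(ev$matched_notes$category)), collapse = ";")
      } else {
        ""
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$animal_id, out$start_date), ]
}
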