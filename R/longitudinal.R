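#' @title Longitudinal baseline, peaks and stress events
#' @name longitudinal
#' @description Per-individual analysis of dated FGM concentrations. The
#'   baseline is a one-pass trimmed mean: values more than 1 SD above the
#'   untrimmed mean are removed and the mean recomputed. Peaks are samples
#'   strictly above mean + 2 SD, both statistics from the full untrimmed
#'   series. An adrenal stress response requires BOTH metabolites
#'   (cortisol- and corticosterone-immunoreactive) to peak on the same
#'   date; single dual-peak dates are acute events, runs of consecutive
#'   sampled dual-peak dates are chronic. Events are matched against
#'   husbandry notes from the peak day and the preceding day (48-h
#'   window).
NULL

#' Trimmed-mean baseline of a concentration series
#'
#' Untrimmed mean and sample SD (n-1), then a single trimming pass: values
#' strictly above `mean + trim_sd * sd` are removed and the mean of the
#' remainder is the baseline. With nothing removed the baseline equals the
#' mean; it can never exceed it.
#'
#' @param values concentrations in ng/g dry feces; at least one.
#' @param trim_sd trim multiplier (default 1 SD).
#' @return List with `mean`, `sd` (`NA` for a single value), `baseline`,
#'   `n`, `n_trimmed`.
#' @examples
#' compute_baseline(c(1, 2, 3, 100))  # trims the 100; baseline 2
#' @export
compute_baseline <- function(values, trim_sd = 1) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty concentration series", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  s_trim <- if (is.na(s)) 0 else s
  keep <- values <= m + trim_sd * s_trim
  list(mean = m, sd = s, baseline = mean(values[keep]),
       n = length(values), n_trimmed = sum(!keep))
}

#' Construct a per-animal hormone series
#'
#' Multiple samples on one calendar day are averaged into a single daily
#' value before any statistic is computed; the raw values are retained.
#' Baseline and peak threshold follow [compute_baseline()] and the
#' `mean + peak_sd * sd` rule on the untrimmed daily series.
#'
#' @param animal_id animal identifier.
#' @param assay metabolite assay name.
#' @param dates sample dates (`Date` or ISO strings).
#' @param values concentrations in ng/g dry feces.
#' @param config an [fgm_config()].
#' @return Object of class `hormone_series` with `observations` (raw),
#'   `daily` (date-ordered daily means), `mean`, `sd`, `baseline`,
#'   `peak_threshold`.
#' @export
hormone_series <- function(animal_id, assay, dates, values,
                           config = fgm_config()) {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("dates and values must have equal length", call. = FALSE)
  }
  ok <- !is.na(dates) & is.finite(values)
  dates <- dates[ok]; values <- values[ok]
  if (!length(values)) stop("empty concentration series", call. = FALSE)
  if (any(values < 0)) stop("concentrations must be >= 0", call. = FALSE)

  daily_val <- tapply(values, dates, mean)
  daily <- data.frame(date = as.Date(names(daily_val)),
                      conc_ng_g = as.numeric(daily_val))
  daily <- daily[order(daily$date), ]
  rownames(daily) <- NULL

  bl <- compute_baseline(daily$conc_ng_g, trim_sd = config$trim_sd)
  sd_for_threshold <- if (is.na(bl$sd)) NA_real_ else bl$sd
  structure(list(
    animal_id = animal_id, assay = assay,
    observations = data.frame(date = dates, conc_ng_g = values),
    daily = daily,
    mean = bl$mean, sd = bl$sd, baseline = bl$baseline,
    n_trimmed = bl$n_trimmed,
    peak_threshold = bl$mean + config$peak_sd * sd_for_threshold
  ), class = "hormone_series")
}

#' @export
print.hormone_series <- function(x, ...) {
  cat(sprintf(
    "<hormone_series> %s / %s: %d daily values (%s to %s)\n",
    x$animal_id, x$assay, nrow(x$daily), min(x$daily$date),
    max(x$daily$date)))
  cat(sprintf("  mean %.1f, SD %.1f, baseline %.1f, peak threshold %.1f ng/g\n",
              x$mean, x$sd, x$baseline, x$peak_threshold))
  invisible(x)
}

#' Detect peak dates in a hormone series
#'
#' A peak is a daily value strictly greater than `mean + peak_sd * sd`
#' of the untrimmed daily series. A constant series (SD zero) or a
#' single-value series has no peaks.
#'
#' @param series a [hormone_series()].
#' @return `Date` vector of peak dates (possibly empty).
#' @export
detect_peaks <- function(series) {
  stopifnot(inherits(series, "hormone_series"))
  thr <- series$peak_threshold
  if (!is.finite(thr)) return(as.Date(character()))
  series$daily$date[series$daily$conc_ng_g > thr]
}

#' Classify dual-metabolite stress events
#'
#' Intersects the peak dates of an animal's cortisol and corticosterone
#' series on the dates sampled for both metabolites, then groups runs of
#' dual-peak dates that are adjacent in the animal's sampled-date sequence
#' (no intervening non-peak sampling) and at most `chronic_gap_days`
#' apart. A single-date run is an acute event; a multi-date run is
#' chronic.
#'
#' @param cortisol,corticosterone the two [hormone_series()] of one animal.
#' @param config an [fgm_config()].
#' @return List of `stress_event` objects, each with `animal_id`, `dates`,
#'   `kind` (`"acute"`/`"chronic"`), `metabolite_values` (per-date cortisol
#'   and corticosterone ng/g) and an empty `matched_notes` slot.
#' @export
classify_stress_events <- function(cortisol, corticosterone,
                                   config = fgm_config()) {
  stopifnot(inherits(cortisol, "hormone_series"),
            inherits(corticosterone, "hormone_series"))
  if (!identical(cortisol$animal_id, corticosterone$animal_id)) {
    stop("series belong to different animals: ", cortisol$animal_id,
         " vs ", corticosterone$animal_id, call. = FALSE)
  }
  sampled <- sort(as.Date(intersect(cortisol$daily$date,
                                    corticosterone$daily$date)))
  dual <- sort(as.Date(intersect(detect_peaks(cortisol),
                                 detect_peaks(corticosterone))))
  dual <- dual[dual %in% sampled]
  if (!length(dual)) return(list())

  idx <- match(dual, sampled)
  new_run <- c(TRUE, diff(idx) > 1L |
                 diff(as.numeric(dual)) > config$chronic_gap_days)
  run_id <- cumsum(new_run)
  lapply(split(dual, run_id), function(dates) {
    structure(list(
      animal_id = cortisol$animal_id,
      dates = dates,
      kind = if (length(dates) > 1L) "chronic" else "acute",
      metabolite_values = data.frame(
        date = dates,
        cortisol_ng_g = cortisol$daily$conc_ng_g[
          match(dates, cortisol$daily$date)],
        corticosterone_ng_g = corticosterone$daily$conc_ng_g[
          match(dates, corticosterone$daily$date)]),
      matched_notes = NULL
    ), class = "stress_event")
  })
}

#' @export
print.stress_event <- function(x, ...) {
  cat(sprintf("<stress_event> %s %s: %s%s (%d matched note%s)\n",
              x$animal_id, x$kind, min(x$dates),
              if (length(x$dates) > 1L) paste0(" to ", max(x$dates)) else "",
              NROW(x$matched_notes),
              if (NROW(x$matched_notes) == 1L) "" else "s"))
  invisible(x)
}

#' Read husbandry notes
#'
#' @param path CSV with columns `animal_id, timestamp` (ISO 8601),
#'   `category` (health, enrichment, exhibit_shift, environment,
#'   normal_behavior, other), `text`.
#' @return Data frame with a parsed `date` column.
#' @export
read_notes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "category", "text")
  if (!all(need %in% names(x))) {
    stop("notes file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c("health", "enrichment", "exhibit_shift", "environment",
               "normal_behavior", "other")
  bad <- setdiff(unique(x$category), allowed)
  if (length(bad)) {
    stop("unknown note category(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x$date <- as.Date(substr(x$timestamp, 1, 10))
  if (anyNA(x$date)) stop("unparseable note timestamp(s)", call. = FALSE)
  x
}

#' Match husbandry notes to stress events
#'
#' A note matches an event when it was logged on a peak date or within the
#' preceding window (48 h by default, i.e. the peak day and the previous
#' calendar day: fecal timestamps are collection times, so matching is at
#' day resolution) for the same animal.
#'
#' @param events list of `stress_event`s from [classify_stress_events()].
#' @param notes data frame as returned by [read_notes()] (needs
#'   `animal_id`, `date`, `category`, `text`).
#' @param window_hours matching window; day resolution, so 48 h spans the
#'   peak day plus one preceding day.
#' @return The events, each with `matched_notes` filled in (possibly an
#'   empty data frame).
#' @export
match_notes <- function(events, notes, window_hours = 48) {
  days_back <- max(1L, as.integer(window_hours / 24)) - 1L
  if (!is.null(notes) && nrow(notes) && is.null(notes$date)) {
    notes$date <- as.Date(substr(notes$timestamp, 1, 10))
  }
  lapply(events, function(ev) {
    if (is.null(notes) || !nrow(notes)) {
      ev$matched_notes <- notes_skeleton()
      return(ev)
    }
    window_days <- unique(as.Date(unlist(
      lapply(ev$dates, function(d) d - 0:days_back))))
    hit <- notes$animal_id == ev$animal_id & notes$date %in% window_days
    ev$matched_notes <- notes[hit, , drop = FALSE]
    ev
  })
}

notes_skeleton <- function() {
  data.frame(animal_id = character(), timestamp = character(),
             category = character(), text = character(),
             date = as.Date(character()))
}

#' Analyse a full study: all animals, both metabolites
#'
#' Builds both hormone series per animal, detects peaks, classifies
#' dual-metabolite stress events, matches notes, and assembles the
#' per-animal summary table.
#'
#' @param series data frame with columns `animal_id, date, assay,
#'   conc_ng_g` (assay values `"cortisol"`/`"corticosterone"`).
#' @param notes optional data frame as from [read_notes()].
#' @param config an [fgm_config()].
#' @return List with `series` (named per-animal lists of
#'   [hormone_series()]), `events` (flat list of matched `stress_event`s),
#'   `per_animal` (summary table: baselines, peak counts, dual-peak and
#'   noted-dual-peak counts) and `totals` (see [study_totals()]).
#' @export
analyze_study <- function(series, notes = NULL, config = fgm_config()) {
  need <- c("animal_id", "date", "assay", "conc_ng_g")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  series$date <- as.Date(series$date)
  animals <- sort(unique(series$animal_id))
  all_series <- list()
  all_events <- list()
  rows <- list()

  for (an in animals) {
    sa <- series[series$animal_id == an, ]
    hs <- list()
    for (assay in c("cortisol", "corticosterone")) {
      sx <- sa[sa$assay == assay, ]
      if (nrow(sx)) {
        hs[[assay]] <- hormone_series(an, assay, sx$date, sx$conc_ng_g,
                                      config = config)
      }
    }
    all_series[[an]] <- hs
    events <- if (!is.null(hs$cortisol) && !is.null(hs$corticosterone)) {
      classify_stress_events(hs$cortisol, hs$corticosterone, config)
    } else {
      list()
    }
    events <- match_notes(events, notes,
                          window_hours = config$note_window_hours)
    all_events <- c(all_events, events)

    dual_dates <- as.Date(unlist(lapply(events, `[[`, "dates")))
    noted_dates <- as.Date(unlist(lapply(events, function(ev) {
      if (!NROW(ev$matched_notes)) return(NULL)
      # a dual-peak date counts as noted if a note falls in ITS window
      days_back <- max(1L, as.integer(config$note_window_hours / 24)) - 1L
      keep <- vapply(ev$dates, function(d) {
        any(ev$matched_notes$date %in% (d - 0:days_back))
      }, logical(1))
      ev$dates[keep]
    })))
    rows[[an]] <- data.frame(
      animal_id = an,
      n_samples = length(unique(sa$date)),
      cortisol_baseline = if (is.null(hs$cortisol)) NA_real_
        else hs$cortisol$baseline,
      corticosterone_baseline = if (is.null(hs$corticosterone)) NA_real_
        else hs$corticosterone$baseline,
      cortisol_peaks = if (is.null(hs$cortisol)) NA_integer_
        else length(detect_peaks(hs$cortisol)),
      corticosterone_peaks = if (is.null(hs$corticosterone)) NA_integer_
        else length(detect_peaks(hs$corticosterone)),
      dual_peaks = length(dual_dates),
      noted_dual_peaks = length(noted_dates),
      n_events = length(events),
      n_acute = sum(vapply(events, function(e) e$kind == "acute",
                           logical(1))),
      n_chronic = sum(vapply(events, function(e) e$kind == "chronic",
                             logical(1)))
    )
  }
  per_animal <- do.call(rbind, rows)
  rownames(per_animal) <- NULL
  list(series = all_series, events = all_events, per_animal = per_animal,
       totals = study_totals(per_animal))
}

#' Study-level totals from a per-animal summary table
#'
#' Column sums of the per-animal table: total samples analysed, total
#' dual-metabolite peak dates, how many of those had an associated note,
#' and the note-association percentage.
#'
#' @param per_animal data frame with columns `n_samples`, `dual_peaks`,
#'   `noted_dual_peaks` (one row per animal).
#' @return List with `total_samples`, `total_dual_peaks`,
#'   `total_noted_dual_peaks`, `percent_noted`.
#' @examples
#' tab <- data.frame(n_samples = c(233, 122, 72, 60),
#'                   dual_peaks = c(11, 0, 5, 7),
#'                   noted_dual_peaks = c(1, 0, 1, 7))
#' study_totals(tab)  # 487 samples, 23 dual peaks, 9 noted, 39%
#' @export
study_totals <- function(per_animal) {
  need <- c("n_samples", "dual_peaks", "noted_dual_peaks")
  if (!all(need %in% names(per_animal))) {
    stop("per-animal table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dual <- sum(per_animal$dual_peaks)
  noted <- sum(per_animal$noted_dual_peaks)
  list(
    total_samples = sum(per_animal$n_samples),
    total_dual_peaks = dual,
    total_noted_dual_peaks = noted,
    percent_noted = if (dual > 0) 100 * noted / dual else NA_real_
  )
}
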