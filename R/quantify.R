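#' @title Quantification to ng per g dry feces
#' @name quantify
#' @description Turns plate responses into final fecal concentrations:
#'   duplicate-mean percent bound is back-calculated through the plate's
#'   standard curve to an extract concentration, multiplied by the working
#'   dilution, and converted through the extraction ratio (solvent volume
#'   over dry mass) to ng per g dry feces. Samples under the curve are
#'   imputed at half the lowest standard; samples over it are flagged for
#'   re-dilution; under-mass extractions are discarded.
NULL

QC_FLAGS <- c("DUP_CV_FAIL", "RERUN", "ABOVE_CURVE", "BLD_IMPUTED",
              "MASS_DISCARD")

#' Convert an extract concentration to dry-feces units
#'
#' `extract_conc * dilution * volume / mass`: linear in the extract
#' concentration and the dilution, inverse-linear in the dry mass.
#'
#' @param extract_conc concentration in the assayed extract, ng/mL.
#' @param dilution working dilution factor applied before the assay
#'   (e.g. 10 for a 1:10 dilution).
#' @param volume extraction solvent volume in mL.
#' @param mass dry fecal mass extracted, g.
#' @return Concentration in ng per g dry feces.
#' @examples
#' to_fecal_concentration(1, dilution = 10, volume = 2, mass = 0.2)  # 100
#' @export
to_fecal_concentration <- function(extract_conc, dilution, volume, mass) {
  if (any(!is.finite(extract_conc)) || any(extract_conc < 0)) {
    stop("extract_conc must be finite and >= 0", call. = FALSE)
  }
  if (any(dilution <= 0) || any(volume <= 0) || any(mass <= 0)) {
    stop("dilution, volume and mass must all be > 0", call. = FALSE)
  }
  extract_conc * dilution * volume / mass
}

#' Below-detection imputation constant
#'
#' Samples whose response falls under the standard curve are assigned the
#' midpoint between zero and the assay's lowest standard, converted to
#' dry-feces units through the extraction ratio: with the defaults,
#' `0.5 * 0.156 ng/mL * (2 mL / 0.2 g) = 0.78` ng/g for cortisol and
#' `0.5 * 0.032 * 10 = 0.16` ng/g for corticosterone. The working dilution
#' is not applied unless `bld_include_dilution` is set in the
#' configuration (see [fgm_config()]).
#'
#' @param assay `"cortisol"` or `"corticosterone"` (or any assay configured
#'   in `config`).
#' @param config an [fgm_config()].
#' @return The imputed concentration in ng per g dry feces.
#' @examples
#' impute_bld("cortisol")        # 0.78
#' impute_bld("corticosterone")  # 0.16
#' @export
impute_bld <- function(assay, config = fgm_config()) {
  a <- config$assays[[assay]]
  if (is.null(a)) {
    stop("unknown assay '", assay, "'; configured assays: ",
         paste(names(config$assays), collapse = ", "), call. = FALSE)
  }
  dil <- if (isTRUE(config$bld_include_dilution)) a$dilution else 1
  # single final division keeps the conventional constants exact
  0.5 * a$min_standard_pg_ml * dil * config$extract_volume_ml /
    (1000 * config$target_mass_g)
}

#' Read extraction records
#'
#' @param path CSV with columns `sample_id, animal_id, collection_datetime`
#'   (ISO 8601), `dry_mass_g, solvent_volume_ml`.
#' @return Data frame with a `date` column parsed from the timestamp.
#' @export
read_extractions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal_id", "collection_datetime", "dry_mass_g",
            "solvent_volume_ml")
  if (!all(need %in% names(x))) {
    stop("extractions file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$dry_mass_g)) || any(x$dry_mass_g <= 0)) {
    stop("dry_mass_g must be finite and > 0", call. = FALSE)
  }
  x$date <- as.Date(substr(x$collection_datetime, 1, 10))
  x
}

#' Plate-level quality control
#'
#' Applies the duplicate-CV cascade: every duplicate pair must agree to a
#' CV under 10%; a failing standard set forces a plate re-run; so does a
#' plate where more than half the sample duplicates fail. The intra-assay
#' CV is summarised as the mean sample-duplicate CV on the plate. The
#' inter-assay CV (CV of a pooled control across plates, see
#' [inter_assay_cv()]) is reported when control values are supplied and
#' `NA` otherwise.
#'
#' @param plate a [plate_record()].
#' @param config an [fgm_config()].
#' @param control_values optional vector of the designated control sample's
#'   measured concentrations across plates.
#' @return A list of class `qc_report`: `plate_id`, `duplicates` (per-pair
#'   table), `n_sample_fail`, `frac_sample_fail`, `standards_cv_fail`,
#'   `plate_rerun_required`, `intra_assay_cv`, `intra_pass`,
#'   `inter_assay_cv`, `inter_pass`.
#' @export
apply_qc <- function(plate, config = fgm_config(), control_values = NULL) {
  stopifnot(inherits(plate, "plate_record"))
  dup <- plate_duplicates(plate, cv_max = config$duplicate_cv_max)
  smp <- dup[dup$role == "SAMPLE", , drop = FALSE]
  std <- dup[dup$role == "STANDARD", , drop = FALSE]

  n_fail <- sum(!smp$pass)
  frac_fail <- if (nrow(smp)) n_fail / nrow(smp) else 0
  standards_fail <- any(!std$pass)
  rerun <- standards_fail || frac_fail > config$plate_fail_fraction

  intra <- if (nrow(smp)) mean(smp$cv_percent) else NA_real_
  inter <- if (is.null(control_values)) NA_real_ else
    inter_assay_cv(control_values)

  structure(list(
    plate_id = plate$plate_id,
    duplicates = dup,
    n_sample_fail = n_fail,
    frac_sample_fail = frac_fail,
    standards_cv_fail = standards_fail,
    plate_rerun_required = rerun,
    intra_assay_cv = intra,
    intra_pass = is.na(intra) || intra < config$intra_cv_max,
    inter_assay_cv = inter,
    inter_pass = if (is.na(inter)) NA else inter < config$inter_cv_max
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> plate %s: %d/%d sample duplicate failures%s%s\n",
              x$plate_id, x$n_sample_fail,
              sum(x$duplicates$role == "SAMPLE"),
              if (x$standards_cv_fail) ", standards FAILED" else "",
              if (x$plate_rerun_required) " -> RE-RUN PLATE" else ""))
  cat(sprintf("  intra-assay CV %.2f%%, inter-assay CV %s\n",
              x$intra_assay_cv,
              if (is.na(x$inter_assay_cv)) "unavailable"
              else sprintf("%.2f%%", x$inter_assay_cv)))
  invisible(x)
}

#' Inter-assay coefficient of variation
#'
#' CV (`100 * sd / mean`, sample SD) of a designated pooled-control
#' sample's concentration measured across plates.
#'
#' @param control_values the control's measured values, one per plate.
#' @return CV in percent; `NA` with fewer than two values.
#' @export
inter_assay_cv <- function(control_values) {
  v <- control_values[is.finite(control_values)]
  if (length(v) < 2L) return(NA_real_)
  100 * stats::sd(v) / mean(v)
}

#' Quantify every sample on a plate
#'
#' For each sample: duplicate-mean OD, percent bound against the plate's
#' NSB/B0 means, back-calculation through the standard curve, conversion to
#' ng/g dry feces using the sample's extraction record. QC flags:
#' `DUP_CV_FAIL`+`RERUN` when duplicates disagree, `BLD_IMPUTED` (with the
#' assay's imputation constant) when the response or back-calculated dose
#' falls under the curve, `ABOVE_CURVE`+`RERUN` (no concentration) when it
#' exceeds the curve, `MASS_DISCARD` (no concentration) when the extracted
#' dry mass is under the minimum.
#'
#' @param plate a [plate_record()].
#' @param curve the plate's fitted [fit_4pl()] curve (in percent-bound
#'   response space).
#' @param extractions data frame from [read_extractions()].
#' @param config an [fgm_config()].
#' @return Data frame with one row per sample: `sample_id, animal_id, date,
#'   assay, plate_id, mean_od, percent_bound, duplicate_cv,
#'   extract_conc_ng_ml, dilution_factor, fecal_conc_ng_g, qc_flags`
#'   (semicolon-joined).
#' @export
quantify_plate <- function(plate, curve, extractions,
                           config = fgm_config()) {
  stopifnot(inherits(plate, "plate_record"),
            inherits(curve, "standard_curve"))
  dup <- plate_duplicates(plate, cv_max = config$duplicate_cv_max)
  nsb <- dup$mean_od[dup$role == "NSB"]
  b0 <- dup$mean_od[dup$role == "B0"]
  smp <- dup[dup$role == "SAMPLE", , drop = FALSE]
  if (!nrow(smp)) {
    return(empty_measurements())
  }
  if (is.null(extractions$date)) {
    extractions$date <- as.Date(substr(extractions$collection_datetime,
                                       1, 10))
  }
  missing_ext <- setdiff(smp$sample_id, extractions$sample_id)
  if (length(missing_ext)) {
    stop("no extraction record for sample(s): ",
         paste(missing_ext, collapse = ", "), call. = FALSE)
  }
  ext <- extractions[match(smp$sample_id, extractions$sample_id), ]
  default_dil <- config$assays[[plate$assay]]$dilution
  dil <- ifelse(is.na(smp$dilution), default_dil, smp$dilution)
  pb <- percent_bound(smp$mean_od, nsb, b0)

  out <- data.frame(
    sample_id = smp$sample_id,
    animal_id = ext$animal_id,
    date = ext$date,
    assay = plate$assay,
    plate_id = plate$plate_id,
    mean_od = smp$mean_od,
    percent_bound = pb,
    duplicate_cv = smp$cv_percent,
    extract_conc_ng_ml = NA_real_,
    dilution_factor = dil,
    fecal_conc_ng_g = NA_real_,
    qc_flags = "",
    stringsAsFactors = FALSE
  )
  bld_value <- impute_bld(plate$assay, config)

  for (i in seq_len(nrow(out))) {
    flags <- character()
    if (!smp$pass[i]) flags <- c(flags, "DUP_CV_FAIL", "RERUN")
    if (ext$dry_mass_g[i] < config$min_mass_g) {
      out$qc_flags[i] <- flag_string(c(flags, "MASS_DISCARD"))
      next
    }
    status <- curve_status(pb[i], curve)
    conc_pg <- NA_real_
    if (status == "ok") {
      conc_pg <- inverse_4pl(pb[i], curve)
      if (conc_pg < curve$range_low) status <- "below_curve"
      if (conc_pg > curve$range_high) status <- "above_curve"
    }
    if (status == "below_curve") {
      out$fecal_conc_ng_g[i] <- bld_value
      flags <- c(flags, "BLD_IMPUTED")
    } else if (status == "above_curve") {
      flags <- c(flags, "ABOVE_CURVE", "RERUN")
    } else {
      out$extract_conc_ng_ml[i] <- conc_pg / 1000
      out$fecal_conc_ng_g[i] <- to_fecal_concentration(
        conc_pg / 1000, dil[i], ext$solvent_volume_ml[i], ext$dry_mass_g[i])
    }
    out$qc_flags[i] <- flag_string(flags)
  }
  out
}

flag_string <- function(flags) paste(unique(flags), collapse = ";")

has_flag <- function(qc_flags, flag) {
  vapply(strsplit(qc_flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

empty_measurements <- function() {
  data.frame(sample_id = character(), animal_id = character(),
             date = as.Date(character()), assay = character(),
             plate_id = character(), mean_od = numeric(),
             percent_bound = numeric(), duplicate_cv = numeric(),
             extract_conc_ng_ml = numeric(), dilution_factor = numeric(),
             fecal_conc_ng_g = numeric(), qc_flags = character(),
             stringsAsFactors = FALSE)
}

#' Resolve re-runs: latest passing measurement wins
#'
#' When a sample was re-run (after a duplicate failure or an over-curve
#' flag), the latest measurement per sample and assay that carries no
#' disqualifying flag supersedes earlier ones. The full audit trail is
#' retained: superseded and disqualified rows are marked, not dropped.
#'
#' @param measurements row-bound output of [quantify_plate()] in run order.
#' @return The same table with a logical `superseded` column; the rows with
#'   `superseded == FALSE` and a usable `fecal_conc_ng_g` form the working
#'   data set.
#' @export
supersede_measurements <- function(measurements) {
  m <- measurements
  m$superseded <- FALSE
  bad <- has_flag(m$qc_flags, "DUP_CV_FAIL") |
    has_flag(m$qc_flags, "ABOVE_CURVE") |
    has_flag(m$qc_flags, "MASS_DISCARD")
  key <- paste(m$sample_id, m$assay, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ok <- idx[!bad[idx]]
    winner <- if (length(ok)) ok[length(ok)] else idx[length(idx)]
    m$superseded[setdiff(idx, winner)] <- TRUE
  }
  m
}

#' Collapse measurements to an analysis-ready series table
#'
#' Keeps non-superseded rows with a usable concentration (flagged
#' `ABOVE_CURVE` and `MASS_DISCARD` rows carry none and drop out).
#'
#' @param measurements output of [quantify_plate()] /
#'   [supersede_measurements()].
#' @return Data frame `animal_id, date, assay, conc_ng_g, qc_flags`.
#' @export
measurements_to_series <- function(measurements) {
  m <- measurements
  if (is.null(m$superseded)) m <- supersede_measurements(m)
  keep <- !m$superseded & is.finite(m$fecal_conc_ng_g)
  out <- m[keep, c("animal_id", "date", "assay", "fecal_conc_ng_g",
                   "qc_flags")]
  names(out)[names(out) == "fecal_conc_ng_g"] <- "conc_ng_g"
  rownames(out) <- NULL
  out
}
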