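#' @title EIA plate model and input/output
#' @name plate-model
#' @description A 96-well competitive EIA plate is represented as a
#'   `plate_record`: a plate identifier, the assay it was run for, and a
#'   table of wells. Every control role (non-specific binding NSB, total
#'   activity TA, maximum binding B0, zero-standard blank), every standard
#'   concentration and every sample is present in duplicate wells.
NULL

WELL_ROLES <- c("NSB", "TA", "B0", "BLANK", "STANDARD", "SAMPLE")
DUPLICATE_ROLES <- c("NSB", "TA", "B0", "BLANK")
N_STANDARDS <- c(cortisol = 7L, corticosterone = 5L)

well_positions <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Construct a validated plate record
#'
#' @param plate_id single plate identifier.
#' @param assay `"cortisol"` or `"corticosterone"`; if `NULL`, inferred from
#'   the number of standard pairs (7 for cortisol, 5 for corticosterone).
#' @param wells data frame with columns `well` (A1..H12), `role` (one of
#'   NSB, TA, B0, BLANK, STANDARD, SAMPLE), `standard_conc_pg_ml` (set iff
#'   role is STANDARD), `sample_id` and `dilution` (set iff role is SAMPLE),
#'   and `od` (optical density at the read wavelength, >= 0).
#' @param read_wavelength read wavelength in nm (kit protocol reads 405 nm).
#'
#' @return An object of class `plate_record`.
#' @export
plate_record <- function(plate_id, wells, assay = NULL, read_wavelength = 405) {
  stopifnot(is.data.frame(wells))
  required <- c("well", "role", "standard_conc_pg_ml", "sample_id",
                "dilution", "od")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("wells table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells <- wells[required]
  wells$role <- toupper(as.character(wells$role))

  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role)) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  bad_pos <- setdiff(wells$well, well_positions())
  if (length(bad_pos)) {
    stop("invalid well position(s): ", paste(bad_pos, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(wells$well)) {
    stop("duplicated well position(s) on plate ", plate_id, call. = FALSE)
  }
  if (any(!is.finite(wells$od)) || any(wells$od < 0)) {
    stop("optical densities must be finite and >= 0", call. = FALSE)
  }

  # control roles in duplicate
  for (r in DUPLICATE_ROLES) {
    n <- sum(wells$role == r)
    if (n != 2L) {
      stop("duplicate required: role ", r, " appears ", n,
           " time(s), expected 2", call. = FALSE)
    }
  }
  # standards: positive concentration, each level in duplicate
  std <- wells[wells$role == "STANDARD", ]
  if (any(is.na(std$standard_conc_pg_ml)) ||
      any(std$standard_conc_pg_ml <= 0)) {
    stop("every STANDARD well needs a positive standard_conc_pg_ml",
         call. = FALSE)
  }
  std_counts <- table(std$standard_conc_pg_ml)
  if (any(std_counts != 2L)) {
    stop("duplicate required: each standard concentration must appear in ",
         "exactly 2 wells", call. = FALSE)
  }
  n_std <- length(std_counts)
  if (is.null(assay)) {
    hit <- names(N_STANDARDS)[N_STANDARDS == n_std]
    if (length(hit) != 1L) {
      stop("cannot infer assay from ", n_std,
           " standard levels; pass assay= explicitly", call. = FALSE)
    }
    assay <- hit
  }
  assay <- match.arg(assay, names(N_STANDARDS))
  if (n_std != N_STANDARDS[[assay]]) {
    stop(assay, " plates carry ", N_STANDARDS[[assay]],
         " standards, found ", n_std, call. = FALSE)
  }
  # samples in duplicate
  smp <- wells[wells$role == "SAMPLE", ]
  if (nrow(smp)) {
    if (any(is.na(smp$sample_id)) || any(smp$sample_id == "")) {
      stop("every SAMPLE well needs a sample_id", call. = FALSE)
    }
    smp_counts <- table(smp$sample_id)
    if (any(smp_counts != 2L)) {
      bad <- names(smp_counts)[smp_counts != 2L]
      stop("duplicate required: sample(s) ", paste(bad, collapse = ", "),
           " not present in exactly 2 wells", call. = FALSE)
    }
    dil <- tapply(smp$dilution, smp$sample_id, function(d) length(unique(d)))
    if (any(dil != 1L)) {
      stop("sample duplicates must share one dilution", call. = FALSE)
    }
  }

  structure(
    list(plate_id = as.character(plate_id), assay = assay,
         wells = wells, read_wavelength = read_wavelength),
    class = "plate_record"
  )
}

#' @export
print.plate_record <- function(x, ...) {
  n_smp <- length(unique(x$wells$sample_id[x$wells$role == "SAMPLE"]))
  cat(sprintf("<plate_record> %s (%s assay), %d wells, %d samples, read at %g nm\n",
              x$plate_id, x$assay, nrow(x$wells), n_smp, x$read_wavelength))
  invisible(x)
}

#' Read a plate from layout and optical-density CSV exports
#'
#' The layout file maps well positions to roles and identifiers; the OD file
#' carries one optical density per well. Both are UTF-8 comma-separated with
#' a header row and well positions A1..H12.
#'
#' @param layout_path CSV with columns `plate_id, well, role,
#'   standard_conc_pg_ml, sample_id, dilution`.
#' @param od_path CSV with columns `plate_id, well, od`.
#' @param plate_id plate to read; default the single plate present (an error
#'   if the files hold several).
#' @param assay passed to [plate_record()]; inferred when `NULL`.
#' @return A validated [plate_record()].
#' @export
read_plate <- function(layout_path, od_path, plate_id = NULL, assay = NULL) {
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  od <- utils::read.csv(od_path, stringsAsFactors = FALSE)
  plates_from_tables(layout, od, plate_id = plate_id, assay = assay,
                     single = TRUE)
}

# Build one or all plate_records from in-memory layout/OD tables.
plates_from_tables <- function(layout, od, plate_id = NULL, assay = NULL,
                               single = FALSE) {
  need_l <- c("plate_id", "well", "role")
  if (!all(need_l %in% names(layout))) {
    stop("layout error: columns plate_id, well, role are required",
         call. = FALSE)
  }
  for (col in c("standard_conc_pg_ml", "sample_id", "dilution")) {
    if (is.null(layout[[col]])) layout[[col]] <- NA
  }
  if (!all(c("plate_id", "well", "od") %in% names(od))) {
    stop("OD error: columns plate_id, well, od are required", call. = FALSE)
  }
  ids <- if (is.null(plate_id)) unique(layout$plate_id) else plate_id
  if (single && length(ids) != 1L) {
    stop("files contain ", length(ids),
         " plates; pass plate_id to pick one", call. = FALSE)
  }
  build_one <- function(pid) {
    lay <- layout[layout$plate_id == pid, , drop = FALSE]
    odi <- od[od$plate_id == pid, , drop = FALSE]
    if (!nrow(lay)) stop("layout error: no wells for plate ", pid,
                         call. = FALSE)
    unmapped <- setdiff(odi$well, lay$well)
    if (length(unmapped)) {
      stop("layout error: OD given for unmapped well(s) ",
           paste(unmapped, collapse = ", "), " on plate ", pid,
           call. = FALSE)
    }
    no_od <- setdiff(lay$well, odi$well)
    if (length(no_od)) {
      stop("data error: no OD for well(s) ", paste(no_od, collapse = ", "),
           " on plate ", pid, call. = FALSE)
    }
    lay$od <- odi$od[match(lay$well, odi$well)]
    if (any(!is.finite(lay$od)) || any(lay$od < 0)) {
      stop("data error: negative or missing OD on plate ", pid,
           call. = FALSE)
    }
    plate_record(pid, lay[c("well", "role", "standard_conc_pg_ml",
                            "sample_id", "dilution", "od")], assay = assay)
  }
  if (single) build_one(ids) else lapply(stats::setNames(ids, ids), build_one)
}

#' Write a plate back to the layout/OD CSV dialect
#'
#' Emits the same dialect [read_plate()] consumes, so that a read/write
#' round trip is the identity on the files.
#'
#' @param plate a [plate_record()].
#' @param layout_path,od_path output CSV paths.
#' @return Invisibly, the plate.
#' @export
write_plate <- function(plate, layout_path, od_path) {
  stopifnot(inherits(plate, "plate_record"))
  w <- plate$wells
  layout <- data.frame(plate_id = plate$plate_id, well = w$well,
                       role = w$role,
                       standard_conc_pg_ml = w$standard_conc_pg_ml,
                       sample_id = w$sample_id, dilution = w$dilution)
  od <- data.frame(plate_id = plate$plate_id, well = w$well, od = w$od)
  utils::write.csv(layout, layout_path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(od, od_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(plate)
}

#' Percent antibody bound
#'
#' Background-corrected response of a competitive EIA well relative to
#' maximum binding: `100 * (od - nsb) / (b0 - nsb)`. Equals 100 at the
#' maximum-binding (B0) OD and 0 at the non-specific-binding (NSB) OD.
#'
#' @param od optical density (or vector of ODs) to transform.
#' @param nsb_mean mean OD of the NSB duplicate wells.
#' @param b0_mean mean OD of the B0 duplicate wells; must exceed `nsb_mean`.
#' @return Percent bound (%B/B0), same length as `od`.
#' @examples
#' percent_bound(0.55, nsb_mean = 0.05, b0_mean = 1.05)  # 50
#' @export
percent_bound <- function(od, nsb_mean, b0_mean) {
  if (!is.finite(nsb_mean) || !is.finite(b0_mean) || b0_mean <= nsb_mean) {
    stop("plate failure: maximum binding (B0) not above background (NSB)",
         call. = FALSE)
  }
  100 * (od - nsb_mean) / (b0_mean - nsb_mean)
}

#' Duplicate-well coefficient of variation
#'
#' CV between a duplicate pair of ODs, `100 * sd / mean` with the sample SD
#' (n-1 denominator), and the pass flag at the strict <10% acceptance rule
#' (threshold configurable).
#'
#' @param od1,od2 the two duplicate optical densities (>= 0).
#' @param cv_max acceptance threshold in percent; strict `<` comparison.
#' @return A list of class `duplicate_pair` with `mean_od`, `cv_percent`
#'   and `pass`.
#' @examples
#' duplicate_cv(0.9, 1.1)   # CV 14.1%, fail
#' duplicate_cv(0.95, 1.05) # CV 7.1%, pass
#' @export
duplicate_cv <- function(od1, od2, cv_max = 10) {
  if (!is.finite(od1) || !is.finite(od2) || od1 < 0 || od2 < 0) {
    stop("duplicate ODs must be finite and >= 0", call. = FALSE)
  }
  m <- mean(c(od1, od2))
  if (m == 0) stop("undefined CV: duplicate mean is zero", call. = FALSE)
  cv <- 100 * stats::sd(c(od1, od2)) / m
  structure(list(mean_od = m, cv_percent = cv, pass = cv < cv_max),
            class = "duplicate_pair")
}

# Duplicate-mean OD and CV for every control role, standard level and sample
# on a plate; one row per duplicate pair.
plate_duplicates <- function(plate, cv_max = 10) {
  w <- plate$wells
  key <- ifelse(w$role == "STANDARD",
                paste0("STD:", w$standard_conc_pg_ml),
                ifelse(w$role == "SAMPLE", paste0("SMP:", w$sample_id),
                       w$role))
  groups <- split(seq_len(nrow(w)), key)
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    dp <- duplicate_cv(w$od[idx[1]], w$od[idx[2]], cv_max = cv_max)
    data.frame(key = k,
               role = w$role[idx[1]],
               standard_conc_pg_ml = w$standard_conc_pg_ml[idx[1]],
               sample_id = w$sample_id[idx[1]],
               dilution = w$dilution[idx[1]],
               mean_od = dp$mean_od, cv_percent = dp$cv_percent,
               pass = dp$pass)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
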