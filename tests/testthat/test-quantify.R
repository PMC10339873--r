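test_that("dry-feces conversion does the unit arithmetic", {
  expect_equal(to_fecal_concentration(1, 10, 2, 0.2), 100)
  expect_equal(to_fecal_concentration(1, 1, 2, 0.2), 10)
  expect_equal(to_fecal_concentration(0.5, 30, 2, 0.25), 120)
  expect_error(to_fecal_concentration(1, 10, 2, 0), "> 0")
})

test_that("conversion is linear in extract and dilution, inverse in mass", {
  set.seed(8)
  for (i in 1:30) {
    e <- runif(1, 0.1, 5); d <- runif(1, 1, 50)
    v <- runif(1, 1, 4); m <- runif(1, 0.1, 0.4); k <- runif(1, 0.5, 4)
    base <- to_fecal_concentration(e, d, v, m)
    expect_equal(to_fecal_concentration(k * e, d, v, m), k * base)
    expect_equal(to_fecal_concentration(e, k * d, v, m), k * base)
    expect_equal(to_fecal_concentration(e, d, v, k * m), base / k)
  }
})

test_that("below-detection imputation equals its closed form for both assays", {
  cfg <- fgm_config()
  expect_equal(impute_bld("cortisol", cfg), 0.78)
  expect_equal(impute_bld("corticosterone", cfg), 0.16)
  expect_equal(impute_bld("cortisol", cfg),
               0.5 * 0.156 * cfg$extract_volume_ml / cfg$target_mass_g)
  expect_error(impute_bld("aldosterone", cfg), "unknown assay")

  # hypothetical assay with a 100 pg/mL minimum standard
  cfg2 <- cfg
  cfg2$assays$hypothetical <- list(standards_pg_ml = 100 * 2^(0:6),
                                   min_standard_pg_ml = 100, dilution = 10)
  expect_equal(impute_bld("hypothetical", cfg2), 0.5)

  # the documented dilution-corrected alternative is switchable
  cfg3 <- fgm_config(bld_include_dilution = TRUE)
  expect_equal(impute_bld("cortisol", cfg3), 7.8)
})

test_that("plate QC applies the duplicate cascade and re-run rules", {
  set.seed(31)
  # exact duplicates: no failures, no re-run
  sp <- simulate_plate(stats::setNames(runif(10, 300, 3000),
                                       sprintf("S%02d", 1:10)),
                       noise_cv = 0)
  qc <- apply_qc(sp$plate)
  expect_equal(qc$n_sample_fail, 0)
  expect_false(qc$plate_rerun_required)
  expect_equal(qc$intra_assay_cv, 0)
  expect_true(is.na(qc$inter_assay_cv))

  # 6 of 10 sample duplicates failing forces a plate re-run
  break_samples <- function(plate, ids) {
    w <- plate$wells
    for (id in ids) {
      idx <- which(w$role == "SAMPLE" & w$sample_id == id)
      w$od[idx[1]] <- w$od[idx[2]] * 1.3   # CV 13%
    }
    plate_record(plate$plate_id, w, assay = plate$assay)
  }
  p6 <- break_samples(sp$plate, sprintf("S%02d", 1:6))
  qc6 <- apply_qc(p6)
  expect_equal(qc6$n_sample_fail, 6)
  expect_true(qc6$plate_rerun_required)
  expect_false(qc6$standards_cv_fail)

  # a failing standard set forces a re-run regardless of samples
  w <- sp$plate$wells
  std_idx <- which(w$role == "STANDARD")[1:2]
  w$od[std_idx[1]] <- w$od[std_idx[2]] * 1.3
  qs <- apply_qc(plate_record(sp$plate$plate_id, w, assay = "cortisol"))
  expect_true(qs$standards_cv_fail)
  expect_true(qs$plate_rerun_required)

  # monotonicity: breaking one more duplicate never rescues a re-run plate
  prev_rerun <- FALSE
  for (k in 1:10) {
    pk <- break_samples(sp$plate, sprintf("S%02d", seq_len(k)))
    now <- apply_qc(pk)$plate_rerun_required
    expect_false(prev_rerun && !now)
    prev_rerun <- now
  }
})

test_that("inter-assay CV summarises a control across plates", {
  expect_equal(inter_assay_cv(c(10, 12)),
               100 * sd(c(10, 12)) / 11)
  expect_true(is.na(inter_assay_cv(7)))
})

test_that("quantification recovers truth and routes QC paths", {
  concs <- c(S1 = 400, S2 = 1200, S3 = 15.6, S4 = 50000)
  sp <- simulate_plate(concs, noise_cv = 0)
  dup <- fgmassay:::plate_duplicates(sp$plate)
  std <- dup[dup$role == "STANDARD", ]
  curve <- fit_4pl(std$standard_conc_pg_ml,
                   percent_bound(std$mean_od,
                                 dup$mean_od[dup$role == "NSB"],
                                 dup$mean_od[dup$role == "B0"]))
  ext <- extractions_for(names(concs))
  ext$dry_mass_g[ext$sample_id == "S2"] <- 0.15  # under the 0.18 g floor
  m <- quantify_plate(sp$plate, curve, ext)

  # zero noise: mid-curve sample recovered exactly
  # (1:10 dilution, 2 mL / 0.2 g: ng/g = pg/mL / 10)
  expect_equal(m$fecal_conc_ng_g[m$sample_id == "S1"], 40,
               tolerance = 1e-6)
  # sample at 0.1x the lowest standard is imputed at the BLD constant
  expect_equal(m$fecal_conc_ng_g[m$sample_id == "S3"], 0.78)
  expect_true(fgmassay:::has_flag(m$qc_flags[m$sample_id == "S3"],
                                  "BLD_IMPUTED"))
  # sample over the top standard carries no concentration
  expect_true(is.na(m$fecal_conc_ng_g[m$sample_id == "S4"]))
  expect_true(fgmassay:::has_flag(m$qc_flags[m$sample_id == "S4"],
                                  "ABOVE_CURVE"))
  # under-mass extraction is discarded
  expect_true(is.na(m$fecal_conc_ng_g[m$sample_id == "S2"]))
  expect_true(fgmassay:::has_flag(m$qc_flags[m$sample_id == "S2"],
                                  "MASS_DISCARD"))

  expect_error(quantify_plate(sp$plate, curve, ext[-1, ]),
               "no extraction record.*S1")
})

test_that("moderate plate noise keeps mid-curve recovery within 10%", {
  set.seed(14)
  errs <- c()
  for (r in 1:20) {
    concs <- stats::setNames(exp(runif(10, log(300), log(3000))),
                             sprintf("S%02d", 1:10))
    sp <- simulate_plate(concs, noise_cv = 0.05)
    dup <- fgmassay:::plate_duplicates(sp$plate)
    std <- dup[dup$role == "STANDARD", ]
    curve <- fit_4pl(std$standard_conc_pg_ml,
                     percent_bound(std$mean_od,
                                   dup$mean_od[dup$role == "NSB"],
                                   dup$mean_od[dup$role == "B0"]))
    m <- quantify_plate(sp$plate, curve, extractions_for(names(concs)))
    truth_ng_g <- concs[m$sample_id] / 10
    ok <- !is.na(m$fecal_conc_ng_g) &
      !fgmassay:::has_flag(m$qc_flags, "BLD_IMPUTED")
    errs <- c(errs, abs(m$fecal_conc_ng_g[ok] / truth_ng_g[ok] - 1))
  }
  expect_lt(median(errs), 0.10)
})

test_that("re-runs supersede earlier flagged measurements, audit retained", {
  m <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    animal_id = "M1", date = as.Date("2010-06-01"),
    assay = "cortisol", plate_id = c("P1", "P2", "P1"),
    mean_od = 0.5, percent_bound = 50, duplicate_cv = c(12, 2, 3),
    extract_conc_ng_ml = c(NA, 0.4, 0.5), dilution_factor = 10,
    fecal_conc_ng_g = c(NA, 40, 50),
    qc_flags = c("DUP_CV_FAIL;RERUN", "", ""))
  s <- supersede_measurements(m)
  expect_identical(s$superseded, c(TRUE, FALSE, FALSE))
  ser <- measurements_to_series(s)
  expect_equal(nrow(ser), 2)
  expect_equal(ser$conc_ng_g, c(40, 50))
})
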