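test_that("trimmed baseline matches hand-worked cases", {
  r <- compute_baseline(c(5, 5, 5))
  expect_equal(r$mean, 5); expect_equal(r$sd, 0)
  expect_equal(r$baseline, 5); expect_equal(r$n_trimmed, 0)

  r2 <- compute_baseline(c(1, 2, 3, 100))
  expect_equal(r2$mean, 26.5)
  expect_equal(r2$sd, sqrt(7205 / 3), tolerance = 1e-12)  # 49.0068
  expect_equal(r2$baseline, 2)
  expect_equal(r2$n_trimmed, 1)

  r3 <- compute_baseline(42)
  expect_equal(r3$baseline, 42)
  expect_true(is.na(r3$sd))

  expect_error(compute_baseline(numeric(0)), "empty")
})

test_that("baseline never exceeds the untrimmed mean", {
  set.seed(91)
  for (i in 1:500) {
    v <- rlnorm(sample(1:40, 1), meanlog = 3, sdlog = runif(1, 0.1, 1.5))
    r <- compute_baseline(v)
    expect_lte(r$baseline, r$mean)
  }
})

test_that("peaks are values strictly over mean + 2 SD of the full series", {
  mk <- function(v) hormone_series("A1", "cortisol",
                                   seq(as.Date("2015-01-01"), by = "day",
                                       length.out = length(v)), v)
  # one clear outlier: threshold 49.17 just under the 50
  s <- mk(c(1, 1, 1, 1, 1, 50))
  expect_equal(s$mean, 55 / 6, tolerance = 1e-6)
  expect_equal(s$sd, 20.00417, tolerance = 1e-5)
  expect_equal(length(detect_peaks(s)), 1)
  expect_equal(detect_peaks(s), as.Date("2015-01-06"))

  # constant series: SD 0, strict inequality, no peaks
  expect_equal(length(detect_peaks(mk(rep(7, 10)))), 0)

  # n = 4 caps the max z-score under 2: no peak however large the spike
  s4 <- mk(c(1, 2, 3, 200))
  expect_equal(s4$mean + 2 * s4$sd, 51.5 + 2 * sqrt(29405 / 3),
               tolerance = 1e-12)  # 249.51
  expect_equal(length(detect_peaks(s4)), 0)
})

test_that("series of five or fewer samples can never contain a peak", {
  # sample z-scores are bounded by (n-1)/sqrt(n) < 2 for n <= 5
  set.seed(92)
  for (i in 1:400) {
    n <- sample(2:5, 1)
    v <- rlnorm(n, 3, runif(1, 0.2, 2)) * sample(c(1, 1, 1, 100), n,
                                                 replace = TRUE)
    s <- hormone_series("A1", "cortisol",
                        seq(as.Date("2015-01-01"), by = "week",
                            length.out = n), v)
    expect_equal(length(detect_peaks(s)), 0)
  }
})

test_that("multiple samples on one day are averaged before detection", {
  s <- hormone_series("A1", "cortisol",
                      as.Date(c("2015-01-01", "2015-01-01", "2015-01-02")),
                      c(10, 20, 12))
  expect_equal(nrow(s$daily), 2)
  expect_equal(s$daily$conc_ng_g[1], 15)
  expect_equal(nrow(s$observations), 3)
})

test_that("stress events require both metabolites and group consecutive days", {
  days <- seq(as.Date("2015-01-01"), by = "day", length.out = 20)
  mk <- function(assay, spike_at) {
    sp <- spiked_series(20, spike_at)
    hormone_series("A1", assay, sp$dates, sp$values)
  }
  # cortisol peaks d1 and d5, corticosterone only d5: one acute event at d5
  ev <- classify_stress_events(mk("cortisol", c(1, 5)),
                               mk("corticosterone", 5))
  expect_length(ev, 1)
  expect_identical(ev[[1]]$kind, "acute")
  expect_equal(ev[[1]]$dates, days[5])
  expect_equal(ev[[1]]$metabolite_values$cortisol_ng_g, 1000)

  # both peak on consecutive sampled days 3 and 4: one chronic event
  ev2 <- classify_stress_events(mk("cortisol", c(3, 4)),
                                mk("corticosterone", c(3, 4)))
  expect_length(ev2, 1)
  expect_identical(ev2[[1]]$kind, "chronic")
  expect_equal(ev2[[1]]$dates, days[3:4])

  # no common peak dates: no events
  expect_length(classify_stress_events(mk("cortisol", 2),
                                       mk("corticosterone", 9)), 0)

  # adjacent-in-sequence but far apart in time: two acute events
  far_dates <- c(as.Date("2015-01-01"),
                 seq(as.Date("2015-03-01"), by = "day", length.out = 19))
  mk_far <- function(assay) {
    v <- rep(10, 20); v[c(1, 2)] <- 1000
    hormone_series("A1", assay, far_dates, v)
  }
  ev3 <- classify_stress_events(mk_far("cortisol"), mk_far("corticosterone"))
  expect_length(ev3, 2)
  expect_true(all(vapply(ev3, function(e) e$kind, "") == "acute"))

  expect_error(classify_stress_events(
    mk("cortisol", 5),
    hormone_series("B9", "corticosterone", days, rep(10, 20))),
    "different animals")
})

test_that("every dual-peak date belongs to exactly one event", {
  set.seed(93)
  for (i in 1:30) {
    n <- 60
    dates <- sort(sample(seq(as.Date("2010-01-01"), by = "day",
                             length.out = 400), n))
    spikes <- sample(n, 6)
    v1 <- rlnorm(n, log(30), 0.3); v1[spikes] <- 400
    v2 <- rlnorm(n, log(60), 0.3); v2[spikes] <- 700
    c1 <- hormone_series("A1", "cortisol", dates, v1)
    c2 <- hormone_series("A1", "corticosterone", dates, v2)
    ev <- classify_stress_events(c1, c2)
    all_dates <- as.Date(unlist(lapply(ev, `[[`, "dates")))
    dual <- intersect(detect_peaks(c1), detect_peaks(c2))
    expect_equal(sort(unique(all_dates)), sort(as.Date(dual)))
    expect_equal(anyDuplicated(all_dates), 0)
    for (e in ev) {
      expect_identical(e$kind, if (length(e$dates) > 1) "chronic"
                       else "acute")
    }
  }
})

test_that("notes match on the peak day or the preceding day only", {
  days <- seq(as.Date("2015-01-01"), by = "day", length.out = 20)
  sp <- spiked_series(20, 10)
  c1 <- hormone_series("A1", "cortisol", sp$dates, sp$values)
  c2 <- hormone_series("A1", "corticosterone", sp$dates, sp$values * 2)
  ev <- classify_stress_events(c1, c2)
  expect_length(ev, 1)
  peak_day <- days[10]

  note_on <- function(day, animal = "A1") {
    data.frame(animal_id = animal,
               timestamp = format(day, "%Y-%m-%dT09:00:00"),
               category = "health", text = "checkup",
               date = day)
  }
  expect_equal(NROW(match_notes(ev, note_on(peak_day - 1))[[1]]$matched_notes), 1)
  expect_equal(NROW(match_notes(ev, note_on(peak_day))[[1]]$matched_notes), 1)
  expect_equal(NROW(match_notes(ev, note_on(peak_day - 3))[[1]]$matched_notes), 0)
  expect_equal(NROW(match_notes(ev, note_on(peak_day + 1))[[1]]$matched_notes), 0)
  # other animal's note never matches
  expect_equal(NROW(match_notes(ev, note_on(peak_day, "B2"))[[1]]$matched_notes), 0)
  # empty note log: events stay unannotated
  expect_equal(NROW(match_notes(ev, NULL)[[1]]$matched_notes), 0)
})

test_that("study totals reproduce the published per-animal count arithmetic", {
  tab <- data.frame(n_samples = c(233, 122, 72, 60),
                    dual_peaks = c(11, 0, 5, 7),
                    noted_dual_peaks = c(1, 0, 1, 7))
  tot <- study_totals(tab)
  expect_equal(tot$total_samples, 487)
  expect_equal(tot$total_dual_peaks, 23)
  expect_equal(tot$total_noted_dual_peaks, 9)
  expect_equal(round(tot$percent_noted), 39)
})

test_that("null dual-peak rate on independent Gaussian pairs stays under 0.5%", {
  set.seed(94)
  n <- 200; reps <- 300
  dates <- seq(as.Date("2000-01-01"), by = "day", length.out = n)
  dual <- 0L
  for (r in seq_len(reps)) {
    c1 <- hormone_series("A1", "cortisol", dates, rnorm(n, 100, 10))
    c2 <- hormone_series("A1", "corticosterone", dates, rnorm(n, 100, 10))
    dual <- dual + length(intersect(detect_peaks(c1), detect_peaks(c2)))
  }
  expect_lt(dual / (n * reps), 0.005)
})
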