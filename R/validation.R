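#' @title Analytical assay validation
#' @name validation
#' @description Before an EIA is trusted on a new sample matrix, two checks
#'   are run. Parallelism: a serially diluted pool of extracts must lose
#'   signal at the same rate as the standards on the log-dose scale
#'   (equal slopes of percent bound against log10 dose), implying
#'   immunological similarity; the working dilution is then read off where
#'   the pool reaches 50% binding. Accuracy (spike recovery): standards
#'   spiked with a fixed pool must be recovered 1:1 after subtracting the
#'   known addition.
NULL

#' Parallelism (equal-slope) test
#'
#' Fits percent bound against log10 dose separately for the standard series
#' (dose = concentration in pg/mL) and the pooled-sample dilution series
#' (dose proxy = 1/dilution factor, neat = 1; only relative dose matters
#' for the slope). The slope comparison is the extra-sum-of-squares ANCOVA
#' F test for the dose-by-series interaction in the combined two-line
#' model, with denominator degrees of freedom `n_total - 4`. Points
#' outside the quasi-linear percent-bound window (default 20-80%) are
#' excluded from both fits. The 50%-binding dilution is interpolated
#' linearly in (log10 dose, percent bound) between the two pool points
#' bracketing 50%.
#'
#' @param standards data frame or list with `conc` (pg/mL) and `pb`
#'   (percent bound).
#' @param pool data frame or list with `dilution` (factor, 1 = neat) and
#'   `pb`.
#' @param alpha significance level for the equal-slope decision.
#' @param linear_range percent-bound window entering the slope fits.
#' @return A list of class `parallelism_result`: `standard_slope`,
#'   `pool_slope`, `f_statistic`, `p_value`, `df` (numerator, denominator),
#'   `parallel` (TRUE when `p_value > alpha`), and `binding50_dilution`
#'   (`NA` when the pool never crosses 50% binding).
#' @export
parallelism_test <- function(standards, pool, alpha = 0.05,
                             linear_range = c(20, 80)) {
  std <- data.frame(logx = log10(standards$conc), pb = standards$pb,
                    series = "standard")
  pl <- data.frame(logx = log10(1 / pool$dilution), pb = pool$pb,
                   series = "pool")
  dat <- rbind(
    std[std$pb >= linear_range[1] & std$pb <= linear_range[2], ],
    pl[pl$pb >= linear_range[1] & pl$pb <= linear_range[2], ]
  )
  if (sum(dat$series == "standard") < 3L || sum(dat$series == "pool") < 3L) {
    stop("parallelism needs >= 3 points per series inside the linear range",
         call. = FALSE)
  }
  dat$series <- factor(dat$series, levels = c("standard", "pool"))
  full <- stats::lm(pb ~ logx * series, data = dat)
  reduced <- stats::lm(pb ~ logx + series, data = dat)
  av <- stats::anova(reduced, full)
  fstat <- av$F[2]
  pval <- av$`Pr(>F)`[2]
  if (is.na(fstat)) {  # exactly equal slopes: interaction adds nothing
    fstat <- 0
    pval <- 1
  }
  slopes <- stats::coef(full)
  std_slope <- unname(slopes["logx"])
  pool_slope <- unname(slopes["logx"] + slopes["logx:seriespool"])

  structure(list(
    standard_slope = std_slope,
    pool_slope = pool_slope,
    f_statistic = unname(fstat),
    p_value = unname(pval),
    df = c(1L, full$df.residual),
    parallel = unname(pval > alpha),
    binding50_dilution = interpolate_binding50(pool$dilution, pool$pb)
  ), class = "parallelism_result")
}

# Dilution factor at which the pool reaches 50% binding, linear in
# (log10 dose, %B) between the bracketing points; NA when all points sit
# on one side of 50%.
interpolate_binding50 <- function(dilution, pb, target = 50) {
  ord <- order(dilution)           # increasing dilution = decreasing dose
  d <- dilution[ord]; y <- pb[ord]
  logdose <- log10(1 / d)
  for (i in seq_len(length(d) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]
    if ((y1 - target) * (y2 - target) <= 0 && y1 != y2) {
      ld <- logdose[i] + (target - y1) * (logdose[i + 1L] - logdose[i]) /
        (y2 - y1)
      return(1 / 10^ld)
    }
  }
  NA_real_
}

#' @export
print.parallelism_result <- function(x, ...) {
  cat(sprintf(
    "<parallelism> slopes std %.3f vs pool %.3f; F(%d,%d) = %.3f, P = %.3f -> %s\n",
    x$standard_slope, x$pool_slope, x$df[1], x$df[2], x$f_statistic,
    x$p_value, if (x$parallel) "parallel" else "NOT parallel"))
  if (is.finite(x$binding50_dilution)) {
    cat(sprintf("  50%% binding at 1:%.2f dilution\n", x$binding50_dilution))
  } else {
    cat("  50% binding dilution unavailable (pool never crosses 50%)\n")
  }
  invisible(x)
}

#' Spike-recovery accuracy test
#'
#' Ordinary least squares of observed on expected concentrations, where
#' the expected values are the standard concentrations after subtracting
#' the known spike contribution. Acceptance requires r-squared > 0.95 and
#' a slope between 0.8 and 1.2.
#'
#' @param expected expected concentrations.
#' @param observed measured concentrations, same length (>= 3).
#' @param r2_min,slope_range acceptance band.
#' @return A list of class `accuracy_result`: `slope`, `intercept`,
#'   `r_squared`, `accepted`.
#' @export
accuracy_test <- function(expected, observed, r2_min = 0.95,
                          slope_range = c(0.8, 1.2)) {
  if (length(expected) != length(observed) || length(expected) < 3L) {
    stop("expected and observed must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(expected) == 0) {
    stop("regression error: expected concentrations have zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(observed ~ expected)
  slope <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((observed - mean(observed))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    accepted = r2 > r2_min && slope >= slope_range[1] &&
      slope <= slope_range[2]
  ), class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy> slope %.3f, intercept %.3f, r2 %.4f -> %s\n",
              x$slope, x$intercept, x$r_squared,
              if (x$accepted) "accepted" else "NOT accepted"))
  invisible(x)
}

#' Choose the working dilution
#'
#' The working dilution is the one putting the pool at 50% binding (mid
#' curve, where back-calculation is most accurate), but never below a
#' floor guarding against solvent matrix interference (a minimum of 1:10
#' is conventional for methanol extracts).
#'
#' @param result a `parallelism_result`, or a bare 50%-binding dilution
#'   factor.
#' @param floor minimum acceptable dilution factor.
#' @return The dilution factor to run samples at:
#'   `max(binding50_dilution, floor)`.
#' @examples
#' choose_working_dilution(6, floor = 10)   # 10
#' choose_working_dilution(30, floor = 10)  # 30
#' @export
choose_working_dilution <- function(result, floor = 10) {
  b50 <- if (inherits(result, "parallelism_result")) {
    result$binding50_dilution
  } else {
    result
  }
  if (!is.finite(b50)) {
    stop("no 50%-binding dilution available; pass one explicitly",
         call. = FALSE)
  }
  max(b50, floor)
}
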