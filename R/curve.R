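#' @title Four-parameter logistic standard curves
#' @name curve-4pl
#' @description Competitive EIA standard curves follow the 4PL model
#'   `y(x) = d + (a - d) / (1 + (x / c)^b)` with `a` the response at zero
#'   dose, `d` the response at infinite dose, `c` the inflection (EC50)
#'   concentration in pg/mL and `b` the slope factor. In the competitive
#'   orientation `a > d` and `b > 0`: the response falls as dose rises.
NULL

#' Evaluate the 4PL model
#'
#' @param x dose(s) in pg/mL, >= 0.
#' @param params list or curve with components `a`, `b`, `c`, `d`.
#' @return Predicted response(s).
#' @export
predict_4pl <- function(x, params) {
  p <- as_4pl_params(params)
  p$d + (p$a - p$d) / (1 + (x / p$c)^p$b)
}

as_4pl_params <- function(params) {
  if (inherits(params, "standard_curve")) params <- params$params
  stopifnot(all(c("a", "b", "c", "d") %in% names(params)))
  if (params$c <= 0) stop("4PL inflection c must be > 0", call. = FALSE)
  if (params$a == params$d) stop("4PL requires a != d", call. = FALSE)
  params[c("a", "b", "c", "d")]
}

#' Fit a 4PL standard curve
#'
#' Unweighted least squares via Levenberg-Marquardt, started from
#' `a = max(response)`, `d = min(response)`, `c = geometric mean of doses`,
#' `b = 1`. If the first fit fails, a fixed fallback grid over the slope
#' factor and the inflection is tried; fitting is fully deterministic.
#'
#' @param conc standard concentrations in pg/mL; at least 4 distinct values.
#' @param response observed responses (duplicate-mean percent bound by
#'   convention; any monotone response works).
#' @param plate_id optional plate identifier carried in the result.
#' @return An object of class `standard_curve`: `params` (a, b, c, d),
#'   `residual_sse`, `range_low`/`range_high` (lowest/highest standard in
#'   pg/mL) and `plate_id`.
#' @examples
#' x <- 156 * 2^(6:0)
#' y <- predict_4pl(x, list(a = 100, b = 1, c = 500, d = 0))
#' fit_4pl(x, y)
#' @export
fit_4pl <- function(conc, response, plate_id = NULL) {
  if (length(conc) != length(response)) {
    stop("conc and response must have equal length", call. = FALSE)
  }
  if (!all(is.finite(conc)) || !all(is.finite(response))) {
    stop("doses and responses must be finite", call. = FALSE)
  }
  if (any(conc <= 0)) stop("standard doses must be > 0", call. = FALSE)
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct standard concentrations are required to fit ",
         "a 4PL curve (got ", length(unique(conc)), ")", call. = FALSE)
  }
  dat <- data.frame(x = conc, y = response)
  starts <- list(list(a = max(response), d = min(response),
                      c = exp(mean(log(conc))), b = 1))
  # fixed fallback restart grid, tried in order only if needed
  for (b0 in c(0.5, 2, 4)) {
    for (c0 in stats::quantile(conc, c(0.25, 0.75), names = FALSE)) {
      starts[[length(starts) + 1L]] <-
        list(a = max(response), d = min(response), c = c0, b = b0)
    }
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = .Machine$double.eps,
                                     ptol = .Machine$double.eps)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
                        data = dat, start = st,
                        lower = c(a = -Inf, d = -Inf, c = 1e-9, b = 1e-6),
                        control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("4PL fit did not converge (",
         length(conc), " points, dose range ",
         signif(min(conc), 3), "-", signif(max(conc), 3),
         " pg/mL, response range ",
         signif(min(response), 3), "-", signif(max(response), 3), ")",
         call. = FALSE)
  }
  est <- as.list(stats::coef(fit))
  sse <- sum(stats::residuals(fit)^2)
  if (!is.finite(sse)) stop("4PL fit produced non-finite residuals",
                            call. = FALSE)
  structure(
    list(params = est[c("a", "b", "c", "d")], residual_sse = sse,
         range_low = min(conc), range_high = max(conc),
         plate_id = plate_id),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<standard_curve>%s a=%.4g d=%.4g c=%.4g pg/mL b=%.4g (SSE %.3g, range %g-%g)\n",
    if (is.null(x$plate_id)) "" else paste0(" ", x$plate_id),
    p$a, p$d, p$c, p$b, x$residual_sse, x$range_low, x$range_high))
  invisible(x)
}

#' Position of a response relative to a curve's asymptotes
#'
#' For a competitive curve (`a > d`), a response at or below the
#' infinite-dose asymptote `d` means the dose is beyond the top of the
#' curve (`"above_curve"`), and a response at or above the zero-dose
#' asymptote `a` means the dose is below the curve (`"below_curve"`).
#'
#' @param response response value(s).
#' @param curve a `standard_curve` or 4PL parameter list.
#' @return Character vector: `"ok"`, `"above_curve"` or `"below_curve"`.
#' @export
curve_status <- function(response, curve) {
  p <- as_4pl_params(curve)
  zero_dose <- p$a
  inf_dose <- p$d
  ifelse(!is.finite(response), NA_character_,
  ifelse((p$a > p$d & response <= inf_dose) |
         (p$a < p$d & response >= inf_dose), "above_curve",
  ifelse((p$a > p$d & response >= zero_dose) |
         (p$a < p$d & response <= zero_dose), "below_curve", "ok")))
}

#' Back-calculate concentration from a response (closed form)
#'
#' Inverts the 4PL model: `x = c * ((a - d) / (y - d) - 1)^(1 / b)`.
#' Responses outside the open interval between the asymptotes cannot be
#' inverted and raise a classed condition distinguishing the two sides
#' (`fgm_above_curve` when the dose would exceed the curve,
#' `fgm_below_curve` when it would fall under it).
#'
#' @param response response value(s), strictly between `min(a, d)` and
#'   `max(a, d)`.
#' @param curve a `standard_curve` or 4PL parameter list.
#' @return Concentration(s) in pg/mL.
#' @examples
#' cv <- list(a = 100, b = 1, c = 500, d = 0)
#' inverse_4pl(50, cv)                    # the inflection: 500
#' inverse_4pl(predict_4pl(156, cv), cv)  # round trip: 156
#' @export
inverse_4pl <- function(response, curve) {
  p <- as_4pl_params(curve)
  status <- curve_status(response, p)
  if (any(is.na(status))) {
    stop("non-finite response passed to inverse_4pl", call. = FALSE)
  }
  if (any(status == "above_curve")) {
    stop(structure(class = c("fgm_above_curve", "error", "condition"),
                   list(message = paste0(
                     "response beyond the high-dose asymptote for ",
                     sum(status == "above_curve"),
                     " value(s): redilute and re-run"),
                     call = NULL)))
  }
  if (any(status == "below_curve")) {
    stop(structure(class = c("fgm_below_curve", "error", "condition"),
                   list(message = paste0(
                     "response under the zero-dose asymptote for ",
                     sum(status == "below_curve"),
                     " value(s): below detection"),
                     call = NULL)))
  }
  p$c * ((p$a - p$d) / (response - p$d) - 1)^(1 / p$b)
}
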