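# Independent oracles and small fixture builders shared across tests.

# Log-scale bisection inverse of the 4PL model; independent of the
# closed-form inverse under test. Assumes the competitive orientation
# (response strictly monotone in dose).
bisect_inverse_4pl <- function(y, params, lo = 1e-8, hi = 1e9, iter = 120L) {
  f <- function(x) predict_4pl(x, params) - y
  a <- log(lo); b <- log(hi)
  fa <- f(exp(a))
  if (sign(fa) == sign(f(exp(b)))) stop("bisection bracket does not straddle")
  for (i in seq_len(iter)) {
    m <- (a + b) / 2
    if (sign(f(exp(m))) == sign(fa)) {
      a <- m
      fa <- f(exp(a))
    } else {
      b <- m
    }
  }
  exp((a + b) / 2)
}

# Closed-form OLS of y on x: slope, intercept, r-squared.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Random 4PL parameter sets in the competitive orientation (a > d, b > 0).
random_4pl_params <- function(n) {
  lapply(seq_len(n), function(i) {
    list(a = stats::runif(1, 80, 120),
         b = stats::runif(1, 0.5, 3),
         c = exp(stats::runif(1, log(50), log(5000))),
         d = stats::runif(1, -5, 5))
  })
}

# Extraction records matching a simulated plate's sample ids.
extractions_for <- function(sample_ids, mass = 0.2, volume = 2,
                            animal_id = "M1", date = "2010-06-01") {
  data.frame(sample_id = sample_ids, animal_id = animal_id,
             collection_datetime = paste0(date, "T11:00:00"),
             dry_mass_g = mass, solvent_volume_ml = volume,
             date = as.Date(date))
}

# A daily-dated series with spikes at chosen positions; baseline `base`,
# spike value `spike`, n days starting at `start`.
spiked_series <- function(n, spike_at, base = 10, spike = 1000,
                          start = as.Date("2015-01-01")) {
  v <- rep(base, n)
  v[spike_at] <- spike
  list(dates = seq(start, by = "day", length.out = n), values = v)
}

# Two parallelism series lying exactly on lines of the given slopes, with
# an identical deterministic perturbation pattern so that equal slopes stay
# exactly equal after fitting.
linear_parallelism_data <- function(std_slope = -20, pool_slope = -20,
                                    noise = NULL) {
  conc <- 156 * 2^(6:0)
  dil <- c(1, 2, 4, 8, 16, 32, 64)
  pert <- rep(c(0.1, -0.1), length.out = 7)
  std_pb <- 50 + std_slope * (log10(conc) - mean(log10(conc))) + pert
  pool_pb <- 50 + pool_slope * (log10(1 / dil) - mean(log10(1 / dil))) + pert
  if (!is.null(noise)) {
    std_pb <- std_pb + stats::rnorm(7, 0, noise)
    pool_pb <- pool_pb + stats::rnorm(7, 0, noise)
  }
  list(standards = data.frame(conc = conc, pb = std_pb),
       pool = data.frame(dilution = dil, pb = pool_pb))
}
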