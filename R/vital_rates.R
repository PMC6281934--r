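#' Vital rates for the three-stage female right whale model
#'
#' Bundles the annual survival probabilities, stage durations, calving
#' interval and calf sex ratio that parameterise the stage-structured
#' (Lefkovitch) projection matrix. Defaults are the best-available estimates
#' for female North Atlantic right whales: the highest annual survival rates
#' from mark--resight analysis (calves 0.96299, juveniles 0.97507, adult
#' females 0.97314), a one-year calf stage, an eight-year immature stage, a
#' 59-year adult stage and a four-year calving interval with an even calf
#' sex ratio.
#'
#' @param sigma_calf,sigma_juv,sigma_adult Annual survival probabilities in
#'   \[0, 1\] for the calf, immature and adult stages.
#' @param d_calf,d_juv,d_adult Stage durations in whole years (>= 1).
#' @param calving_interval Mean years between successive calves of one
#'   female (> 0).
#' @param female_fraction Probability a calf is female, in \[0, 1\].
#'
#' @return An object of class `"vital_rates"`: a named list of the eight
#'   parameters.
#' @examples
#' vr <- vital_rates()
#' vr$sigma_adult
#' @export
vital_rates <- function(sigma_calf = 0.96299,
                        sigma_juv = 0.97507,
                        sigma_adult = 0.97314,
                        d_calf = 1L,
                        d_juv = 8L,
                        d_adult = 59L,
                        calving_interval = 4,
                        female_fraction = 0.5) {
  vr <- list(
    sigma_calf = sigma_calf, sigma_juv = sigma_juv, sigma_adult = sigma_adult,
    d_calf = as.integer(d_calf), d_juv = as.integer(d_juv),
    d_adult = as.integer(d_adult),
    calving_interval = calving_interval, female_fraction = female_fraction
  )
  for (p in c("sigma_calf", "sigma_juv", "sigma_adult", "female_fraction")) {
    x <- vr[[p]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1]", p))
    }
  }
  for (p in c("d_calf", "d_juv", "d_adult")) {
    x <- vr[[p]]
    if (is.na(x) || x < 1L) {
      stop(sprintf("'%s' must be a whole number of years >= 1", p))
    }
  }
  if (!is.numeric(vr$calving_interval) || is.na(vr$calving_interval) ||
      vr$calving_interval <= 0) {
    stop("'calving_interval' must be > 0")
  }
  structure(vr, class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Vital rates (three-stage female model)\n")
  cat(sprintf("  survival:  calf %.5f  immature %.5f  adult %.5f\n",
              x$sigma_calf, x$sigma_juv, x$sigma_adult))
  cat(sprintf("  duration:  calf %d  immature %d  adult %d (years)\n",
              x$d_calf, x$d_juv, x$d_adult))
  cat(sprintf("  calving interval %.3g years, female fraction %.3g\n",
              x$calving_interval, x$female_fraction))
  invisible(x)
}

check_sigma_d <- function(sigma, d) {
  if (any(!is.finite(sigma)) || any(sigma < 0) || any(sigma > 1)) {
    stop("'sigma' must lie in [0, 1]")
  }
  if (any(!is.finite(d)) || any(d < 1) || any(d != round(d))) {
    stop("'d' must be a whole number of years >= 1")
  }
}

#' Stage retention and advancement probabilities
#'
#' Under the fixed-stage-duration approximation, an individual with annual
#' survival `sigma` in a stage lasting `d` years remains in the stage with
#' probability `P = sigma * (1 - sigma^(d-1)) / (1 - sigma^d)` and advances
#' to the next stage with probability `G = sigma^d * (1 - sigma) /
#' (1 - sigma^d)`. The two satisfy `P + G = sigma` exactly. At `sigma = 1`
#' the continuity limits `P = (d-1)/d` and `G = 1/d` are used.
#'
#' @param sigma Annual survival probability in \[0, 1\].
#' @param d Stage duration in whole years (>= 1).
#' @return A probability in `[0, sigma]`. Both functions are vectorised over
#'   `sigma` and `d`.
#' @examples
#' stage_retention_prob(0.97507, 8)   # juvenile retention, 0.86368
#' stage_transition_prob(0.97507, 8)  # juvenile advancement, 0.11139
#' @export
stage_retention_prob <- function(sigma, d) {
  check_sigma_d(sigma, d)
  n <- max(length(sigma), length(d))
  sigma <- rep_len(sigma, n)
  d <- rep_len(d, n)
  out <- numeric(n)
  i <- d > 1 & sigma == 1
  out[i] <- (d[i] - 1) / d[i]
  i <- d > 1 & sigma > 0 & sigma < 1
  out[i] <- sigma[i] * (1 - sigma[i]^(d[i] - 1)) / (1 - sigma[i]^d[i])
  out
}

#' @rdname stage_retention_prob
#' @export
stage_transition_prob <- function(sigma, d) {
  check_sigma_d(sigma, d)
  n <- max(length(sigma), length(d))
  sigma <- rep_len(sigma, n)
  d <- rep_len(d, n)
  out <- numeric(n)
  out[d == 1] <- sigma[d == 1]
  i <- d > 1 & sigma == 1
  out[i] <- 1 / d[i]
  i <- d > 1 & sigma > 0 & sigma < 1
  out[i] <- sigma[i]^d[i] * (1 - sigma[i]) / (1 - sigma[i]^d[i])
  out
}

#' Per-year female-calf production of an adult female
#'
#' The reciprocal of the calving interval gives the annual probability an
#' adult gives birth; multiplying by the female fraction gives the expected
#' number of female calves per adult female per year (the fecundity entry of
#' the projection matrix). A 4-year interval and even sex ratio give 0.125.
#'
#' @param calving_interval Years between calves (> 0).
#' @param female_fraction Probability a calf is female.
#' @return Expected female calves per adult female per year.
#' @examples
#' fecundity(4, 0.5)  # 0.125
#' @export
fecundity <- function(calving_interval, female_fraction) {
  if (any(is.na(calving_interval)) || any(calving_interval <= 0)) {
    stop("'calving_interval' must be > 0")
  }
  if (any(female_fraction < 0) || any(female_fraction > 1)) {
    stop("'female_fraction' must lie in [0, 1]")
  }
  female_fraction / calving_interval
}
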