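#' Fit a negative-binomial GLM of calf counts with per-site year slopes
#'
#' Fits `count ~ 0 + site + site:year` by maximum likelihood with a log link
#' and NB2 variance (`mu + mu^2 / theta`), alternating the GLM fit with
#' score iterations for the overdispersion parameter `theta` (via
#' [MASS::glm.nb()]). The per-site coding means each site's intercept and
#' annual log-linear slope, with its standard error, is read directly off
#' the coefficient table; it is a reparameterisation of the usual
#' reference-level-plus-interaction coding and gives identical fitted
#' values.
#'
#' @param data A data frame with columns `year` (integer calendar year),
#'   `site` (population label) and `count` (nonnegative integer calves),
#'   one row per observed site-year; sites may span different year ranges.
#'   Each site needs at least 3 records and at least one nonzero count.
#' @param maxit Iteration cap for the alternating fit.
#' @param epsilon Convergence tolerance on the deviance.
#' @param theta Optional fixed overdispersion; when supplied the GLM is fit
#'   with a fixed NB2 variance function instead of estimating `theta` by
#'   maximum likelihood (a very large value approaches the Poisson fit).
#' @return An object of class `"trend_fit"`: a list with the fitted
#'   `model`, a `slopes` data frame (`site`, `slope`, `se` on the log-link
#'   scale), `theta`, `theta_se`, `converged` and `logLik`.
#' @examples
#' d <- generate_counts(trend_scenario(), seed = 1)
#' fit <- fit_nb_glm(d)
#' fit$slopes
#' @export
fit_nb_glm <- function(data, maxit = 100, epsilon = 1e-8, theta = NULL) {
  data <- validate_counts(data)
  tab <- table(data$site)
  if (any(tab < 3)) {
    stop("each site needs at least 3 records; too few for: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  }
  zero <- tapply(data$count, data$site, function(x) all(x == 0))
  if (any(zero)) {
    stop("site(s) with all-zero counts cannot be fitted on the log scale: ",
         paste(names(zero)[zero], collapse = ", "))
  }
  data$site <- factor(data$site)
  ctrl <- stats::glm.control(epsilon = epsilon, maxit = maxit)
  if (is.null(theta)) {
    model <- MASS::glm.nb(count ~ 0 + site + site:year, data = data,
                          control = ctrl)
    theta_hat <- model$theta
    theta_se <- model$SE.theta
  } else {
    if (theta <= 0) stop("'theta' must be > 0")
    model <- stats::glm(count ~ 0 + site + site:year, data = data,
                        family = MASS::negative.binomial(theta),
                        control = ctrl)
    theta_hat <- theta
    theta_se <- NA_real_
  }
  if (!model$converged) {
    stop(sprintf("negative-binomial fit did not converge within %d iterations",
                 maxit))
  }
  cf <- stats::coef(model)
  se <- sqrt(diag(stats::vcov(model)))
  slope_idx <- grep(":year$", names(cf))
  sites <- sub("^site", "", sub(":year$", "", names(cf)[slope_idx]))
  slopes <- data.frame(site = sites, slope = unname(cf[slope_idx]),
                       se = unname(se[slope_idx]))
  structure(
    list(model = model, slopes = slopes, theta = theta_hat,
         theta_se = theta_se, converged = model$converged,
         logLik = as.numeric(stats::logLik(model))),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial calf-count trend fit (theta = %.2f, logLik = %.2f)\n",
              x$theta, x$logLik))
  print(site_growth_rates(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-site annual growth rates from a trend fit
#'
#' Reports each site's annual rate of increase as `100 * slope` percent per
#' year (the log-link slope scaled to percent, the conventional reporting
#' for small rates) alongside the exact back-transformed rate
#' `100 * (exp(slope) - 1)`.
#'
#' @param fit A [fit_nb_glm()] result.
#' @return A data frame with columns `site`, `slope`, `se` (link scale),
#'   `pct_per_year`, `pct_se` (both `100 *` link scale) and
#'   `pct_exact` (`100 * (exp(slope) - 1)`).
#' @export
site_growth_rates <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  s <- fit$slopes
  data.frame(site = s$site, slope = s$slope, se = s$se,
             pct_per_year = 100 * s$slope, pct_se = 100 * s$se,
             pct_exact = 100 * (exp(s$slope) - 1))
}

#' FDR-adjusted pairwise slope contrasts
#'
#' Tests, for every unordered pair of sites, whether the two annual
#' log-linear slopes differ: a Wald chi-square statistic on 1 degree of
#' freedom, `(b1 - b2)^2 / (v11 + v22 - 2 v12)`, from the fitted
#' coefficient covariance, with p-values adjusted jointly across all pairs
#' by the Benjamini--Hochberg false discovery rate.
#'
#' @param fit A [fit_nb_glm()] result with at least 2 sites.
#' @return An object of class `"pairwise_contrasts"`: a data frame with one
#'   row per pair: `site1`, `site2`, `difference` (link-scale
#'   `slope1 - slope2`), `df`, `chisq`, `p_value`, `p_adjusted`.
#' @export
pairwise_slope_contrasts <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  sites <- fit$slopes$site
  if (length(sites) < 2) stop("need at least 2 sites for contrasts")
  V <- stats::vcov(fit$model)
  nm <- paste0("site", sites, ":year")
  pairs <- utils::combn(seq_along(sites), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- fit$slopes$slope[i] - fit$slopes$slope[j]
    v <- V[nm[i], nm[i]] + V[nm[j], nm[j]] - 2 * V[nm[i], nm[j]]
    if (!is.finite(v) || v <= 0) {
      stop("singular coefficient covariance for contrast ",
           sites[i], "-", sites[j])
    }
    c(d = d, chisq = d^2 / v)
  })
  out <- data.frame(
    site1 = sites[pairs[1, ]], site2 = sites[pairs[2, ]],
    difference = res["d", ], df = 1L, chisq = res["chisq", ],
    p_value = stats::pchisq(res["chisq", ], df = 1, lower.tail = FALSE)
  )
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("pairwise_contrasts", "data.frame")
  out
}

#' Geometric abundance extrapolation
#'
#' Projects an abundance forward at a constant annual proportional rate:
#' `n0 * (1 + rate)^years`. Used to cross-check a calf-count growth rate
#' against an independent abundance series, e.g. 270 whales growing at
#' 1.98% per year for 26 years gives about 450.
#'
#' @param n0 Starting abundance (>= 0).
#' @param rate Annual proportional rate of increase (> -1); 0.0198 means
#'   1.98% per year.
#' @param years Number of years (>= 0).
#' @param round_result Round to the nearest whole animal?
#' @return The extrapolated abundance.
#' @examples
#' extrapolate_abundance(270, 0.0198, 26, round_result = TRUE)  # 450
#' @export
extrapolate_abundance <- function(n0, rate, years, round_result = FALSE) {
  if (any(n0 < 0)) stop("'n0' must be >= 0")
  if (any(rate <= -1)) stop("'rate' must be > -1")
  if (any(years < 0)) stop("'years' must be >= 0")
  out <- n0 * (1 + rate)^years
  if (round_result) round(out) else out
}
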