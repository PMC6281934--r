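test_that("fitted slopes recover the generating slopes on a synthetic panel", {
  sc <- trend_scenario()
  d <- generate_counts(sc, seed = 101)
  fit <- fit_nb_glm(d)
  expect_true(fit$converged)
  expect_gt(fit$theta, 0)
  expect_true(all(fitted(fit$model) > 0))
  expect_identical(fit$slopes$site, sort(sc$sites))
  ord <- match(fit$slopes$site, sc$sites)
  expect_true(all(abs(fit$slopes$slope - sc$slopes[ord]) <
                    3 * fit$slopes$se))
})

test_that("slopes are invariant to centring the year covariate", {
  d <- generate_counts(trend_scenario(), seed = 102)
  d2 <- d
  d2$year <- d2$year - 2004L
  f1 <- fit_nb_glm(d)
  f2 <- fit_nb_glm(d2)
  expect_equal(f1$slopes$slope, f2$slopes$slope, tolerance = 1e-6)
  expect_equal(f1$slopes$se, f2$slopes$se, tolerance = 1e-4)
})

test_that("per-site coding agrees with reference-level interaction coding", {
  d <- generate_counts(trend_scenario(), seed = 103)
  fit <- fit_nb_glm(d)
  d$site <- factor(d$site)
  ref <- MASS::glm.nb(count ~ site * year, data = d)
  cf <- coef(ref)
  base_slope <- cf["year"]
  ref_slopes <- c(base_slope,
                  base_slope + cf[grep("^site.*:year$", names(cf))])
  expect_equal(unname(fit$slopes$slope), unname(ref_slopes),
               tolerance = 1e-5)
})

test_that("a very large fixed dispersion reproduces the Poisson fit", {
  d <- generate_counts(trend_scenario(theta = 1e6), seed = 104)
  nb <- fit_nb_glm(d, theta = 1e7)
  d$site <- factor(d$site)
  pois <- glm(count ~ 0 + site + site:year, family = poisson, data = d)
  expect_equal(unname(nb$slopes$slope),
               unname(coef(pois)[grep(":year$", names(coef(pois)))]),
               tolerance = 1e-4)
})

test_that("a constant count series gets a (near) zero slope", {
  yrs <- 1992:2015
  d <- rbind(data.frame(year = yrs, site = "FLAT", count = 20L),
             generate_counts(trend_scenario(), seed = 105))
  fit <- suppressWarnings(fit_nb_glm(d))
  expect_lt(abs(fit$slopes$slope[fit$slopes$site == "FLAT"]), 1e-6)
})

test_that("growth rates are reported on the percent scale both ways", {
  d <- generate_counts(trend_scenario(), seed = 106)
  fit <- fit_nb_glm(d)
  r <- site_growth_rates(fit)
  expect_equal(r$pct_per_year, 100 * r$slope)
  expect_equal(r$pct_se, 100 * r$se)
  expect_equal(r$pct_exact, 100 * (exp(r$slope) - 1))
  expect_true(all(r$pct_exact >= r$pct_per_year))  # exp(b) - 1 >= b
})

test_that("pairwise contrasts are Wald 1-df tests with BH-adjusted p-values", {
  d <- generate_counts(trend_scenario(), seed = 107)
  fit <- fit_nb_glm(d)
  ct <- pairwise_slope_contrasts(fit)
  expect_equal(nrow(ct), choose(4, 2))
  expect_true(all(ct$df == 1))
  # difference column is the plain slope difference (antisymmetric by
  # construction in pair order)
  s <- setNames(fit$slopes$slope, fit$slopes$site)
  expect_equal(ct$difference, unname(s[ct$site1] - s[ct$site2]))
  # chisq consistent with its own p-value
  expect_equal(ct$p_value, pchisq(ct$chisq, 1, lower.tail = FALSE))
  # BH: adjusted >= raw, and adjusted ordering follows raw ordering
  expect_true(all(ct$p_adjusted >= ct$p_value))
  expect_true(all(diff(ct$p_adjusted[order(ct$p_value)]) >= -1e-15))
  expect_equal(ct$p_adjusted, p.adjust(ct$p_value, "BH"))
})

test_that("degenerate count series are rejected with clear errors", {
  d <- generate_counts(trend_scenario(), seed = 108)
  expect_error(fit_nb_glm(d[d$site == "NARW", ][1:2, ]), "at least 3")
  dz <- rbind(d, data.frame(year = 1992:2000, site = "ZERO", count = 0L))
  expect_error(fit_nb_glm(dz), "all-zero")
  ds <- d
  names(ds)[3] <- "calves"
  expect_error(fit_nb_glm(ds), "missing column")
})

test_that("geometric extrapolation matches direct arithmetic", {
  expect_equal(extrapolate_abundance(100, 0, 30), 100)
  # a 4%/year increase over the 25-year projection horizon
  expect_equal(extrapolate_abundance(123, 0.04, 25), 123 * 1.04^25)
  expect_equal(extrapolate_abundance(123, 0.04, 25, round_result = TRUE), 328)
  expect_error(extrapolate_abundance(-1, 0.01, 5), "n0")
  expect_error(extrapolate_abundance(100, -1, 5), "rate")
  expect_error(extrapolate_abundance(100, 0.01, -5), "years")
})
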