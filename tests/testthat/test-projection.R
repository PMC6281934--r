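an_paper <- analyze(paper_matrix())

test_that("stable-stage allocation preserves totals and scales linearly", {
  expect_identical(unname(initial_vector_from_ssd(0, an_paper)), c(0L, 0L, 0L))
  v123 <- initial_vector_from_ssd(123, an_paper)
  v246 <- initial_vector_from_ssd(246, an_paper)
  expect_identical(sum(v246), 246L)
  # independent recomputation by the largest-remainder rule from w
  raw <- 246 * an_paper$ssd
  base <- floor(raw)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(246 - sum(base))]
  base[extra] <- base[extra] + 1
  expect_identical(unname(v246), unname(as.integer(base)))
  expect_true(all(abs(v246 - 2 * v123) <= 1))
  # totals always preserved across a sweep
  for (n in c(1, 7, 50, 999)) {
    expect_identical(sum(initial_vector_from_ssd(n, an_paper)), as.integer(n))
  }
  expect_error(initial_vector_from_ssd(-5, an_paper), "nonnegative")
})

test_that("deterministic projection grows near-geometrically from the SSD", {
  A <- paper_matrix()
  traj1 <- project_deterministic(A, c(8, 46, 69), 1)
  expect_equal(sum(traj1[2, ]), 123 * an_paper$lambda, tolerance = 0.01)
  traj25 <- project_deterministic(A, c(8, 46, 69), 25, start_year = 1990)
  expect_equal(sum(traj25["2015", ]), 123 * an_paper$lambda^25,
               tolerance = 0.01)
  expect_equal(unname(traj25[1, ]), c(8, 46, 69))
  # zero start stays zero
  z <- project_deterministic(A, c(0, 0, 0), 10)
  expect_true(all(z == 0))
})

test_that("stochastic projection is seed-reproducible, bit for bit", {
  vr <- paper_vr()
  e1 <- project_stochastic(vr, c(8, 46, 69), 10, reps = 50, seed = 99)
  e2 <- project_stochastic(vr, c(8, 46, 69), 10, reps = 50, seed = 99)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_identical(e1$totals, e2$totals)
  e3 <- project_stochastic(vr, c(8, 46, 69), 10, reps = 50, seed = 100)
  expect_false(identical(e1$totals, e3$totals))
})

test_that("stochastic edge cases: extinction stays extinct, immortals conserve", {
  vr <- paper_vr()
  ez <- project_stochastic(vr, c(0, 0, 0), 8, reps = 20, seed = 1)
  expect_true(all(ez$trajectories == 0L))
  # no death, no birth: every replicate conserves its total every year
  # d_adult so long that ageing out is (numerically) impossible here
  vr1 <- vital_rates(sigma_calf = 1, sigma_juv = 1, sigma_adult = 1,
                     d_adult = 1000000000L, calving_interval = Inf)
  ec <- project_stochastic(vr1, c(5, 10, 20), 12, reps = 30, seed = 2)
  expect_true(all(ec$totals == 35L))
  expect_error(project_stochastic(vr, c(1.5, 2, 3), 5, reps = 5), "integer")
})

test_that("lower survival strictly lowers the projected median", {
  base <- paper_vr()
  worse <- vital_rates(sigma_calf = base$sigma_calf * 0.93,
                       sigma_juv = base$sigma_juv * 0.93,
                       sigma_adult = base$sigma_adult * 0.93)
  m_base <- stats::median(project_stochastic(base, c(8, 46, 69), 25,
                                             reps = 2000, seed = 7)$totals[, 26])
  m_worse <- stats::median(project_stochastic(worse, c(8, 46, 69), 25,
                                              reps = 2000, seed = 7)$totals[, 26])
  expect_lt(m_worse, m_base)
})

test_that("birth timing switch discounts calves by adult survival", {
  vr <- paper_vr()
  pre <- project_stochastic(vr, c(0, 0, 50000), 1, reps = 20, seed = 5,
                            birth_timing = "pre_survival")
  post <- project_stochastic(vr, c(0, 0, 50000), 1, reps = 20, seed = 5,
                             birth_timing = "post_survival")
  f <- fecundity(vr$calving_interval, vr$female_fraction)
  Pa <- stage_retention_prob(vr$sigma_adult, vr$d_adult)
  expect_equal(mean(pre$trajectories[, 2, "calf"]), 50000 * f,
               tolerance = 0.02)
  expect_equal(mean(post$trajectories[, 2, "calf"]), 50000 * f * Pa,
               tolerance = 0.02)
})

test_that("ensemble summaries report medians, quantiles and stage means", {
  vr <- paper_vr()
  e1 <- project_stochastic(vr, c(8, 46, 69), 5, reps = 1, seed = 3,
                           start_year = 1990)
  s1 <- ensemble_summary(e1)
  expect_equal(s1$median_total, unname(e1$totals[1, ]))
  expect_equal(s1$year, 1990:1995)
  e <- project_stochastic(vr, c(8, 46, 69), 25, reps = 400, seed = 4)
  s <- ensemble_summary(e, quantiles = c(0.025, 0.5, 0.975))
  expect_named(s, c("year", "median_total", "q0.025", "q0.5", "q0.975",
                    "mean_total", "mean_calf", "mean_immature", "mean_adult"))
  det_total <- 123 * an_paper$lambda^25
  expect_lt(s$q0.025[26], det_total)
  expect_gt(s$q0.975[26], det_total)
  expect_equal(s$mean_calf + s$mean_immature + s$mean_adult, s$mean_total)
})
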