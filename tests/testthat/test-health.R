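test_that("relative risk is 1 at and below the counterfactual, rising above", {
  th <- list(theta = 0.143, alpha = 1.6, mu = 15.5, upsilon = 36.8)
  rr <- function(c) do.call(relative_risk, c(list(c = c), th))
  expect_equal(rr(2.4), 1)
  expect_equal(rr(0), 1)
  expect_equal(rr(seq(0, 2.4, by = 0.1)), rep(1, 25))
  # continuity at the threshold and monotone growth above it
  expect_lt(abs(rr(2.4 + 1e-9) - 1), 1e-8)
  cs <- seq(2.4, 60, by = 0.1)
  expect_true(all(diff(rr(cs)) > 0))
  # direct-arithmetic oracle at c = 10 (fixture parameters):
  # z = 7.6, log(7.6/1.6 + 1) = log(5.75), logistic weight 1/(1+exp(7.9/36.8))
  expect_equal(rr(10), 1.118171, tolerance = 1e-6)
  expect_error(rr(-1), ">= 0")
})

test_that("attributable deaths reproduce hand arithmetic and additivity", {
  g <- generate_domain(2, 2, seed = 1)
  gp <- flat_gemm(theta = 1)  # RR controlled through exposure below
  # choose exposure giving RR = 1.25 in one cell: theta*k = log(1.25)
  k_target <- log(1.25)
  # invert gemm_shape numerically for the exposure
  f <- function(c) log((c - 2.4) / 1.6 + 1) / (1 + exp(-((c - 2.4) - 15.5) / 36.8)) - k_target
  c25 <- uniroot(f, c(2.5, 50), tol = 1e-12)$root
  field <- c(c25, 0, 0, 0)
  ages <- unit_ages(g, pop_per_cell = 1e5, base_rate = 0.01)
  res <- attributable_deaths(field, ages, gp)
  expect_equal(res$deaths, 0.01 * 1e5 * (1 - 1 / 1.25), tolerance = 1e-9)

  # splitting the exposed population across two equal cells changes nothing
  ages2 <- unit_ages(g, pop_per_cell = c(5e4, 5e4, 0, 0), base_rate = 0.01)
  res2 <- attributable_deaths(c(c25, c25, 0, 0), ages2, gp)
  expect_equal(res2$deaths, res$deaths, tolerance = 1e-9)

  # scale invariance
  ages3 <- unit_ages(g, pop_per_cell = 2e5, base_rate = 0.01)
  expect_equal(attributable_deaths(field, ages3, gp)$deaths, 2 * res$deaths)

  # below-threshold exposure yields exactly zero
  expect_equal(attributable_deaths(rep(2.0, 4), ages, gp)$deaths, 0)
  expect_error(attributable_deaths(field[1:3], ages, gp), "grids")
})

test_that("the as-printed form returns total rather than excess mortality", {
  g <- generate_domain(2, 2, seed = 1)
  ages <- unit_ages(g, pop_per_cell = 1e5, base_rate = 0.01)
  gp <- flat_gemm()
  below <- rep(2.0, 4)
  expect_equal(attributable_deaths(below, ages, gp, as_printed = TRUE)$deaths,
               sum(ages$pop * ages$base_rate))
})

test_that("avoided deaths are differences of attributable burdens", {
  g <- generate_domain(2, 2, seed = 1)
  ages <- unit_ages(g, pop_per_cell = 1e5, base_rate = 0.01)
  gp <- flat_gemm(theta = 0.143)
  base <- c(20, 15, 10, 8)
  expect_equal(avoided_deaths(base, base, ages, gp)$deaths, 0)
  clean <- rep(2.0, 4)
  expect_equal(avoided_deaths(base, clean, ages, gp)$deaths,
               attributable_deaths(base, ages, gp)$deaths)
  # hand-computed two-exposure difference
  d <- attributable_deaths(base, ages, gp)$deaths -
    attributable_deaths(c(12, 9, 6, 5), ages, gp)$deaths
  expect_equal(avoided_deaths(base, c(12, 9, 6, 5), ages, gp)$deaths, d)
  expect_gt(d, 0)
})

test_that("Monte Carlo CI degenerates when theta has no uncertainty", {
  g <- generate_domain(2, 2, seed = 1)
  ages <- unit_ages(g, pop_per_cell = 1e5, base_rate = 0.01)
  gp <- flat_gemm(theta = 0.143, theta_se = 0)
  res <- monte_carlo_ci(c(20, 15, 10, 8), ages = ages, params = gp,
                        n_draws = 500, seed = 3)
  expect_equal(res$ci_low, res$deaths, tolerance = 1e-9)
  expect_equal(res$ci_high, res$deaths, tolerance = 1e-9)
  expect_equal(eval(formals(monte_carlo_ci)$n_draws), 10000L)
})

test_that("Monte Carlo CI matches the closed-form percentile transform", {
  # one cell, one group: deaths(theta) = BP * (1 - exp(-theta k)) is monotone
  # in theta, so the CI must equal the transform of the normal percentiles
  g <- generate_domain(2, 2, seed = 1)
  ages <- unit_ages(g, pop_per_cell = c(1e5, 0, 0, 0), base_rate = 0.01)
  th <- 0.143; se <- 0.02
  gp <- flat_gemm(theta = th, theta_se = se)
  field <- c(20, 0, 0, 0)
  res <- monte_carlo_ci(field, ages = ages, params = gp,
                        n_draws = 1e5, seed = 7)
  k <- log((20 - 2.4) / 1.6 + 1) / (1 + exp(-((20 - 2.4) - 15.5) / 36.8))
  bp <- 0.01 * 1e5
  expect_equal(res$ci_low, bp * (1 - exp(-(th + qnorm(0.025) * se) * k)),
               tolerance = 0.01)
  expect_equal(res$ci_high, bp * (1 - exp(-(th + qnorm(0.975) * se) * k)),
               tolerance = 0.01)
})

test_that("the CI contains the point estimate across seeded runs", {
  g <- generate_domain(2, 2, seed = 1)
  ages <- unit_ages(g, pop_per_cell = 1e5, base_rate = 0.01)
  gp <- flat_gemm(theta = 0.143, theta_se = 0.03)
  field <- c(20, 15, 10, 8)
  inside <- vapply(1:20, function(s) {
    r <- monte_carlo_ci(field, ages = ages, params = gp, n_draws = 400, seed = s)
    r$ci_low <= r$deaths && r$deaths <= r$ci_high
  }, TRUE)
  expect_gte(sum(inside), 19)
})
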