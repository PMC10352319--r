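test_that("level interpolation reproduces knots and linear responses", {
  lv <- c(0, 0.3, 0.6, 0.8, 1)
  pm_lin <- 10 - 2 * lv
  cv <- interpolate_levels(lv, pm_lin)
  expect_equal(cv$pm_at_level, 10 - 2 * cv$levels, tolerance = 1e-12)
  # knot values returned exactly (index by level position, not float match)
  pm_curved <- 10 - 2 * lv^2
  cv2 <- interpolate_levels(lv, pm_curved)
  expect_equal(cv2$pm_at_level[round(10 * lv) + 1], pm_curved, tolerance = 1e-12)
  expect_error(interpolate_levels(c(0, 0.3, 0.3, 1), c(1, 2, 3, 4)), "duplicate")
  expect_error(interpolate_levels(c(0.1, 0.3, 0.6, 1), 1:4), "base")
  expect_error(interpolate_levels(c(0, 0.5, 1), 1:3), ">= 4")
})

test_that("interpolated 10% grid tracks the surrogate between knots", {
  inv <- small_inventory()
  p <- chem_params()  # finite sharpness: smooth response
  pm_at <- function(r) regional_mean(sia_equilibrium(inv, scenario_spec(r, 0), p))
  knots <- c(0, 0.3, 0.6, 0.8, 1)
  cv <- interpolate_levels(knots, vapply(knots, pm_at, 0))
  direct <- vapply(cv$levels, pm_at, 0)
  expect_lt(max(abs(cv$pm_at_level - direct)), 0.05 * diff(range(direct)))
})

test_that("instant efficiency matches analytic stencils", {
  lv <- seq(0, 1, 0.1)
  # linear response: beta = slope/base everywhere
  b_lin <- instant_efficiency(interpolate_levels(c(0, 0.3, 0.6, 0.8, 1),
                                                 10 - 2 * c(0, 0.3, 0.6, 0.8, 1)))
  expect_equal(b_lin$beta, rep(0.2, 11), tolerance = 1e-12)
  # constant response: beta = 0
  b_const <- instant_efficiency(interpolate_levels(c(0, 0.3, 0.6, 0.8, 1),
                                                   rep(7, 5)))
  expect_equal(b_const$beta, rep(0, 11))
  # quadratic response, centered stencil at 50% from the 40%/60% values:
  # pm = 10 - 2 r^2 -> beta(0.5) = (Delta(0.6)-Delta(0.4))/10 / 0.2 = 0.2
  cv <- interpolate_levels(lv, 10 - 2 * lv^2)
  bq <- instant_efficiency(cv)
  expect_equal(bq$beta[6], 0.2, tolerance = 1e-12)
  # one-sided ends: forward at 0% (slope ~0), backward at 100% (slope ~0.4/ base)
  expect_equal(bq$beta[1], (2 * 0.1^2) / 10 / 0.1, tolerance = 1e-12)
  expect_equal(bq$beta[11], (2 * (1^2 - 0.9^2)) / 10 / 0.1, tolerance = 1e-12)
})

test_that("beta agrees with fine-grid finite differences of the surrogate", {
  inv <- box_inventory(A = 0.2, TN = 0.06, bg = 5)
  set.seed(99)
  for (rep in 1:10) {
    p <- chem_params(a_tot = 1, n_tot = 1, p_ox = runif(1, 1, 2),
                     s_fix = runif(1, 0.005, 0.03), eps = runif(1, 0.3, 1),
                     sharpness = 60)
    pm_at <- function(r) regional_mean(sia_equilibrium(inv, scenario_spec(r, 0), p))
    lv <- seq(0, 1, 0.1)
    pm <- vapply(lv, pm_at, 0)
    beta <- instant_efficiency(interpolate_levels(lv, pm))$beta
    h <- 1e-4
    for (k in c(3, 5, 7, 9)) {
      oracle <- (pm_at(lv[k] - h) - pm_at(lv[k] + h)) / (2 * h) / pm[1]
      # centered 20%-stencil truncation error is bounded by (h^2/6) max|f'''|
      # over the stencil span (h = 0.1); bound |f'''| by dense third
      # differences across [lv[k] - 0.1, lv[k] + 0.1]
      hh <- 2.5e-3
      xs <- seq(max(0, lv[k] - 0.1), min(1, lv[k] + 0.1), by = hh)
      fs <- vapply(xs, pm_at, 0)
      d3 <- max(abs(diff(fs, differences = 3))) / hh^3
      tol <- 1.5 * (0.1^2 / 6) * d3 / pm[1] + 1e-8
      expect_lt(abs(beta[k] - oracle), tol)
    }
  }
})

test_that("G ratio follows its molar definition with masking", {
  # hand example: (10 - 4)/3 = 2
  inv <- box_inventory(A = 10, TN = 3)
  st <- sia_equilibrium(inv, scenario_spec(0, 0), box_params(s_fix = 2))
  gf <- g_ratio(st)
  expect_equal(as.vector(gf$g), rep(2, length(gf$g)), tolerance = 1e-12)
  # free ammonia equal to total nitrate -> G = 1
  st1 <- sia_equilibrium(box_inventory(A = 7, TN = 3),
                         scenario_spec(0, 0), box_params(s_fix = 2))
  expect_equal(as.vector(g_ratio(st1)$g), rep(1, 16), tolerance = 1e-12)
  # ammonia exactly neutralizing sulfate -> G = 0
  st0 <- sia_equilibrium(box_inventory(A = 4, TN = 3),
                         scenario_spec(0, 0), box_params(s_fix = 2))
  expect_equal(as.vector(g_ratio(st0)$g), rep(0, 16), tolerance = 1e-12)
  # zero total nitrate -> masked, not infinite
  stm <- sia_equilibrium(box_inventory(A = 4, TN = 0),
                         scenario_spec(0, 0), box_params(s_fix = 1))
  expect_true(all(is.na(g_ratio(stm)$g)))
})

test_that("G moves the right way under controls and flags unreliable months", {
  inv <- small_inventory()
  p <- chem_params()
  g_of <- function(x, y) g_ratio(sia_equilibrium(inv, scenario_spec(x, y), p))$g
  g0 <- g_of(0, 0)
  ok <- is.finite(g0)
  expect_true(all(g_of(0.3, 0)[ok] < g0[ok]))   # strictly decreasing in NH3 cuts
  # increasing in NOx cuts wherever free ammonia is positive (G > 0);
  # where ammonia cannot even neutralize sulfate, G is negative and the
  # direction reverses with the shrinking denominator
  pos <- ok & g0 > 0
  expect_true(all(g_of(0, 0.3)[pos] > g0[pos]))
  p_dry <- chem_params(eps = c(Jan = 0.95, Apr = 0.9, Jul = 0.04, Oct = 0.85))
  st <- sia_equilibrium(inv, scenario_spec(0, 0), p_dry)
  expect_equal(g_ratio(st, params = p_dry)$unreliable_months, "Jul")
})

test_that("molar normalization rescales by total molar emissions", {
  b <- instant_efficiency(interpolate_levels(c(0, 0.3, 0.6, 0.8, 1),
                                             10 - 2 * c(0, 0.3, 0.6, 0.8, 1)))
  m1 <- molar_normalize(b, 2e9)
  expect_equal(m1$beta, b$beta / 2e9)
  # doubling one species' molar total halves its molar beta relative ranking
  m2 <- molar_normalize(b, 4e9)
  expect_equal(m1$beta / m2$beta, rep(2, 11))
  expect_error(molar_normalize(b, 0), "emi_total_molN")
  inv <- box_inventory(A = 1, TN = 1)
  expect_equal(molar_emissions(inv, "NH3"), sum(inv$e_nh3) * 1e12 / 14)
})

test_that("tipping points interpolate the first sign change", {
  lv <- seq(0, 1, 0.1)
  tp <- tipping_point(seq(-0.1, 0.1, length.out = 11), criterion = "beta_equal")
  expect_equal(tp$reduction, 0.5)
  tp2 <- tipping_point(rep(-1, 11), criterion = "beta_equal")
  expect_true(tp2$unreachable)
  expect_error(tipping_point(c(NA, rep(1, 10))), "NaN")
  # first crossing from the 0% side is reported when several exist
  s <- c(-1, 1, -1, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(tipping_point(s)$reduction, 0.05)
})

test_that("G-based tipping point matches a brute-force scan of the surrogate", {
  inv <- box_inventory(A = 0.2, TN = 0.06)
  p <- box_params(s_fix = 0.02, sharpness = Inf)
  g_at <- function(x) {
    st <- sia_equilibrium(inv, scenario_spec(x, 0), p)
    g_ratio(st)$g[1, 1]
  }
  lv <- seq(0, 1, 0.1)
  tp <- tipping_point(vapply(lv, g_at, 0) - 1, criterion = "g_equal_one")
  xs <- seq(0, 1, by = 0.001)
  brute <- xs[which(vapply(xs, g_at, 0) <= 1 + 1e-9)[1]]
  # G is linear in x here, so interpolation lands within one scan step
  expect_lt(abs(tp$reduction - brute), 0.0011)
})

test_that("the per-mole equivalence point of the sharp-min surrogate is G = 1", {
  eq <- g_equivalence_point()
  expect_equal(eq$g, 1, tolerance = 1e-6)
  eq2 <- g_equivalence_point(s_fix = 0.03, tn = 0.11, ratio_range = c(0.3, 4))
  expect_equal(eq2$g, 1, tolerance = 1e-6)
})
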