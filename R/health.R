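#' GEMM hazard-ratio parameter table
#'
#' Per-age-group parameters of the Global Exposure Mortality Model (GEMM)
#' relative-risk function, plus the counterfactual threshold below which no
#' impact occurs. Parameter values are supplied by the user (e.g. via
#' [read_gemm_params()]); the package ships a synthetic fixture table only.
#'
#' @param table data frame with columns `group`, `theta`, `theta_se`,
#'   `alpha`, `mu`, `upsilon`; one row per age group.
#' @param cf counterfactual threshold, ug/m3 (default 2.4).
#' @return Object of class `nr_gemm` (the validated data frame with `cf`
#'   attribute).
#' @export
gemm_params <- function(table, cf = 2.4) {
  need <- c("group", "theta", "theta_se", "alpha", "mu", "upsilon")
  if (!all(need %in% names(table)))
    stop("GEMM table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(table$alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(table$upsilon <= 0)) stop("upsilon must be > 0", call. = FALSE)
  if (any(table$theta_se < 0)) stop("theta_se must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(cf, "cf", min = 0)
  structure(as.data.frame(table), cf = cf, class = c("nr_gemm", "data.frame"))
}

#' Read GEMM parameters from a delimited text file
#'
#' @param path CSV file with columns `group,theta,theta_se,alpha,mu,upsilon`.
#' @param cf counterfactual threshold, ug/m3.
#' @return an `nr_gemm` table.
#' @export
read_gemm_params <- function(path, cf = 2.4) {
  if (!file.exists(path))
    stop("GEMM parameter file not found: ", path, call. = FALSE)
  gemm_params(utils::read.csv(path, stringsAsFactors = FALSE), cf = cf)
}

#' Synthetic fixture GEMM parameters
#'
#' A 12-age-group parameter table with GEMM-like shape constants and
#' log-hazard scales declining with age. These are synthetic fixture values
#' for testing and examples, not published coefficients.
#'
#' @param cf counterfactual threshold, ug/m3.
#' @return an `nr_gemm` table.
#' @export
gemm_fixture_params <- function(cf = 2.4) {
  path <- system.file("extdata", "gemm_params_synthetic.csv",
                      package = "nrpathways")
  read_gemm_params(path, cf = cf)
}

# Exposure transform shared by all GEMM evaluations: the age-independent
# factor log(z/alpha + 1) * logistic((z - mu)/upsilon), with z = max(0, c - cf).
# RR = exp(theta * gemm_shape(...)), so RR(cf) = exp(0) = 1 exactly.
gemm_shape <- function(c, alpha, mu, upsilon, cf) {
  if (any(c < 0)) stop("PM2.5 concentrations must be >= 0", call. = FALSE)
  z <- pmax(0, c - cf)
  log(z / alpha + 1) / (1 + exp(-(z - mu) / upsilon))
}

#' GEMM relative risk
#'
#' Hazard-ratio function of annual-mean PM2.5 exposure:
#' `RR(c) = exp(theta * log(z/alpha + 1) / (1 + exp(-(z - mu)/upsilon)))`
#' with `z = max(0, c - cf)`, so `RR = 1` for all concentrations at or below
#' the counterfactual threshold and RR is continuous and non-decreasing above
#' it (for `theta >= 0`).
#'
#' @param c annual-mean PM2.5, ug/m3 (vectorized).
#' @param theta log-hazard scale.
#' @param alpha,mu,upsilon shape parameters (ug/m3 scale).
#' @param cf counterfactual threshold, ug/m3.
#' @return relative risk, same length as `c`.
#' @examples
#' relative_risk(10, theta = 0.143, alpha = 1.6, mu = 15.5, upsilon = 36.8)
#' @export
relative_risk <- function(c, theta, alpha, mu, upsilon, cf = 2.4) {
  exp(theta * gemm_shape(c, alpha, mu, upsilon, cf))
}

new_mortality_result <- function(deaths, by_region, by_cell, grid,
                                 ci_low = NA_real_, ci_high = NA_real_,
                                 n_draws = 0L, kind = "attributable") {
  structure(list(deaths = deaths, by_region = by_region, by_cell = by_cell,
                 ci_low = ci_low, ci_high = ci_high, n_draws = n_draws,
                 grid = grid, kind = kind),
            class = "nr_mort")
}

#' @export
print.nr_mort <- function(x, ...) {
  lab <- if (identical(x$kind, "avoided")) "avoided" else "attributable"
  cat(sprintf("PM2.5-%s premature deaths: %.0f per year\n", lab, x$deaths))
  if (x$n_draws > 0)
    cat(sprintf("  95%% CI (%d Monte Carlo draws): %.0f - %.0f\n",
                x$n_draws, x$ci_low, x$ci_high))
  cat(sprintf("  by region: %s\n",
              paste(sprintf("%s %.0f", names(x$by_region), x$by_region),
                    collapse = ", ")))
  invisible(x)
}

check_field_alignment <- function(field, ages) {
  if (length(field) != nrow(ages$pop))
    stop("concentration field and age structure are on different grids",
         call. = FALSE)
  invisible(TRUE)
}

# Deaths per cell for one theta vector (one value per age group). The
# attributable-fraction form Base*Pop*(1 - 1/RR) is the default; the
# as-printed form Base*Pop*(1/RR) is retained for audit only.
deaths_by_cell <- function(field, ages, params, theta = params$theta,
                           as_printed = FALSE) {
  cf <- attr(params, "cf")
  out <- numeric(length(field))
  for (i in seq_len(nrow(params))) {
    k <- gemm_shape(field, params$alpha[i], params$mu[i], params$upsilon[i], cf)
    inv_rr <- exp(-theta[i] * k)
    w <- if (as_printed) inv_rr else 1 - inv_rr
    out <- out + ages$base_rate[, i] * ages$pop[, i] * w
  }
  out
}

sum_by_region <- function(by_cell, grid) {
  vapply(c(West = "West", East = "East"),
         function(r) sum(by_cell[grid$cells$region == r]), 0)
}

#' Attributable premature deaths (point estimate)
#'
#' Annual PM2.5-attributable NCD+LRI deaths,
#' `sum_i Base_i * Pop_i * (1 - 1/RR_i(c))` over age groups and grid cells.
#'
#' @param pm25_annual annual-mean PM2.5 per cell, ug/m3.
#' @param ages an `nr_ages` structure on the same grid.
#' @param params an `nr_gemm` table with one row per age group.
#' @param as_printed if TRUE, use the raw `Base*Pop/RR` form (total rather
#'   than excess mortality; audit switch).
#' @return an `nr_mort` result (no CI).
#' @export
attributable_deaths <- function(pm25_annual, ages, params, as_printed = FALSE) {
  stopifnot(inherits(ages, "nr_ages"), inherits(params, "nr_gemm"))
  if (ncol(ages$pop) != nrow(params))
    stop("GEMM table rows must match age groups", call. = FALSE)
  check_field_alignment(pm25_annual, ages)
  by_cell <- deaths_by_cell(pm25_annual, ages, params, as_printed = as_printed)
  new_mortality_result(sum(by_cell), sum_by_region(by_cell, ages$grid),
                       by_cell, ages$grid)
}

#' Avoided premature deaths of a control scenario
#'
#' Difference of attributable deaths between a base and a scenario
#' concentration field on the same grid; positive wherever the scenario is
#' cleaner.
#'
#' @param base_field,scenario_field annual-mean PM2.5 per cell, ug/m3.
#' @inheritParams attributable_deaths
#' @return an `nr_mort` result (no CI).
#' @export
avoided_deaths <- function(base_field, scenario_field, ages, params) {
  check_field_alignment(base_field, ages)
  check_field_alignment(scenario_field, ages)
  a <- attributable_deaths(base_field, ages, params)
  b <- attributable_deaths(scenario_field, ages, params)
  by_cell <- a$by_cell - b$by_cell
  new_mortality_result(a$deaths - b$deaths, a$by_region - b$by_region,
                       by_cell, ages$grid, kind = "avoided")
}

#' Monte Carlo confidence interval for the health burden
#'
#' Empirical 95% CI obtained by re-evaluating the burden with the log-hazard
#' scale of each age group drawn independently from
#' `Normal(theta, theta_se)`, by default ten thousand times. Only theta is
#' sampled; the shape constants are treated as fixed.
#'
#' @inheritParams avoided_deaths
#' @param scenario_field optional; if supplied the avoided-deaths difference
#'   is sampled, otherwise the attributable burden of `base_field`.
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed.
#' @return an `nr_mort` result with `ci_low`/`ci_high` at the empirical
#'   2.5/97.5 percentiles and the point estimate at the central theta.
#' @export
monte_carlo_ci <- function(base_field, scenario_field = NULL, ages, params,
                           n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(params, "nr_gemm"))
  stop_if_not_scalar_number(n_draws, "n_draws", min = 2)
  n_draws <- as.integer(n_draws)
  check_field_alignment(base_field, ages)
  if (!is.null(scenario_field)) check_field_alignment(scenario_field, ages)
  cf <- attr(params, "cf")
  ng <- nrow(params)

  point <- if (is.null(scenario_field))
    attributable_deaths(base_field, ages, params)
  else avoided_deaths(base_field, scenario_field, ages, params)

  totals <- numeric(n_draws)
  with_seed(seed, {
    thetas <- matrix(stats::rnorm(n_draws * ng, mean = rep(params$theta, each = n_draws),
                                  sd = rep(params$theta_se, each = n_draws)),
                     nrow = n_draws, ncol = ng)
    for (i in seq_len(ng)) {
      bp <- ages$base_rate[, i] * ages$pop[, i]
      k_base <- gemm_shape(base_field, params$alpha[i], params$mu[i],
                           params$upsilon[i], cf)
      # deaths_i(theta) = sum_cell bp * (1 - exp(-theta k)); matrix over draws
      contrib <- colSums(bp * (1 - exp(-outer(k_base, thetas[, i]))))
      if (!is.null(scenario_field)) {
        k_scen <- gemm_shape(scenario_field, params$alpha[i], params$mu[i],
                             params$upsilon[i], cf)
        contrib <- contrib -
          colSums(bp * (1 - exp(-outer(k_scen, thetas[, i]))))
      }
      totals <- totals + contrib
    }
  })
  ci <- unname(stats::quantile(totals, c(0.025, 0.975), type = 7))
  new_mortality_result(point$deaths, point$by_region, point$by_cell,
                       ages$grid, ci_low = ci[1], ci_high = ci[2],
                       n_draws = n_draws, kind = point$kind)
}
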