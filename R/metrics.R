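#' N-share field: fraction of PM2.5 attributable to reactive nitrogen
#'
#' Relative change of PM2.5 with versus without anthropogenic Nr emissions,
#' `(pm_base - pm_noNr) / pm_base`, per cell.
#'
#' @param pm_base,pm_noNr aligned annual-mean PM2.5 fields, ug/m3; `pm_base`
#'   must be strictly positive.
#' @return numeric per-cell fraction.
#' @export
n_share <- function(pm_base, pm_noNr) {
  if (length(pm_base) != length(pm_noNr))
    stop("fields are not aligned", call. = FALSE)
  if (any(pm_base <= 0))
    stop("base PM2.5 must be > 0 in every cell", call. = FALSE)
  (pm_base - pm_noNr) / pm_base
}

#' Area-weighted regional N-share
#'
#' @inheritParams n_share
#' @param grid an `nr_domain` aligned with the fields.
#' @param region `"West"`, `"East"` or `"all"`.
#' @return scalar area-weighted mean N-share.
#' @export
regional_n_share <- function(pm_base, pm_noNr, grid, region = "all") {
  sel <- if (identical(region, "all")) rep(TRUE, grid$n_cell)
         else grid$cells$region == region
  area_weighted_mean(n_share(pm_base, pm_noNr), grid$cells$area, sel)
}

#' Fraction of regional area meeting the annual WHO guideline
#'
#' Area-weighted fraction of region cells whose annual mean PM2.5 lies
#' strictly below the guideline value (default: the updated annual guideline
#' of 5 ug/m3).
#'
#' @param annual_field annual-mean PM2.5 per cell, ug/m3.
#' @param grid an `nr_domain`.
#' @param region `"West"`, `"East"` or `"all"`.
#' @param guideline annual guideline, ug/m3.
#' @return fraction in \[0, 1\].
#' @export
annual_guideline_achievement <- function(annual_field, grid, region = "all",
                                         guideline = 5) {
  sel <- if (identical(region, "all")) rep(TRUE, grid$n_cell)
         else grid$cells$region == region
  if (!any(sel)) stop("empty region", call. = FALSE)
  area_weighted_mean(as.numeric(annual_field < guideline), grid$cells$area, sel)
}

#' Fraction of days exceeding the daily WHO guideline
#'
#' Share of a regional-mean daily PM2.5 series lying strictly above the
#' guideline (default: daily guideline of 15 ug/m3). The threshold is
#' applied to the regional-mean series, not per cell.
#'
#' @param daily_regional_means numeric series of daily regional means, ug/m3.
#' @param guideline daily guideline, ug/m3.
#' @return fraction of days in \[0, 1\].
#' @export
daily_exceedance_fraction <- function(daily_regional_means, guideline = 15) {
  if (length(daily_regional_means) == 0L)
    stop("empty daily series", call. = FALSE)
  mean(daily_regional_means > guideline)
}

#' Synthesize a daily regional-mean PM2.5 series
#'
#' Daily values are drawn as lognormal fluctuations around each monthly
#' regional mean with a configurable coefficient of variation, exercising
#' the daily-guideline logic without a transport model. Each represented
#' month stands for its season (here: ~91 days per month).
#'
#' @param monthly_means named regional-mean PM2.5 per month (Jan/Apr/Jul/Oct).
#' @param cv day-to-day coefficient of variation.
#' @param days_per_month days simulated per represented month.
#' @param seed integer seed.
#' @return numeric daily series of length `4 * days_per_month`.
#' @export
synth_daily_series <- function(monthly_means, cv = 0.4, days_per_month = 91L,
                               seed = 1L) {
  stopifnot(all(NR_MONTHS %in% names(monthly_means)))
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    unlist(lapply(NR_MONTHS, function(m) {
      mu <- log(monthly_means[[m]]) - sdlog^2 / 2  # mean-preserving
      stats::rlnorm(days_per_month, meanlog = mu, sdlog = sdlog)
    }), use.names = FALSE)
  })
}

#' Required emission reduction to meet the annual guideline, per cell
#'
#' For each grid cell, the minimal control fraction under which the annual
#' mean drops strictly below the guideline, found by bisection on a
#' monotone response function; cells that remain at or above the guideline
#' even at 100% control are flagged unreachable (NA) with
#' `unreachable = TRUE`.
#'
#' @param response function mapping a control fraction in \[0, 1\] to the
#'   per-cell annual-mean PM2.5 field (monotone non-increasing in the
#'   control fraction).
#' @param guideline annual guideline, ug/m3.
#' @param tol bisection tolerance on the control fraction.
#' @return data frame with `required` (fraction, NA if unreachable) and
#'   `unreachable` (logical) per cell.
#' @export
required_reduction_map <- function(response, guideline = 5, tol = 1e-3) {
  f0 <- response(0)
  f1 <- response(1)
  n <- length(f0)
  if (any(f1 > f0 + 1e-9))
    stop("response is not monotone non-increasing in the control fraction",
         call. = FALSE)
  required <- rep(NA_real_, n)
  unreachable <- rep(FALSE, n)
  required[f0 < guideline] <- 0          # already attaining
  unreachable[f1 >= guideline] <- TRUE   # hopeless even at phase-out
  todo <- which(is.na(required) & !unreachable)
  for (i in todo) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (response(mid)[i] < guideline) hi <- mid else lo <- mid
    }
    required[i] <- hi  # smallest fraction known to attain, within tol
  }
  data.frame(required = required, unreachable = unreachable)
}
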