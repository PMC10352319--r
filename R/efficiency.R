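#' Interpolate scenario PM2.5 onto the 10% control-level grid
#'
#' Builds the response curve used by the instant-efficiency stencils:
#' a shape-preserving piecewise cubic (PCHIP) through the simulated control
#' levels (typically 0/30/60/80/100%), evaluated on the 11-level grid
#' 0%, 10%, ..., 100%. Emissions are linear in the control level by
#' construction.
#'
#' @param levels simulated reduction fractions (>= 4 distinct values,
#'   including 0, sorted or sortable).
#' @param pm PM2.5 at each simulated level (regional mean or one cell),
#'   ug/m3.
#' @param base_emi baseline emissions of the controlled species, Tg N/yr.
#' @return Object of class `nr_curve`: `levels` (0..1 by 0.1), `pm_at_level`,
#'   `emi_at_level`, `base_pm`, `base_emi`, and the knots.
#' @export
interpolate_levels <- function(levels, pm, base_emi = 1) {
  if (length(levels) != length(pm)) stop("levels/pm length mismatch", call. = FALSE)
  ord <- order(levels)
  levels <- levels[ord]; pm <- pm[ord]
  if (anyDuplicated(levels)) stop("duplicate control levels", call. = FALSE)
  if (length(levels) < 4L) stop("need >= 4 distinct levels", call. = FALSE)
  if (levels[1] != 0) stop("levels must include the uncontrolled base (0)", call. = FALSE)
  grid <- seq(0, 1, by = 0.1)
  pm_i <- pracma::pchip(levels, pm, pmin(grid, max(levels)))
  if (max(levels) < 1) pm_i[grid > max(levels)] <- NA_real_
  structure(list(levels = grid, pm_at_level = pm_i,
                 emi_at_level = base_emi * (1 - grid),
                 base_pm = pm[1], base_emi = base_emi,
                 knot_levels = levels, knot_pm = pm),
            class = "nr_curve")
}

#' Instant efficiency of emission controls (beta)
#'
#' Percent PM2.5 decrease per 1% emission decrease, evaluated on the
#' 11-level control grid: a forward difference at level 1 (0%), centered
#' differences at levels 2..10, and a backward difference at level 11
#' (100%). Each difference of PM2.5-decrease fractions is divided by the
#' matching difference of emission-decrease fractions, which for emissions
#' linear in level is the 10% (one-sided) or 20% (centered) level gap.
#'
#' @param curve an `nr_curve` from [interpolate_levels()].
#' @return Object of class `nr_beta`: `levels` and `beta` (%/%) vectors.
#' @export
instant_efficiency <- function(curve) {
  stopifnot(inherits(curve, "nr_curve"))
  if (curve$base_emi <= 0) stop("zero emission denominator", call. = FALSE)
  lv <- curve$levels
  n <- length(lv)
  dpm <- (curve$base_pm - curve$pm_at_level) / curve$base_pm   # decrease fraction
  demi <- lv                                                   # linear emissions
  beta <- numeric(n)
  beta[1] <- (dpm[1] - dpm[2]) / (demi[1] - demi[2])
  for (k in 2:(n - 1))
    beta[k] <- (dpm[k - 1] - dpm[k + 1]) / (demi[k - 1] - demi[k + 1])
  beta[n] <- (dpm[n - 1] - dpm[n]) / (demi[n - 1] - demi[n])
  structure(list(levels = lv, beta = beta), class = "nr_beta")
}

#' @export
print.nr_beta <- function(x, ...) {
  df <- data.frame(level = x$levels, beta = round(x$beta, 4))
  cat("Instant efficiency (% PM2.5 per % emission):\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Convert an efficiency series from a per-percent to a per-mole basis
#'
#' Divides the mass-based beta (%/%) by the species' total molar nitrogen
#' emissions so that cross-species comparisons are per mole of N removed
#' rather than per percent of each species' own total.
#'
#' @param beta an `nr_beta`.
#' @param emi_total_molN total species emissions, mol N.
#' @return an `nr_beta` on the per-mole scale (`basis = "molar"`).
#' @export
molar_normalize <- function(beta, emi_total_molN) {
  stopifnot(inherits(beta, "nr_beta"))
  stop_if_not_scalar_number(emi_total_molN, "emi_total_molN", min = 0,
                            strict_min = TRUE)
  out <- beta
  out$beta <- beta$beta / emi_total_molN
  out$basis <- "molar"
  out
}

#' Total molar nitrogen emissions of an inventory
#'
#' @param inv an `nr_inventory`.
#' @param species `"NH3"` or `"NOx"`.
#' @return mol N per year (emissions are in Tg N; 14 g N per mol).
#' @export
molar_emissions <- function(inv, species = c("NH3", "NOx")) {
  species <- match.arg(species)
  tg <- if (species == "NH3") sum(inv$e_nh3) else sum(inv$e_nox)
  tg * 1e12 / 14
}

#' G ratio: free ammonia over total nitrate (molar)
#'
#' `G = ([NH3] + [NH4+] - 2 [SO4]) / ([HNO3] + [NO3-])`, elementwise in
#' umol/m3. G > 1 marks an HNO3-limited regime (NOx cuts bite), G < 1 an
#' NH3-limited regime. Cells where total nitrate falls below a tiny
#' threshold are masked (NA) rather than returned as infinities. The
#' diagnostic is flagged unreliable for months whose ammonium-nitrate yield
#' `eps` is below 0.05 (hot/dry conditions with little nitrate aerosol).
#'
#' @param state an `nr_species`.
#' @param level vertical layer.
#' @param denom_tiny masking threshold on total nitrate, umol/m3.
#' @param params optional `nr_chem_params` used to flag unreliable months.
#' @return Object of class `nr_gfield`: matrix `g` (cells x months), the
#'   grid, and `unreliable_months`.
#' @export
g_ratio <- function(state, level = 1L, denom_tiny = 1e-9, params = NULL) {
  stopifnot(inherits(state, "nr_species"))
  num <- state$nh3[, , level] + state$nh4[, , level] - 2 * state$so4[, , level]
  den <- state$hno3[, , level] + state$no3[, , level]
  g <- num / den
  g[den <= denom_tiny] <- NA_real_
  unrel <- character(0)
  if (!is.null(params)) unrel <- NR_MONTHS[params$eps < 0.05]
  structure(list(g = g, grid = state$grid, unreliable_months = unrel),
            class = "nr_gfield")
}

#' Area-weighted regional mean (and spatial sd) of the G ratio
#'
#' @param gf an `nr_gfield`.
#' @param region `"West"`, `"East"` or `"all"`.
#' @return list with `mean` and `sd` of the annual-mean per-cell G.
#' @export
regional_g <- function(gf, region = "all") {
  cells <- gf$grid$cells
  sel <- if (identical(region, "all")) rep(TRUE, nrow(cells))
         else cells$region == region
  gcell <- rowMeans(gf$g, na.rm = TRUE)
  ok <- sel & is.finite(gcell)
  list(mean = area_weighted_mean(gcell[ok], cells$area[ok]),
       sd = stats::sd(gcell[ok]))
}

#' Locate a control-level tipping point by sign-change interpolation
#'
#' Finds the first reduction level (from the 0% side) at which a diagnostic
#' series crosses zero, by linear interpolation between adjacent levels of
#' the 11-level grid. Used with `beta_NH3 - beta_NOx` (efficiency criterion)
#' or `G - 1` (regime criterion). If the series never changes sign on
#' \[0, 100%\] the tipping point is unreachable.
#'
#' @param series numeric values on the 11-level grid (e.g. beta difference
#'   or G minus one).
#' @param levels control fractions matching `series`.
#' @param criterion label stored on the result (`"beta_equal"` or
#'   `"g_equal_one"`).
#' @return Object of class `nr_tipping`: `reduction` (fraction, NA if
#'   unreachable), `unreachable`, `criterion`.
#' @export
tipping_point <- function(series, levels = seq(0, 1, by = 0.1),
                          criterion = c("beta_equal", "g_equal_one")) {
  criterion <- match.arg(criterion)
  if (length(series) != length(levels)) stop("series/levels mismatch", call. = FALSE)
  if (anyNA(series)) stop("NaN-contaminated series", call. = FALSE)
  s <- sign(series)
  red <- NA_real_
  if (s[1] == 0) {
    red <- levels[1]
  } else {
    for (k in seq_len(length(series) - 1)) {
      if (s[k + 1] == 0) { red <- levels[k + 1]; break }
      if (s[k] * s[k + 1] < 0) {
        red <- levels[k] + (levels[k + 1] - levels[k]) *
          abs(series[k]) / (abs(series[k]) + abs(series[k + 1]))
        break
      }
    }
  }
  structure(list(reduction = red, unreachable = is.na(red),
                 criterion = criterion),
            class = "nr_tipping")
}

#' @export
print.nr_tipping <- function(x, ...) {
  if (x$unreachable)
    cat(sprintf("Tipping point (%s): not reached within 0-100%% controls\n",
                x$criterion))
  else
    cat(sprintf("Tipping point (%s): %.1f%% reduction\n",
                x$criterion, 100 * x$reduction))
  invisible(x)
}

#' Per-mole NH3/NOx equivalence point of the sharp-min surrogate
#'
#' Single-cell diagnostic: with the exact minimum, unit nitrate yield and
#' fully neutralized sulfate, sweep the base free-ammonia to total-nitrate
#' ratio and locate (by bisection on the sign change of the sensitivity
#' difference) the point where equal per-mole perturbations of total ammonia
#' and of total nitrate produce equal PM2.5 changes. Returns the G ratio at
#' that point; analytically the crossing sits exactly at G = 1, where the
#' ammonium-nitrate minimum switches between its two arguments.
#'
#' @param s_fix sulfate, umol/m3 (ammonia availability always exceeds
#'   2*s_fix in the sweep so sulfate stays fully neutralized).
#' @param tn total nitrate availability, umol/m3.
#' @param ratio_range sweep range of the free-ammonia/total-nitrate ratio.
#' @param h finite-difference step, umol/m3.
#' @param tol bisection tolerance on the ratio.
#' @return list: `g` (the G ratio at the equivalence point), `ratio`, and
#'   the sensitivity difference bracket.
#' @export
g_equivalence_point <- function(s_fix = 0.01, tn = 0.05,
                                ratio_range = c(0.2, 5), h = 1e-6,
                                tol = 1e-9) {
  pm_mass <- function(A, TN) {
    # sharp-min box model, eps = 1: PM = 96 s + 62 no3 + 18 nh4
    fa <- pmax(0, A - 2 * s_fix)
    no3 <- pmin(fa, TN)
    nh4 <- pmin(A, 2 * s_fix) + no3
    MW_SO4 * s_fix + MW_NO3 * no3 + MW_NH4 * nh4
  }
  sens_diff <- function(ratio) {
    A <- 2 * s_fix + ratio * tn          # free ammonia = ratio * TN
    dA <- (pm_mass(A + h, tn) - pm_mass(A - h, tn)) / (2 * h)
    dTN <- (pm_mass(A, tn + h) - pm_mass(A, tn - h)) / (2 * h)
    dA - dTN
  }
  lo <- ratio_range[1]; hi <- ratio_range[2]
  if (sens_diff(lo) <= 0 || sens_diff(hi) >= 0)
    stop("sweep range does not bracket the equivalence point", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sens_diff(mid) > 0) lo <- mid else hi <- mid
  }
  ratio <- (lo + hi) / 2
  A <- 2 * s_fix + ratio * tn
  g <- (A - 2 * s_fix) / tn              # Eq.-6 G with fully neutralized sulfate
  list(g = g, ratio = ratio, bracket = c(sens_diff(lo), sens_diff(hi)))
}
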