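#' Chemistry parameters for the SIA equilibrium surrogate
#'
#' Parameters of the closed-form secondary-inorganic-aerosol (SIA) response
#' used in place of a full chemistry-transport model. The surrogate encodes
#' the regime structure that drives NH3/NOx control effectiveness: ammonia
#' first neutralizes sulfate, the remaining free ammonia forms ammonium
#' nitrate against the available total nitrate, and deeper NOx cuts have a
#' diminishing nitrate yield through an oxidant-curvature exponent.
#'
#' @param a_tot total-ammonia availability coefficient, umol/m3 per unit NH3
#'   emission density (Tg N/yr/km2).
#' @param n_tot total-nitrate availability coefficient, same emission-density
#'   units for NOx.
#' @param p_ox oxidant-curvature exponent (>= 1); values above 1 make the
#'   marginal HNO3 response shrink as NOx cuts deepen.
#' @param s_fix sulfate concentration, umol/m3, unaffected by Nr controls.
#' @param eps ammonium-nitrate yield in (0, 1], one value per represented
#'   month (Jan, Apr, Jul, Oct); low summer values reflect nitrate volatility.
#' @param sharpness smooth-minimum parameter (1/(umol/m3)); `Inf` gives the
#'   exact minimum (kinked but analytically transparent), finite values give
#'   kink-free response surfaces for interpolation and gradient work.
#' @param level_decay_nh3,level_decay_nox,level_decay_bg exponential decay
#'   rates of ammonia/nitrate availability and background aerosol per vertical
#'   layer above the surface.
#' @return Object of class `nr_chem_params`.
#' @export
chem_params <- function(a_tot = 1.55e5, n_tot = 4.3e4, p_ox = 1.6,
                        s_fix = 0.012,
                        eps = c(Jan = 0.95, Apr = 0.90, Jul = 0.35, Oct = 0.85),
                        sharpness = 150,
                        level_decay_nh3 = 0.6, level_decay_nox = 0.3,
                        level_decay_bg = 0.4) {
  stop_if_not_scalar_number(a_tot, "a_tot", min = 0)
  stop_if_not_scalar_number(n_tot, "n_tot", min = 0)
  stop_if_not_scalar_number(p_ox, "p_ox", min = 1)
  stop_if_not_scalar_number(s_fix, "s_fix", min = 0)
  if (length(eps) == 1L) eps <- stats::setNames(rep(eps, 4), NR_MONTHS)
  if (!all(NR_MONTHS %in% names(eps)))
    stop("'eps' must be named with months Jan, Apr, Jul, Oct", call. = FALSE)
  eps <- eps[NR_MONTHS]
  if (any(eps <= 0) || any(eps > 1)) stop("'eps' must lie in (0, 1]", call. = FALSE)
  if (!(is.infinite(sharpness) || sharpness > 0))
    stop("'sharpness' must be positive or Inf", call. = FALSE)
  structure(list(a_tot = a_tot, n_tot = n_tot, p_ox = p_ox, s_fix = s_fix,
                 eps = eps, sharpness = sharpness,
                 level_decay_nh3 = level_decay_nh3,
                 level_decay_nox = level_decay_nox,
                 level_decay_bg = level_decay_bg),
            class = "nr_chem_params")
}

# Smooth minimum with sharpness k (Inf = exact min). Always <= min(a, b);
# clamped at zero so nitrate can never go negative for small free ammonia.
smoothmin <- function(a, b, sharpness) {
  if (is.infinite(sharpness)) return(pmin(a, b))
  lo <- pmin(a, b)
  m <- lo - log1p(exp(-sharpness * abs(a - b))) / sharpness
  pmax(0, m)
}

#' Scenario specification on the (NH3, NOx) control plane
#'
#' @param x fraction of NH3 emissions removed, in \[0, 1\].
#' @param y fraction of NOx emissions removed, in \[0, 1\].
#' @param label scenario label (e.g. "Base", "S3R60").
#' @return Object of class `nr_scenario`.
#' @export
scenario_spec <- function(x, y, label = sprintf("x%.0f_y%.0f", 100 * x, 100 * y)) {
  stop_if_not_scalar_number(x, "x", min = 0)
  stop_if_not_scalar_number(y, "y", min = 0)
  if (x > 1 || y > 1) stop("control fractions must lie in [0, 1]", call. = FALSE)
  structure(list(x = x, y = y, label = label), class = "nr_scenario")
}

# Molecular weights (g/mol) for the molar-to-mass assembly of PM2.5.
MW_SO4 <- 96
MW_NO3 <- 62
MW_NH4 <- 18

#' Evaluate the SIA equilibrium surrogate for one control scenario
#'
#' Closed-form per-cell/month/level species state under NH3 reduction `x` and
#' NOx reduction `y`. Total ammonia availability is
#' `A = a_tot * nh3_density * (1 - x)`; total nitrate is
#' `TN = n_tot * nox_density * (1 - y)^p_ox`. Ammonia neutralizes sulfate
#' first (`nh4_sulfate = min(A, 2 s_fix)`); the remaining free ammonia
#' `FA = max(0, A - 2 s_fix)` forms aerosol nitrate
#' `no3 = eps * smoothmin(FA, TN)`. PM2.5 is the background mass plus
#' `96 so4 + 62 no3 + 18 nh4`.
#'
#' @param inv an `nr_inventory`.
#' @param spec an `nr_scenario`.
#' @param params an `nr_chem_params`.
#' @return Object of class `nr_species`: arrays `[cell, month, level]` for
#'   `nh3`, `nh4`, `so4`, `hno3`, `no3` (umol/m3), `background_mass` and
#'   `pm25` (ug/m3), plus the generating `spec` and the grid.
#' @export
sia_equilibrium <- function(inv, spec, params) {
  stopifnot(inherits(inv, "nr_inventory"), inherits(spec, "nr_scenario"),
            inherits(params, "nr_chem_params"))
  grid <- inv$grid
  n <- grid$n_cell
  nm <- length(NR_MONTHS)
  nl <- grid$n_level
  dims <- c(n, nm, nl)
  dn <- list(NULL, NR_MONTHS, NULL)
  arr <- function() array(0, dims, dimnames = dn)
  out <- list(nh3 = arr(), nh4 = arr(), so4 = arr(), hno3 = arr(),
              no3 = arr(), background_mass = arr(), pm25 = arr())

  dens_nh3 <- inv$e_nh3 / grid$cells$area
  dens_nox <- inv$e_nox / grid$cells$area
  soa_mult <- c(Jan = 2, Apr = 2, Jul = 3, Oct = 2)

  for (lev in seq_len(nl)) {
    fa_lev <- exp(-params$level_decay_nh3 * (lev - 1))
    fn_lev <- exp(-params$level_decay_nox * (lev - 1))
    fb_lev <- exp(-params$level_decay_bg * (lev - 1))
    s_lev <- params$s_fix * fn_lev
    for (m in seq_along(NR_MONTHS)) {
      mon <- NR_MONTHS[m]
      A <- params$a_tot * dens_nh3 * inv$monthly_factor[mon, "nh3"] *
        (1 - spec$x) * fa_lev
      TN <- params$n_tot * dens_nox * inv$monthly_factor[mon, "nox"] *
        (1 - spec$y)^params$p_ox * fn_lev
      nh4_sulf <- pmin(A, 2 * s_lev)
      FA <- pmax(0, A - 2 * s_lev)
      no3 <- params$eps[[mon]] * smoothmin(FA, TN, params$sharpness)
      nh4 <- nh4_sulf + no3
      bg <- (inv$bc + inv$oc * (1 + soa_mult[[mon]]) + inv$dust + inv$seasalt) *
        fb_lev
      out$nh3[, m, lev] <- A - nh4
      out$nh4[, m, lev] <- nh4
      out$so4[, m, lev] <- s_lev
      out$hno3[, m, lev] <- TN - no3
      out$no3[, m, lev] <- no3
      out$background_mass[, m, lev] <- bg
      out$pm25[, m, lev] <- bg + MW_SO4 * s_lev + MW_NO3 * no3 + MW_NH4 * nh4
    }
  }
  out$spec <- spec
  out$grid <- grid
  class(out) <- "nr_species"
  out
}

#' @export
print.nr_species <- function(x, ...) {
  cat(sprintf("SIA species state for scenario %s (x=%.2f, y=%.2f)\n",
              x$spec$label, x$spec$x, x$spec$y))
  cat(sprintf("  surface annual-mean PM2.5: West %.2f, East %.2f ug/m3\n",
              regional_mean(x, "West"), regional_mean(x, "East")))
  invisible(x)
}

#' Annual-mean field of a species variable
#'
#' Arithmetic mean over the four represented months (the package's annual
#' convention) at one vertical level.
#'
#' @param state an `nr_species`.
#' @param var variable name (default `"pm25"`).
#' @param level vertical layer (default surface).
#' @return numeric vector, one value per grid cell.
#' @export
annual_mean <- function(state, var = "pm25", level = 1L) {
  stopifnot(inherits(state, "nr_species"), var %in% names(state)[1:7])
  rowMeans(state[[var]][, , level, drop = FALSE][, , 1])
}

#' Area-weighted regional mean of a species variable
#'
#' @inheritParams annual_mean
#' @param region `"West"`, `"East"` or `"all"`.
#' @return scalar regional annual mean.
#' @export
regional_mean <- function(state, region = "all", var = "pm25", level = 1L) {
  cells <- state$grid$cells
  sel <- if (identical(region, "all")) rep(TRUE, nrow(cells))
         else cells$region == region
  area_weighted_mean(annual_mean(state, var, level), cells$area, sel)
}

#' Generate the scenario ensemble
#'
#' Evaluates the surrogate for the Base scenario plus three control groups at
#' the given reduction levels: joint NH3+NOx cuts, NOx-only cuts and NH3-only
#' cuts (the S1/S2/S3 design). The default levels 30/60/80/100% give the
#' 13-member ensemble the downstream response-surface analysis expects.
#'
#' @param inv an `nr_inventory`.
#' @param params an `nr_chem_params`.
#' @param levels reduction fractions in (0, 1].
#' @return Object of class `nr_ensemble`: `specs` (data frame label/x/y),
#'   named list `states` of `nr_species`, and the generating inputs.
#' @export
generate_scenario_ensemble <- function(inv, params = chem_params(),
                                       levels = c(0.3, 0.6, 0.8, 1.0)) {
  if (any(levels <= 0) || any(levels > 1))
    stop("scenario levels must lie in (0, 1]", call. = FALSE)
  if (anyDuplicated(levels)) stop("duplicate scenario levels", call. = FALSE)
  lv <- sort(levels)
  pct <- function(l) sprintf("%.0f", 100 * l)
  specs <- list(scenario_spec(0, 0, "Base"))
  for (l in lv) specs <- c(specs, list(scenario_spec(l, l, paste0("S1R", pct(l)))))
  for (l in lv) specs <- c(specs, list(scenario_spec(0, l, paste0("S2R", pct(l)))))
  for (l in lv) specs <- c(specs, list(scenario_spec(l, 0, paste0("S3R", pct(l)))))
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate scenario specs", call. = FALSE)

  states <- lapply(specs, function(s) sia_equilibrium(inv, s, params))
  names(states) <- labels
  structure(list(specs = data.frame(label = labels,
                                    x = vapply(specs, `[[`, 0, "x"),
                                    y = vapply(specs, `[[`, 0, "y")),
                 states = states, inv = inv, params = params,
                 levels = lv),
            class = "nr_ensemble")
}

#' @export
print.nr_ensemble <- function(x, ...) {
  cat(sprintf("Nr control scenario ensemble: %d members (levels %s)\n",
              nrow(x$specs), paste(100 * x$levels, collapse = "/")))
  pm <- vapply(x$states, regional_mean, 0)
  df <- cbind(x$specs, pm25_mean = round(pm, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Regional-mean PM2.5 along one control ray of an ensemble
#'
#' Convenience extractor: the regional-mean PM2.5 at each level of one group
#' (joint, NOx-only or NH3-only), ordered by reduction level and including
#' the Base point.
#'
#' @param ens an `nr_ensemble`.
#' @param mode `"Nr"` (joint), `"NOx"` or `"NH3"`.
#' @param region region passed to [regional_mean()].
#' @param level vertical layer.
#' @return data frame with `level` (reduction fraction) and `pm25`.
#' @export
ensemble_ray <- function(ens, mode = c("Nr", "NOx", "NH3"), region = "all",
                         level = 1L) {
  mode <- match.arg(mode)
  sel <- switch(mode,
                Nr = ens$specs$x == ens$specs$y,
                NOx = ens$specs$x == 0,
                NH3 = ens$specs$y == 0)
  specs <- ens$specs[sel, , drop = FALSE]
  red <- pmax(specs$x, specs$y)
  ord <- order(red)
  pm <- vapply(specs$label[ord],
               function(lb) regional_mean(ens$states[[lb]], region, "pm25", level), 0)
  data.frame(level = red[ord], pm25 = unname(pm))
}
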