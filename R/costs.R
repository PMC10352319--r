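# Shape-preserving C1 quadratic spline (Schumaker-style) through convex
# increasing data: knot slopes are secant-weighted averages (so they
# interlace the secants), and each interval gets one or two quadratic
# pieces. Convexity and monotonicity of the data are preserved exactly --
# pracma's piecewise cubics preserve monotonicity only, which is not enough
# for marginal-cost curves. Returns a vectorized evaluator.
convex_quad_spline <- function(t, z) {
  n <- length(t)
  h <- diff(t)
  delta <- diff(z) / h
  d <- numeric(n)
  if (n > 2)
    for (i in 2:(n - 1))
      d[i] <- (h[i] * delta[i - 1] + h[i - 1] * delta[i]) / (h[i - 1] + h[i])
  d[1] <- max(0, (3 * delta[1] - d[2]) / 2)
  if (d[1] > delta[1]) d[1] <- delta[1]
  d[n] <- (3 * delta[n - 1] - d[n - 1]) / 2
  # per-interval pieces: (start, slope, half-curvature) segments
  segs <- list()
  for (i in seq_len(n - 1)) {
    t1 <- t[i]; t2 <- t[i + 1]; z1 <- z[i]
    s1 <- d[i]; s2 <- d[i + 1]; dl <- delta[i]; hh <- h[i]
    if (abs(s1 + s2 - 2 * dl) < 1e-12 * max(1, abs(dl))) {
      segs[[length(segs) + 1]] <- c(t1, t2, z1, s1, (s2 - s1) / (2 * hh))
    } else {
      xi <- if ((s1 - dl) * (s2 - dl) >= 0) (t1 + t2) / 2
            else if (abs(s2 - dl) < abs(s1 - dl)) t1 + hh * (s2 - dl) / (s2 - s1)
            else t2 + hh * (s1 - dl) / (s2 - s1)
      xi <- min(max(xi, t1 + 1e-12), t2 - 1e-12)
      al <- xi - t1; be <- t2 - xi
      sbar <- (2 * (z[i + 1] - z1) - (al * s1 + be * s2)) / hh
      zxi <- z1 + al * (s1 + sbar) / 2
      segs[[length(segs) + 1]] <- c(t1, xi, z1, s1, (sbar - s1) / (2 * al))
      segs[[length(segs) + 1]] <- c(xi, t2, zxi, sbar, (s2 - sbar) / (2 * be))
    }
  }
  starts <- vapply(segs, `[`, 0, 1)
  function(x) {
    vapply(x, function(xx) {
      k <- findInterval(xx, starts, rightmost.closed = TRUE)
      k <- max(1L, min(k, length(segs)))
      sg <- segs[[k]]
      u <- xx - sg[1]
      sg[3] + sg[4] * u + sg[5] * u^2
    }, 0)
  }
}

#' Construct a marginal-abatement cost curve from anchors
#'
#' Smooth, strictly increasing, (weakly) convex annual-cost curve on
#' reductions \[0, 0.5\], passing through the supplied anchor points. Between
#' anchors the curve is a convexity-preserving C1 quadratic spline; beyond
#' the last anchor it continues linearly at the spline's end slope -- the
#' mildest convex continuation, reflecting that cost data above currently
#' feasible levels are an extrapolation.
#'
#' @param reduction anchor reduction fractions (must include 0).
#' @param cost anchor annual costs, billion euro per year (0 at reduction 0,
#'   strictly increasing, convex).
#' @param species,region labels carried as metadata.
#' @return Object of class `nr_costcurve`; evaluate with `predict()`.
#' @export
cost_curve <- function(reduction, cost, species = "NH3", region = "West") {
  if (length(reduction) != length(cost) || length(reduction) < 2L)
    stop("need matching anchor vectors of length >= 2", call. = FALSE)
  ord <- order(reduction)
  reduction <- reduction[ord]; cost <- cost[ord]
  if (anyDuplicated(reduction)) stop("duplicate anchor reductions", call. = FALSE)
  if (reduction[1] != 0 || cost[1] != 0)
    stop("anchors must include the zero-cost origin (0, 0)", call. = FALSE)
  if (any(diff(cost) <= 0))
    stop("anchor costs must be strictly increasing (non-monotone anchors)",
         call. = FALSE)
  slopes <- diff(cost) / diff(reduction)
  if (any(diff(slopes) < -1e-9))
    stop("anchor costs must be convex in reduction", call. = FALSE)
  spline_fun <- if (length(reduction) >= 3L) convex_quad_spline(reduction, cost)
                else function(x) stats::approx(reduction, cost, x)$y
  end_slope <- if (length(reduction) >= 3L) {
    eps <- 1e-7 * diff(range(reduction))
    (spline_fun(max(reduction)) - spline_fun(max(reduction) - eps)) / eps
  } else slopes[length(slopes)]
  structure(list(reduction = reduction, cost = cost,
                 spline_fun = spline_fun, end_slope = end_slope,
                 species = species, region = region),
            class = "nr_costcurve")
}

#' @export
predict.nr_costcurve <- function(object, reduction, ...) {
  r <- reduction
  if (any(r < 0 | r > 0.5 + 1e-12))
    stop("cost curves are defined on reductions [0, 0.5] only", call. = FALSE)
  r <- pmin(r, 0.5)
  rmax <- max(object$reduction)
  out <- numeric(length(r))
  inside <- r <= rmax
  if (any(inside)) out[inside] <- object$spline_fun(r[inside])
  if (any(!inside)) {
    cmax <- object$cost[length(object$cost)]
    out[!inside] <- cmax + object$end_slope * (r[!inside] - rmax)
  }
  out
}

#' @export
print.nr_costcurve <- function(x, ...) {
  cat(sprintf("Cost curve %s/%s: %d anchors, cost(%.0f%%) = %.2f B euro/yr\n",
              x$region, x$species, length(x$reduction),
              100 * max(x$reduction), max(x$cost)))
  invisible(x)
}

#' Generate cost curves for both species in a region
#'
#' @param anchors named list with elements `NH3` and `NOx`, each a data frame
#'   or list with `reduction` and `cost` anchor vectors (including the
#'   origin).
#' @param region region label.
#' @return named list of two `nr_costcurve` objects.
#' @export
generate_cost_curves <- function(anchors, region = "West") {
  stopifnot(all(c("NH3", "NOx") %in% names(anchors)))
  out <- lapply(c(NH3 = "NH3", NOx = "NOx"), function(sp) {
    a <- anchors[[sp]]
    cost_curve(a$reduction, a$cost, species = sp, region = region)
  })
  # calibration requirement: NH3 abatement is cheaper than NOx at equal depth
  probe <- seq(0.05, 0.5, by = 0.05)
  if (any(predict(out$NH3, probe) >= predict(out$NOx, probe)))
    warning("NH3 cost curve is not uniformly below the NOx curve", call. = FALSE)
  out
}

#' Bundled Western-Europe calibration anchors
#'
#' Published GAINS-style calibration values for a Western-Europe-like region:
#' feasible-technology cost points (29% NH3 at 0.8, 16% NOx at 3.7 billion
#' euro/yr), the 10%/30% control-cost points (NH3 0.08/1.1, NOx 1.1/12.7
#' billion euro/yr) used for the cost-effectiveness diagram, and the
#' regional-mean PM2.5 abatements along each single-species control ray
#' (NH3: 0.11/0.40/1.03/2.51 ug/m3 at 10/30/60/100%; NOx: 0.23/0.67 ug/m3 at
#' 10/30%).
#'
#' @return list with `cost_anchors` (for the cost-effectiveness analysis),
#'   `feasible_anchors` (feasible-scenario points), and `abatement` ray knots
#'   (reduction fraction vs PM2.5 decrease from base, ug/m3).
#' @export
west_europe_calibration <- function() {
  list(
    region = "West",
    cost_anchors = list(
      NH3 = list(reduction = c(0, 0.10, 0.30), cost = c(0, 0.08, 1.1)),
      NOx = list(reduction = c(0, 0.10, 0.30), cost = c(0, 1.1, 12.7))),
    feasible_anchors = list(
      NH3 = list(reduction = c(0, 0.29), cost = c(0, 0.8)),
      NOx = list(reduction = c(0, 0.16), cost = c(0, 3.7))),
    abatement = list(
      NH3 = list(reduction = c(0, 0.10, 0.30, 0.60, 1.00),
                 drop = c(0, 0.11, 0.40, 1.03, 2.51)),
      NOx = list(reduction = c(0, 0.10, 0.30),
                 drop = c(0, 0.23, 0.67))))
}

#' Western-Europe anchor-calibrated analysis fixture
#'
#' Builds the PM2.5 response surface and cost curves calibrated to the
#' bundled Western-Europe anchors (see [west_europe_calibration()]): the
#' response surface interpolates the published per-ray abatements (additively
#' separable interior, NOx ray continued past its last anchor at constant
#' marginal abatement), and the cost curves pass through the 10%/30%
#' control-cost points. This is the fixture behind the cost-effectiveness
#' diagram and pathway.
#'
#' @param base baseline regional-mean PM2.5, ug/m3 (only differences enter
#'   the cost-effectiveness ratio).
#' @return list with `pm_surface` (an `nr_surface`), `costs`
#'   (an `nr_costsurface`), and `calibration`.
#' @export
west_anchor_fixture <- function(base = 8.0) {
  cal <- west_europe_calibration()
  ab <- cal$abatement
  # continue the NOx abatement ray beyond its last published anchor at the
  # last inter-anchor marginal abatement (constant-return continuation)
  rn <- ab$NOx$reduction; dn <- ab$NOx$drop
  slope <- diff(utils::tail(dn, 2)) / diff(utils::tail(rn, 2))
  rn <- c(rn, 0.6, 1.0)
  dn <- c(dn, utils::tail(dn, 1) + slope * (c(0.6, 1.0) - utils::tail(ab$NOx$reduction, 1)))
  fx <- function(t) pracma::pchip(ab$NH3$reduction, ab$NH3$drop, t)
  fy <- function(t) pracma::pchip(rn, dn, t)
  td <- c(0, 0.3, 0.6, 0.8, 1.0)
  specs <- rbind(
    data.frame(x = ab$NH3$reduction, y = 0, value = base - ab$NH3$drop),
    data.frame(x = 0, y = rn[-1], value = base - dn[-1]),
    data.frame(x = td[-1], y = td[-1],
               value = base - fx(td[-1]) - fy(td[-1])))
  surf <- fit_response_surface(specs$x, specs$y, specs$value)
  curves <- generate_cost_curves(cal$cost_anchors, region = "West")
  list(pm_surface = surf, costs = cost_surface(curves), calibration = cal)
}

#' Bundled Eastern-Europe feasible cost anchors
#'
#' Feasible-technology points for an Eastern-Europe-like region: 31% NH3 at
#' 0.2 and 32% NOx at 1.9 billion euro/yr.
#' @return list in the same layout as [west_europe_calibration()].
#' @export
east_europe_calibration <- function() {
  list(
    region = "East",
    feasible_anchors = list(
      NH3 = list(reduction = c(0, 0.31), cost = c(0, 0.2)),
      NOx = list(reduction = c(0, 0.32), cost = c(0, 1.9))))
}
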