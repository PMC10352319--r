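#' Fit the PM2.5 response surface over the (NH3, NOx) control plane
#'
#' The central fit of the package. Input are regional-mean PM2.5 values at
#' control scenarios lying on the three rays the scenario design covers:
#' the NH3-only axis (y = 0), the NOx-only axis (x = 0) and the joint
#' diagonal (x = y) -- 13 scenarios under the default 30/60/80/100% design.
#' Each ray is interpolated by a shape-preserving piecewise cubic (PCHIP) on
#' the 10% grid; the interior is filled by a transfinite blend
#' `f(x, y) = fx(x) + fy(y) - base + s(m(x, y))`, where `s(t)` is the
#' diagonal residual `fd(t) - fx(t) - fy(t) + base` at the diagonal knots and
#' `m(x, y) = min(x, y)` (the joint-control depth shared by both species).
#' The blend is exact on all three rays (hence at every input scenario),
#' exact everywhere for additively separable responses, and monotone
#' non-increasing whenever the joint-control ray falls at least as fast as
#' each single-species ray; the grid is clipped by running minima as a final
#' safeguard.
#'
#' @param x,y scenario control fractions (NH3, NOx).
#' @param value regional-mean PM2.5 at each scenario, ug/m3 (or another
#'   scalar response).
#' @param step grid spacing of the fitted surface (default 10%).
#' @return Object of class `nr_surface` with `x_grid`, `y_grid`, matrix
#'   `value` (x by y), the ray interpolants and `provenance`.
#' @examples
#' lv <- c(0, 0.3, 0.6, 0.8, 1)
#' f <- function(x, y) 10 - 2 * x^2 - 1.5 * y
#' sp <- rbind(data.frame(x = lv, y = 0), data.frame(x = 0, y = lv[-1]),
#'             data.frame(x = lv[-1], y = lv[-1]))
#' s <- fit_response_surface(sp$x, sp$y, f(sp$x, sp$y))
#' predict(s, 0.25, 0.45)
#' @export
fit_response_surface <- function(x, y, value, step = 0.1) {
  if (!(length(x) == length(y) && length(y) == length(value)))
    stop("x, y, value must have equal length", call. = FALSE)
  on_x <- y == 0
  on_y <- x == 0
  on_d <- abs(x - y) < 1e-12
  if (!all(on_x | on_y | on_d))
    stop("scenarios must lie on the x-axis, y-axis or diagonal", call. = FALSE)

  ray <- function(t, v) {
    ord <- order(t)
    t <- t[ord]; v <- v[ord]
    keep <- !duplicated(t)
    list(t = t[keep], v = v[keep])
  }
  rx <- ray(x[on_x], value[on_x])
  ry <- ray(y[on_y], value[on_y])
  rd <- ray(x[on_d], value[on_d])
  if (rx$t[1] != 0 || ry$t[1] != 0 || rd$t[1] != 0)
    stop("each ray must include the base scenario (0, 0)", call. = FALSE)
  base <- rx$v[1]

  grid <- seq(0, 1, by = step)
  # diagonal residual measured at the diagonal knots themselves, where the
  # ray interpolants are exact; for ray-consistent separable inputs every
  # residual is zero, making the blend exactly separable
  s_knots <- rd$v - (pracma::pchip(rx$t, rx$v, rd$t) +
                       pracma::pchip(ry$t, ry$v, rd$t) - base)
  blend <- function(xv, yv) {
    m <- pmin(xv, yv)
    pracma::pchip(rx$t, rx$v, xv) + pracma::pchip(ry$t, ry$v, yv) - base +
      pracma::pchip(rd$t, s_knots, m)
  }
  val <- outer(grid, grid, blend)

  # clip to monotone non-increasing in both coordinates with the smallest
  # monotone majorant (running maxima from the full-control corner): local
  # dips of the blend are filled upward, so ray and node values -- which
  # dominate their own quadrant for monotone inputs -- are never altered
  ng <- length(grid)
  if (ng > 1) {
    for (j in (ng - 1):1) val[, j] <- pmax(val[, j], val[, j + 1])
    for (i in (ng - 1):1) val[i, ] <- pmax(val[i, ], val[i + 1, ])
  }

  structure(list(x_grid = grid, y_grid = grid, value = val, base = base,
                 rays = list(x = rx, y = ry, d = rd), s_knots = s_knots,
                 step = step, provenance = "interpolated_from_scenarios"),
            class = "nr_surface")
}

#' @export
predict.nr_surface <- function(object, x, y, ...) {
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    stop("control fractions must lie in [0, 1]", call. = FALSE)
  # bilinear interpolation on the monotonized grid: keeps the fitted
  # scenario values exact (they sit on grid nodes) and inherits the
  # monotone clipping, which corrects the raw blend in strongly
  # sub-additive regions
  gx <- object$x_grid; gy <- object$y_grid
  i <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  j <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  tx <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  ty <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  v <- object$value
  v[cbind(i, j)] * (1 - tx) * (1 - ty) +
    v[cbind(i + 1L, j)] * tx * (1 - ty) +
    v[cbind(i, j + 1L)] * (1 - tx) * ty +
    v[cbind(i + 1L, j + 1L)] * tx * ty
}

#' @export
print.nr_surface <- function(x, ...) {
  cat(sprintf("Nr control response surface (%s): %d x %d grid, step %.0f%%\n",
              x$provenance, length(x$x_grid), length(x$y_grid), 100 * x$step))
  cat(sprintf("  base %.3f, full-control value %.3f\n",
              x$base, x$value[length(x$x_grid), length(x$y_grid)]))
  invisible(x)
}

#' @export
summary.nr_surface <- function(object, ...) {
  g <- gradient_field(object)
  cat(sprintf("Response surface: base %.3f, total abatement %.3f\n",
              object$base,
              object$base - object$value[length(object$x_grid),
                                         length(object$y_grid)]))
  cat(sprintf("  initial gradient: d/dx %.4f (NH3), d/dy %.4f (NOx)\n",
              g$gx[1, 1], g$gy[1, 1]))
  invisible(object)
}

#' Gradient field of a response surface
#'
#' Finite-difference gradient on the surface grid: centered differences in
#' the interior, one-sided at the edges -- the same stencil family as the
#' instant-efficiency series, so the axis restrictions of the gradient
#' reproduce the per-axis efficiencies up to the base normalization. For a
#' PM2.5 surface both components are <= 0 (PM2.5 falls as controls deepen);
#' their magnitudes are the NH3/NOx instant efficiencies.
#'
#' @param surface an `nr_surface`.
#' @return Object of class `nr_gradient`: matrices `gx`, `gy` on the grid.
#' @export
gradient_field <- function(surface) {
  stopifnot(inherits(surface, "nr_surface"))
  v <- surface$value
  hx <- diff(surface$x_grid)
  hy <- diff(surface$y_grid)
  if (length(surface$x_grid) < 2L || any(hx <= 0) || any(hy <= 0))
    stop("degenerate surface grid", call. = FALSE)
  n <- nrow(v); m <- ncol(v)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[1, ] <- (v[2, ] - v[1, ]) / hx[1]
  gx[n, ] <- (v[n, ] - v[n - 1, ]) / hx[n - 1]
  if (n > 2) for (i in 2:(n - 1))
    gx[i, ] <- (v[i + 1, ] - v[i - 1, ]) / (hx[i] + hx[i - 1])
  gy[, 1] <- (v[, 2] - v[, 1]) / hy[1]
  gy[, m] <- (v[, m] - v[, m - 1]) / hy[m - 1]
  if (m > 2) for (j in 2:(m - 1))
    gy[, j] <- (v[, j + 1] - v[, j - 1]) / (hy[j] + hy[j - 1])
  structure(list(gx = gx, gy = gy, x_grid = surface$x_grid,
                 y_grid = surface$y_grid),
            class = "nr_gradient")
}

#' Plot a diagnostic diagram: isopleths and gradient arrows
#'
#' Contour plot of the response surface over the control plane with the
#' (negated) gradient drawn as arrows and, optionally, a pathway overlaid.
#'
#' @param x an `nr_surface`.
#' @param path optional `nr_path` to overlay.
#' @param arrow_scale arrow length scaling.
#' @param ... passed to [graphics::contour()].
#' @export
plot.nr_surface <- function(x, path = NULL, arrow_scale = 0.05, ...) {
  graphics::contour(x$x_grid, x$y_grid, x$value,
                    xlab = "NH3 reduction fraction",
                    ylab = "NOx reduction fraction", ...)
  g <- gradient_field(x)
  sc <- arrow_scale / max(abs(c(g$gx, g$gy)), na.rm = TRUE)
  idx <- seq(1, length(x$x_grid), by = 2)
  for (i in idx) for (j in idx) {
    graphics::arrows(x$x_grid[i], x$y_grid[j],
                     x$x_grid[i] - sc * g$gx[i, j],
                     x$y_grid[j] - sc * g$gy[i, j],
                     length = 0.04, col = "steelblue")
  }
  if (!is.null(path))
    graphics::lines(path$nodes$x, path$nodes$y, col = "purple", lwd = 2)
  invisible(x)
}
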