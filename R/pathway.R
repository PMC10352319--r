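#' Greedy steepest-descent control pathway
#'
#' Lattice pathway from the uncontrolled corner (0, 0): at each node the
#' path advances one step in x (NH3) or y (NOx), whichever move lowers the
#' surface more (both moves cost the same control effort, so this is the
#' projected steepest descent). Ties break toward NH3 (x). The path stops at
#' (1, 1) or as soon as no admissible move decreases the surface.
#'
#' @param surface an `nr_surface` (monotone non-increasing PM2.5).
#' @param step control-fraction step (must match the surface grid spacing).
#' @return Object of class `nr_path`: data frame `nodes` with `x`, `y`,
#'   `value` and `cumulative_abatement` per node.
#' @export
steepest_descent_path <- function(surface, step = 0.1) {
  stopifnot(inherits(surface, "nr_surface"))
  gx <- surface$x_grid
  if (!isTRUE(all.equal(diff(gx)[1], step)))
    stop("step must match the surface grid spacing", call. = FALSE)
  v <- surface$value
  n <- nrow(v); m <- ncol(v)
  i <- 1L; j <- 1L
  nodes <- data.frame(x = 0, y = 0, value = v[1, 1])
  repeat {
    cand_x <- if (i < n) v[i + 1L, j] else Inf
    cand_y <- if (j < m) v[i, j + 1L] else Inf
    best <- min(cand_x, cand_y)
    if (!is.finite(best) || best >= v[i, j] - 1e-12) break
    if (cand_x <= cand_y) i <- i + 1L else j <- j + 1L  # tie -> NH3
    nodes <- rbind(nodes, data.frame(x = gx[i], y = surface$y_grid[j],
                                     value = v[i, j]))
  }
  nodes$cumulative_abatement <- nodes$value[1] - nodes$value
  structure(list(nodes = nodes, step = step, kind = "steepest_descent"),
            class = "nr_path")
}

#' @export
print.nr_path <- function(x, ...) {
  last <- x$nodes[nrow(x$nodes), ]
  cat(sprintf("%s pathway: %d steps to (x=%.2f, y=%.2f)\n",
              x$kind, nrow(x$nodes) - 1L, last$x, last$y))
  cat(sprintf("  cumulative abatement %.3f", last$cumulative_abatement))
  if (!is.null(x$nodes$cumulative_cost))
    cat(sprintf(", cumulative cost %.2f B euro/yr", last$cumulative_cost))
  cat("\n")
  invisible(x)
}

# All monotone lattice paths on the first nx x ny nodes of a surface grid,
# as the per-length maximum cumulative abatement (brute-force oracle).
best_lattice_abatement <- function(value, nx, ny) {
  steps <- nx + ny - 2L
  # moves: choose which of the steps go in x; enumerate combinations
  best <- rep(-Inf, steps + 1L)
  best[1] <- 0
  combs <- utils::combn(steps, nx - 1L)
  base <- value[1, 1]
  for (c_i in seq_len(ncol(combs))) {
    xmoves <- logical(steps)
    xmoves[combs[, c_i]] <- TRUE
    i <- 1L; j <- 1L
    for (s in seq_len(steps)) {
      if (xmoves[s]) i <- i + 1L else j <- j + 1L
      ab <- base - value[i, j]
      if (ab > best[s + 1L]) best[s + 1L] <- ab
    }
  }
  best
}

#' Optimality gap of the greedy pathway versus exhaustive enumeration
#'
#' Enumerates every monotone lattice path on the `nx` x `ny` corner of the
#' surface grid and compares, at each path length, the greedy pathway's
#' cumulative abatement with the enumerated optimum. Greedy descent is not
#' globally optimal for increasing-returns surfaces, so the gap is measured
#' and reported rather than assumed to vanish.
#'
#' @param surface an `nr_surface`.
#' @param nx,ny sub-grid size for the enumeration (default 6 x 6).
#' @return list: `gap` (max over path lengths of optimum minus greedy),
#'   `by_length` data frame with greedy and optimal abatement per length.
#' @export
path_optimality_gap <- function(surface, nx = 6L, ny = 6L) {
  v <- surface$value[seq_len(nx), seq_len(ny), drop = FALSE]
  sub <- surface
  sub$value <- v
  sub$x_grid <- surface$x_grid[seq_len(nx)]
  sub$y_grid <- surface$y_grid[seq_len(ny)]
  greedy <- steepest_descent_path(sub, step = sub$step)
  opt <- best_lattice_abatement(v, nx, ny)
  steps <- nx + ny - 2L
  g_ab <- rep(NA_real_, steps + 1L)
  g_ab[seq_len(nrow(greedy$nodes))] <- greedy$nodes$cumulative_abatement
  # a stopped greedy path holds its last abatement
  if (anyNA(g_ab)) g_ab[is.na(g_ab)] <- max(g_ab, na.rm = TRUE)
  by_length <- data.frame(length = 0:steps, greedy = g_ab, optimal = opt)
  list(gap = max(opt - g_ab), by_length = by_length)
}

#' Additive control-cost surface over the control plane
#'
#' `cost(x, y) = cost_NH3(x) + cost_NOx(y)` from a pair of per-species cost
#' curves; defined on reductions up to 50% per species only (cost data above
#' feasible levels are an extrapolation that is hard-capped there).
#'
#' @param curves named list with `NH3` and `NOx` [cost_curve()] objects.
#' @return Object of class `nr_costsurface` with an `eval(x, y)` closure and
#'   the curves.
#' @export
cost_surface <- function(curves) {
  stopifnot(all(c("NH3", "NOx") %in% names(curves)),
            inherits(curves$NH3, "nr_costcurve"),
            inherits(curves$NOx, "nr_costcurve"))
  ev <- function(x, y) {
    if (any(x < 0 | x > 0.5 | y < 0 | y > 0.5))
      stop("cost surface is defined on [0, 0.5] per species only", call. = FALSE)
    predict(curves$NH3, x) + predict(curves$NOx, y)
  }
  structure(list(eval = ev, curves = curves), class = "nr_costsurface")
}

#' Cost-effectiveness surface: cumulative cost per unit PM2.5 abated
#'
#' Ratio of cumulative control cost to cumulative PM2.5 decrease from the
#' base state, on the \[0, 0.5\] x \[0, 0.5\] control grid. The ratio is
#' undefined (NA) at the origin and wherever abatement is zero; such nodes
#' with nonzero cost are masked with a warning.
#'
#' @param pm_surface an `nr_surface` (PM2.5).
#' @param costs an `nr_costsurface`.
#' @param step grid spacing.
#' @return an `nr_surface` whose `value` is the cost/abatement ratio
#'   (billion euro per ug/m3), with `provenance = "cost_per_abatement"`.
#' @export
cost_effectiveness_surface <- function(pm_surface, costs, step = 0.1) {
  grid <- seq(0, 0.5, by = step)
  ab <- outer(grid, grid, function(x, y)
    pm_surface$base - predict(pm_surface, x, y))
  cc <- outer(grid, grid, costs$eval)
  ratio <- cc / ab
  zero_ab <- ab <= 1e-12
  if (any(zero_ab & cc > 1e-12 & row(ab) + col(ab) > 2))
    warning("zero abatement with nonzero cost; nodes masked", call. = FALSE)
  ratio[zero_ab] <- NA_real_
  structure(list(x_grid = grid, y_grid = grid, value = ratio,
                 abatement = ab, cost = cc, base = NA_real_, step = step,
                 provenance = "cost_per_abatement"),
            class = "nr_surface")
}

#' Cost-optimal control pathway
#'
#' Greedy lattice pathway from (0, 0) on the \[0, 0.5\] control plane,
#' following the lowest isopleths of the cost/PM2.5-abatement diagram: each
#' step takes the move (one step of NH3 or of NOx control) with the lowest
#' incremental cost per incremental microgram abated. The path stops when
#' the best remaining move is no better than a move it previously passed
#' over -- once extending the path requires an option that was already
#' rejected in favor of cheaper abatement, the efficient frontier of the
#' diagram has been exhausted (in the anchor-calibrated fixtures this is
#' the forced switch to the other species at a species cap).
#'
#' @param pm_surface an `nr_surface` (PM2.5 on \[0, 1\]^2; only \[0, 0.5\]^2
#'   is used).
#' @param costs an `nr_costsurface`.
#' @param step control step (default 10%).
#' @return an `nr_path` whose nodes carry `cumulative_cost` and
#'   `cumulative_abatement`.
#' @export
cost_optimal_path <- function(pm_surface, costs, step = 0.1) {
  x <- 0; y <- 0
  base <- predict(pm_surface, 0, 0)
  nodes <- data.frame(x = 0, y = 0, cumulative_abatement = 0,
                      cumulative_cost = 0)
  min_rejected <- Inf
  repeat {
    cand <- list()
    if (x + step <= 0.5 + 1e-12) cand$x <- c(min(x + step, 0.5), y)
    if (y + step <= 0.5 + 1e-12) cand$y <- c(x, min(y + step, 0.5))
    if (length(cand) == 0L) break
    last <- nodes[nrow(nodes), ]
    score <- vapply(cand, function(p) {
      dab <- (base - predict(pm_surface, p[1], p[2])) - last$cumulative_abatement
      dcc <- costs$eval(p[1], p[2]) - last$cumulative_cost
      if (dab <= 1e-12) Inf else dcc / dab
    }, 0)
    k <- which.min(score)  # ties resolve to the first candidate (NH3)
    if (!is.finite(score[k])) break
    if (score[k] >= min_rejected - 1e-12) break
    if (length(score) > 1L)
      min_rejected <- min(min_rejected, score[-k])
    p <- cand[[k]]
    x <- p[1]; y <- p[2]
    nodes <- rbind(nodes, data.frame(
      x = x, y = y,
      cumulative_abatement = base - predict(pm_surface, x, y),
      cumulative_cost = costs$eval(x, y)))
  }
  structure(list(nodes = nodes, step = step, kind = "cost_optimal"),
            class = "nr_path")
}
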