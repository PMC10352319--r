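# Shared fixtures, built in code at test time.

# Small default-calibration domain: fast but heterogeneous enough to carry
# regional contrasts.
small_domain <- function(n_lat = 6, n_lon = 8, n_level = 1, seed = 11) {
  generate_domain(n_lat, n_lon, n_level, seed = seed)
}

small_inventory <- function(grid = small_domain(), seed = 12) {
  generate_emissions(grid, seed = seed)
}

# Single-cell "box" inventory with unit conversion factors so that the
# ammonia/nitrate availabilities equal chosen values directly:
# a_tot = n_tot = 1 and emission density A (resp. TN) per cell, flat monthly
# factors, zero background unless requested.
box_inventory <- function(A, TN, bg = 0) {
  grid <- generate_domain(2, 2, seed = 1)
  n <- grid$n_cell
  mf <- matrix(1, 4, 2, dimnames = list(c("Jan", "Apr", "Jul", "Oct"),
                                        c("nh3", "nox")))
  structure(list(grid = grid,
                 e_nh3 = rep(A, n) * grid$cells$area,
                 e_nox = rep(TN, n) * grid$cells$area,
                 total_nh3 = sum(rep(A, n) * grid$cells$area),
                 total_nox = sum(rep(TN, n) * grid$cells$area),
                 monthly_factor = mf,
                 bc = rep(bg, n), oc = rep(0, n), dust = rep(0, n),
                 seasalt = rep(0, n), seed = 1L),
            class = "nr_inventory")
}

box_params <- function(s_fix = 0, eps = 1, sharpness = Inf, p_ox = 1) {
  chem_params(a_tot = 1, n_tot = 1, p_ox = p_ox, s_fix = s_fix,
              eps = eps, sharpness = sharpness)
}

# One-cell age structure for hand-computable burden arithmetic.
unit_ages <- function(grid, pop_per_cell, base_rate, n_groups = 1) {
  n <- grid$n_cell
  structure(list(pop = matrix(pop_per_cell, n, n_groups),
                 base_rate = matrix(base_rate, n, n_groups),
                 grid = grid, total_pop = sum(pop_per_cell) * n,
                 seed = 0L),
            class = "nr_ages")
}

# GEMM table with n identical groups (convenient for closure tests).
flat_gemm <- function(theta = 0.143, theta_se = 0, n = 1, cf = 2.4) {
  gemm_params(data.frame(group = paste0("g", seq_len(n)), theta = theta,
                         theta_se = theta_se, alpha = 1.6, mu = 15.5,
                         upsilon = 36.8), cf = cf)
}

# Separable analytic response surface specs on the three scenario rays.
separable_specs <- function(f, g, base, levels = c(0, 0.3, 0.6, 0.8, 1)) {
  lv <- levels[-1]
  rbind(data.frame(x = levels, y = 0, value = base - f(levels)),
        data.frame(x = 0, y = lv, value = base - g(lv)),
        data.frame(x = lv, y = lv, value = base - f(lv) - g(lv)))
}
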