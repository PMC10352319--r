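#' Age-group labels for the adult population
#'
#' Twelve adult age groups: eleven 5-year intervals from 25-29 through
#' 75-79, plus an open-ended 80+ group. (Thirteen bins would be needed to
#' carry 5-year intervals to 85+; with twelve groups the oldest interval is
#' left open.)
#' @return character vector of length 12.
#' @export
age_group_labels <- function() {
  c(paste(seq(25, 75, 5), seq(29, 79, 5), sep = "-"), "80+")
}

#' Generate a synthetic gridded population and baseline mortality
#'
#' Distributes an adult population total over the grid as a log-normal
#' density field, splits it into the twelve 5-year age groups with a
#' demographically plausible pyramid, and attaches baseline mortality rates
#' for the aggregate of noncommunicable diseases and lower respiratory
#' infections (NCD+LRI) that rise Gompertz-like with age. Rates carry a mild
#' per-cell multiplier, so spatial variation never breaks the within-cell
#' age ordering.
#'
#' @param grid an `nr_domain`.
#' @param total_pop total adult (25+) population, persons.
#' @param seed integer seed.
#' @return Object of class `nr_ages`: matrices `pop` (persons) and
#'   `base_rate` (deaths per person-year), cells x 12 age groups, plus the
#'   grid.
#' @export
generate_population_mortality <- function(grid, total_pop = 3e8, seed = 1L) {
  stopifnot(inherits(grid, "nr_domain"))
  stop_if_not_scalar_number(total_pop, "total_pop", min = 0, strict_min = TRUE)
  n <- grid$n_cell
  groups <- age_group_labels()

  # population pyramid: shares shrink with age
  share <- exp(-0.12 * (seq_len(12) - 1))
  share <- share / sum(share)
  # NCD+LRI baseline mortality, per person-year, rising with age
  rate0 <- 0.002 * exp(0.42 * (seq_len(12) - 1))

  with_seed(seed, {
    dens <- stats::rlnorm(n, meanlog = 0, sdlog = 0.9) * grid$cells$area
    cell_pop <- total_pop * dens / sum(dens)
    pop <- outer(cell_pop, share)
    rate_mult <- stats::runif(n, 0.8, 1.2)
    base_rate <- outer(rate_mult, rate0)
    colnames(pop) <- colnames(base_rate) <- groups
    structure(list(pop = pop, base_rate = base_rate, grid = grid,
                   total_pop = total_pop, seed = as.integer(seed)),
              class = "nr_ages")
  })
}

#' @export
print.nr_ages <- function(x, ...) {
  cat(sprintf("Synthetic age structure: %.3g persons, %d cells x %d age groups\n",
              sum(x$pop), nrow(x$pop), ncol(x$pop)))
  cat(sprintf("  baseline NCD+LRI rate: %.4f (youngest) .. %.3f (85+) per person-year\n",
              mean(x$base_rate[, 1]), mean(x$base_rate[, 12])))
  invisible(x)
}
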