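#' @keywords internal
"_PACKAGE"

# Run expr with a locally seeded RNG, restoring any pre-existing global state.
# All randomness in the package flows through this helper so that every
# generator is reproducible from its explicit `seed` argument and no call
# disturbs the caller's random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

# Area-weighted mean over a logical cell selection.
area_weighted_mean <- function(values, area, select = NULL) {
  if (!is.null(select)) {
    values <- values[select]
    area <- area[select]
  }
  if (length(values) == 0L) stop("empty region in area-weighted mean", call. = FALSE)
  sum(values * area) / sum(area)
}

# Months represented in the synthetic year; their arithmetic mean stands in
# for the annual mean throughout.
NR_MONTHS <- c("Jan", "Apr", "Jul", "Oct")
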