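# Plain-text gridded I/O. Fields travel as long-format CSV with the full
# dimension set (scenario, month, level, lat, lon, variable) and full float
# precision, so a write/read round trip is lossless and locale-independent
# (dot decimal, C numeric formatting).

#' Long-format table of a species state
#'
#' @param state an `nr_species`.
#' @return data frame with columns `scenario`, `month`, `level`, `lat`,
#'   `lon`, `region`, `area`, `variable`, `value`.
#' @export
field_table <- function(state) {
  stopifnot(inherits(state, "nr_species"))
  grid <- state$grid
  vars <- c("nh3", "nh4", "so4", "hno3", "no3", "background_mass", "pm25")
  nl <- grid$n_level
  out <- vector("list", length(vars) * length(NR_MONTHS) * nl)
  k <- 1L
  for (v in vars) for (lev in seq_len(nl)) for (m in seq_along(NR_MONTHS)) {
    out[[k]] <- data.frame(scenario = state$spec$label, month = NR_MONTHS[m],
                           level = lev, lat = grid$cells$lat,
                           lon = grid$cells$lon, region = grid$cells$region,
                           area = grid$cells$area, variable = v,
                           value = state[[v]][, m, lev])
    k <- k + 1L
  }
  do.call(rbind, out)
}

#' Write gridded fields to CSV at full float precision
#'
#' @param table a data frame (e.g. from [field_table()], or several rbound).
#' @param path output file.
#' @export
write_fields_csv <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.numeric, TRUE)
  for (j in which(num)) tab[[j]] <- sprintf("%.17g", tab[[j]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gridded fields written by [write_fields_csv()]
#'
#' @param path CSV file.
#' @param numeric_cols columns parsed back to numeric.
#' @return data frame.
#' @export
read_fields_csv <- function(path,
                            numeric_cols = c("level", "lat", "lon", "area",
                                             "value")) {
  if (!file.exists(path)) stop("no such field file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cc in intersect(numeric_cols, names(df)))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- vapply(df[intersect(numeric_cols, names(df))],
                function(v) anyNA(v), TRUE)
  if (any(bad))
    stop("malformed field file (non-numeric values) in column(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  df
}
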