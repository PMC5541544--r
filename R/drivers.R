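#' Annual fishing effort in tonne-days
#'
#' Effort for each year is the sum over (optionally target-filtered) vessels
#' of vessel tonnage times days at sea. Additive over disjoint vessel
#' subsets.
#'
#' @param records data frame with columns `year`, `vessel_id`, `tonnage_t`,
#'   `days_at_sea`, `target`.
#' @param target_filter optional target class (e.g. `"benthic"`); vessels
#'   with other targets are excluded.
#' @return named numeric series (names = years) of tonne-days.
#' @export
fishing_effort <- function(records, target_filter = NULL) {
  stopifnot(is.data.frame(records),
            all(c("year", "vessel_id", "tonnage_t", "days_at_sea", "target")
                %in% names(records)))
  if (any(records$tonnage_t <= 0)) stop("tonnage must be positive")
  if (any(records$days_at_sea < 0)) stop("days at sea must be non-negative")
  if (!is.null(target_filter)) {
    records <- records[records$target %in% target_filter, , drop = FALSE]
  }
  td <- records$tonnage_t * records$days_at_sea
  out <- tapply(td, records$year, sum)
  setNames(as.numeric(out), names(out))
}

#' Read an effort CSV (`year, vessel_id, tonnage_t, days_at_sea, target`)
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_effort_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("year", "vessel_id", "tonnage_t", "days_at_sea", "target")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("effort table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Aggregated climate index from component series
#'
#' Each component is z-scored against its baseline-interval mean and standard
#' deviation, multiplied by its sign (chosen so negative values correspond to
#' colder conditions), and the index is the sum of the scaled components.
#' The index is linear in its components.
#'
#' @param components named list of named numeric series (names = years), all
#'   covering the baseline.
#' @param baseline inclusive year interval for the z-scoring (default
#'   `c(1981, 2010)`).
#' @param sign_map named numeric vector of +1/-1 per component (default +1).
#' @return list of class `"climate_series"`: `index` (named annual sum over
#'   the common year range), `scaled` (matrix years x components),
#'   `baseline`.
#' @export
climate_index <- function(components, baseline = c(1981L, 2010L),
                          sign_map = NULL) {
  stopifnot(is.list(components), length(components) > 0L)
  if (is.null(sign_map)) {
    sign_map <- setNames(rep(1, length(components)), names(components))
  }
  years <- Reduce(intersect, lapply(components, function(x) as.integer(names(x))))
  years <- sort(years)
  base_years <- as.character(seq.int(baseline[1L], baseline[2L]))
  scaled <- sapply(names(components), function(nm) {
    x <- components[[nm]]
    if (!all(base_years %in% names(x))) {
      stop("baseline years missing in component '", nm, "'")
    }
    mu <- mean(x[base_years]); s <- sd(x[base_years])
    if (s == 0) stop("constant component '", nm, "' over the baseline")
    sign_map[[nm]] * (x[as.character(years)] - mu) / s
  })
  rownames(scaled) <- years
  structure(list(index = setNames(rowSums(scaled), years),
                 scaled = scaled, baseline = baseline),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("climate_series: %d components, years %s-%s, baseline %d-%d\n",
              ncol(x$scaled), rownames(x$scaled)[1L],
              rownames(x$scaled)[nrow(x$scaled)],
              x$baseline[1L], x$baseline[2L]))
  invisible(x)
}

#' Trailing moving average of an annual series
#'
#' Arithmetic mean over the window ending in each year; years with fewer than
#' `window` observations are returned as `NA`.
#'
#' @param x named numeric series (names = years) or plain vector.
#' @param window window length in years.
#' @return series of the same length with leading `NA`s.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (window > n) stop("window longer than series")
  if (window < 1L) stop("window must be >= 1")
  out <- rep(NA_real_, n)
  cs <- cumsum(as.numeric(x))
  out[window:n] <- (cs[window:n] - c(0, cs)[((window:n) - window) + 1L]) / window
  names(out) <- names(x)
  out
}
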