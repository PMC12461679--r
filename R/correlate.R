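## Experiment-vs-computation comparison: per-pH shift tables, trend
## checks, and the measured-vs-computed linear correlation.

#' Correlate measured against computed chemical shifts
#'
#' Ordinary least-squares fit of measured shifts against computed
#' ensemble-averaged shifts for one species, as in a measured-vs-computed
#' correlation plot.  `weighted = TRUE` weights rows by
#' `1 / measuredErr^2` when uncertainties are available.
#'
#' @param table long shift table with columns `pH`, `species`, `measured`,
#'   `computed` (and optionally `measuredErr`), e.g. from
#'   [assembleShiftTable()].
#' @param species species to fit (`"Pi"` or `"PNC"`); `NULL` uses all rows.
#' @param weighted use inverse-variance weights from `measuredErr`.
#' @return list of class `correlationResult`: `slope`, `intercept` (ppm),
#'   `residRMS` (ppm), `n`, and the underlying `fit`.
#' @export
correlateShifts <- function(table, species = NULL, weighted = FALSE) {
  rows <- if (is.null(species)) table else table[table$species == species, ]
  if (nrow(rows) < 2L) stop("need at least 2 rows for a correlation")
  if (stats::var(rows$computed) == 0)
    stop("degenerate abscissa: computed values are all equal")
  w <- NULL
  if (weighted) {
    if (is.null(rows$measuredErr) || any(rows$measuredErr <= 0))
      stop("weighted fit needs positive measuredErr values")
    w <- 1 / rows$measuredErr^2
  }
  fit <- stats::lm(measured ~ computed, data = rows, weights = w)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf["computed"]),
                 intercept = unname(cf["(Intercept)"]),
                 residRMS = sqrt(mean(stats::residuals(fit)^2)),
                 n = nrow(rows), fit = fit),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("correlationResult: slope m = %.3f, intercept = %.3f ppm, residual RMS = %.3g ppm (n = %d)\n",
              x$slope, x$intercept, x$residRMS, x$n))
  invisible(x)
}

#' Check the pH trend of a shift column
#'
#' Verdict on whether the shift moves strictly downfield (increases) with
#' rising pH, and the overall range `delta(max pH) - delta(min pH)`.
#'
#' @param table long shift table (see [correlateShifts()]).
#' @param species species to check; `NULL` uses all rows.
#' @param column which shift column to test (default `"measured"`).
#' @return list: `monotone` (strictly increasing with pH), `range` (ppm),
#'   `values` ordered by pH.
#' @export
trendCheck <- function(table, species = NULL, column = "measured") {
  rows <- if (is.null(species)) table else table[table$species == species, ]
  if (nrow(rows) < 2L) stop("need at least 2 rows for a trend check")
  rows <- rows[order(rows$pH), ]
  v <- rows[[column]]
  list(monotone = all(diff(v) > 0),
       range = v[length(v)] - v[1],
       values = stats::setNames(v, rows$pH))
}

#' Bundle correlation and trend results as a JSON report
#'
#' @param table long shift table.
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
writeCorrelationReport <- function(table, path) {
  rep <- list()
  for (sp in unique(table$species)) {
    co <- correlateShifts(table, sp)
    tr <- trendCheck(table, sp)
    rep[[sp]] <- list(slope = co$slope, intercept = co$intercept,
                      residRMS = co$residRMS, n = co$n,
                      monotone = tr$monotone, range = tr$range)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
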