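#' Read a two-column decay signal file
#'
#' Parses the plain-text dialect used by decay-decomposition programs: two
#' whitespace-separated numeric columns per row — time in seconds, then
#' amplitude in arbitrary units — with the point as decimal mark. Lines
#' beginning with `#` and blank lines are ignored. Rows that fail to parse
#' are never dropped silently: each is reported with its line number.
#'
#' @param file Path or connection to read.
#' @param strict If `TRUE`, amplitudes that are not non-increasing raise an
#'   error (the model assumes the signal amplitude continuously reduces
#'   with time); if `FALSE` (default) a warning is given.
#'
#' @return A [decay_signal()].
#' @examples
#' tf <- tempfile()
#' writeLines(c("0 1.0", "1 0.5", "2 0.25"), tf)
#' read_signal(tf)
#' @export
read_signal <- function(file, strict = FALSE) {
  lines <- readLines(file, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (any(grepl(",", lines, fixed = TRUE)))
    stop_format(sprintf(
      "comma found on line %d: the dialect requires the point as decimal mark and whitespace-separated columns",
      lineno[grepl(",", lines, fixed = TRUE)][1L]))
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  parsed <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f)))
  ok <- ncols == 2L & vapply(parsed, function(p) !anyNA(p) && all(is.finite(p)),
                             logical(1))
  if (any(!ok))
    warning(sprintf("skipped %d unparseable line(s): %s",
                    sum(!ok), paste(lineno[!ok], collapse = ", ")))
  if (sum(ok) < 2L)
    stop_format("fewer than 2 valid data rows")
  times <- vapply(parsed[ok], `[`, numeric(1), 1L)
  amps <- vapply(parsed[ok], `[`, numeric(1), 2L)
  if (any(diff(times) <= 0))
    stop_format("times (column 1) must be strictly increasing")
  if (any(diff(amps) > 0)) {
    msg <- "signal amplitude is not non-increasing; the decay model assumes the amplitude continuously reduces with time"
    if (strict) stop_format(msg) else warning(msg)
  }
  decay_signal(times, amps)
}

#' Write the approximation signal
#'
#' Writes the model prediction on the input time grid in the same
#' two-column text dialect as the input, on the original (unnormalized)
#' amplitude scale, with 9 significant digits. The file round-trips
#' through [read_signal()].
#'
#' @param signal The `decay_signal` that was fitted (supplies the grid).
#' @param result An `expdecomp` fit (or a [decay_model()]).
#' @param file Path or connection to write.
#' @export
write_approximation <- function(signal, result, file) {
  signal <- as_signal(signal)
  if (length(signal$times) < 1L)
    stop_input("empty time grid")
  model <- if (inherits(result, "expdecomp")) result$model else result
  if (!inherits(model, "decay_model"))
    stop_input("`result` must be an expdecomp fit or a decay_model")
  pred <- predict(model, signal$times)
  writeLines(sprintf("%.9g %.9g", signal$times, pred), file)
  invisible(NULL)
}

#' Write the exponential-parameter table
#'
#' Writes a tab-separated table with one row per component: index, weight
#' in original amplitude units, weight as percent of the summed weights
#' (rounded to integers, so the column sums to about 100), and decrement in
#' s^-1, sorted by decreasing decrement. Trailing comment lines report the
#' number of components and the dispersion.
#'
#' @param result An `expdecomp` fit.
#' @param file Path or connection to write.
#' @export
write_parameters <- function(result, file) {
  if (!inherits(result, "expdecomp"))
    stop_input("`result` must be an expdecomp fit")
  tab <- result$components
  lines <- c(
    "component\tweight\tweight_pct\tdecrement",
    sprintf("%d\t%.9g\t%d\t%.9g",
            seq_len(nrow(tab)), tab$weight, round(tab$weight_pct),
            tab$decrement),
    sprintf("# n_components = %d", result$n_components),
    sprintf("# dispersion = %.9g", result$dispersion))
  writeLines(lines, file)
  invisible(NULL)
}
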