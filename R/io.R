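# CSV/JSON input-output.
#
# CSV dialect (fixed): comma delimiter, '.' decimal point, UTF-8, required
# header.  Time series files carry columns `time` and `concentration` plus an
# optional `replicate`.  Fit reports and fitting configurations are JSON.

#' Read a time-concentration series from CSV
#'
#' Expects a header with columns `time` and `concentration` (an optional
#' `replicate` column is preserved).  Rows are sorted by time; replicate rows
#' stay as duplicate times.  Malformed cells are reported with their file
#' line number.
#'
#' @param path path to a CSV file.
#' @return a [conc_series()].
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) {
    stop_biokin("biokin_input_error", sprintf("file not found: %s", path))
  }
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = TRUE),
    error = function(e) stop_biokin("biokin_input_error",
      sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  need <- c("time", "concentration")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_biokin("biokin_input_error", sprintf(
      "%s: missing required column(s): %s", path,
      paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    stop_biokin("biokin_input_error",
                sprintf("%s: no data rows below the header", path))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(trimws(raw[[col]]) %in% c("NA", "")))
    bad <- union(bad, which(is.na(v)))
    if (length(bad)) {
      stop_biokin("biokin_input_error", sprintf(
        "%s: non-numeric '%s' value(s) at line(s) %s", path, col,
        paste(lines[bad], collapse = ", ")))
    }
    v
  }
  time <- num("time")
  conc <- num("concentration")
  neg <- which(time < 0)
  if (length(neg)) {
    stop_biokin("biokin_input_error", sprintf(
      "%s: negative time(s) at line(s) %s", path,
      paste(lines[neg], collapse = ", ")))
  }
  ord <- order(time)
  conc_series(time[ord], conc[ord],
              replicate = if ("replicate" %in% names(raw))
                raw$replicate[ord],
              label = basename(path))
}

#' Write a time-concentration series to CSV
#'
#' Inverse of [read_timeseries_csv()]: the written file reads back as an
#' identical series.
#'
#' @param x a [conc_series()] (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  x <- as_conc_series(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit both biokinetic models and assemble a self-contained report
#'
#' Runs [fit_model()] for each requested model, computes per-model
#' [fit_statistics()] and the cross-model [compare_models()] comparison, and
#' echoes the scenario and configuration so that re-running the report's own
#' inputs reproduces its numbers exactly.
#'
#' @inheritParams fit_model
#' @param models models to fit (default both).
#' @return an object of class `"fit_report"`.
#' @export
fit_report <- function(data, scenario, models = c("OC", "OC-SF"),
                       config = fit_config()) {
  data <- as_conc_series(data)
  models <- vapply(models, model_kind, character(1), USE.NAMES = FALSE)
  fits <- lapply(models, function(m) fit_model(data, m, scenario, config))
  names(fits) <- models
  comparison <- compare_models(data, fits)
  structure(
    list(tool = "biokin",
         version = as.character(utils::packageVersion("biokin")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         scenario = unclass(scenario), config = unclass(config),
         data = as.data.frame(data), fits = fits, comparison = comparison),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("biokin fit report (%s, seed %d)\n", x$timestamp,
              x$config$seed))
  for (f in x$fits) print(f)
  print(x$comparison)
  invisible(x)
}

report_as_list <- function(report) {
  fits <- lapply(report$fits, function(f) {
    list(model = f$model,
         params = unclass(f$params),
         rss = f$rss, fitted_values = f$fitted_values,
         residuals = f$residuals, generations_run = f$generations_run,
         converged = f$converged, seed = f$seed, n = f$n, npar = f$npar)
  })
  cmp <- report$comparison
  list(
    tool = report$tool, version = report$version,
    timestamp = report$timestamp,
    scenario = report$scenario, config = report$config,
    data = report$data, fits = fits,
    comparison = list(
      labels = cmp$labels,
      statistics = lapply(cmp$statistics, unclass),
      aicc_values = cmp$aicc_values, deltas = cmp$deltas,
      weights = cmp$weights, best_index = cmp$best_index,
      best_model = cmp$labels[cmp$best_index], degenerate = cmp$degenerate)
  )
}

#' Write a fit report to JSON
#'
#' @param report a [fit_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read and write fitting configurations as JSON
#'
#' @param config a [fit_config()].
#' @param path a file path.
#' @return `write_fit_config()` returns `path` invisibly;
#'   `read_fit_config()` a [fit_config()].
#' @export
write_fit_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_config
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) {
    stop_biokin("biokin_input_error", sprintf("file not found: %s", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(fit_config, x[intersect(names(x), names(formals(fit_config)))])
}
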