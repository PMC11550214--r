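# Registry of published exposure scenarios.
#
# The bundled JSON file carries, per scenario, the web-tool fitted kinetic
# constants (canonical), the exposure-medium concentration where printed, the
# reported adjusted R-squared, and a literature comparison fit where one was
# published.  Exposure duration and horizon are optional: most source rows do
# not print them (they live in the underlying experimental studies).  The
# registry is read-only at run time; user-defined scenarios belong in a
# separate file loaded with the same schema.

.biokin_env <- new.env(parent = emptyenv())

registry_path <- function() {
  system.file("extdata", "scenarios.json", package = "biokin", mustWork = TRUE)
}

load_registry <- function() {
  if (is.null(.biokin_env$registry)) {
    raw <- jsonlite::read_json(registry_path(), simplifyVector = FALSE)
    recs <- lapply(raw$scenarios, function(r) {
      r$params <- kinetic_params(r$params$k1, r$params$k2, r$params$sf %||% 0)
      structure(r, class = "scenario_record")
    })
    names(recs) <- vapply(recs, function(r) r$id, character(1))
    stopifnot(!anyDuplicated(names(recs)))
    .biokin_env$registry <- recs
  }
  .biokin_env$registry
}

#' List the bundled exposure scenarios
#'
#' One row per registry record: aquatic invertebrates (and zebrafish) exposed
#' to TiO2, SiO2, C60, graphene, graphene oxide and Au nanomaterials, plus
#' the silver case studies (water flea exposed to Ag-NP; earthworm exposed to
#' Ag-NP and AgNO3), each under the OC and/or OC-SF model with the published
#' fitted constants.
#'
#' @return a data frame summarising all records (id, organism, material,
#'   exposure type, model, exposure concentration, k1, k2, SF, reported
#'   adjusted R-squared).
#' @examples
#' head(list_scenarios())
#' @export
list_scenarios <- function() {
  recs <- load_registry()
  data.frame(
    id = names(recs),
    organism = vapply(recs, function(r) r$organism, character(1)),
    material = vapply(recs, function(r) r$material, character(1)),
    exposure_type = vapply(recs, function(r) r$exposure_type, character(1)),
    model = vapply(recs, function(r) r$model, character(1)),
    c_exposure = vapply(recs, function(r) r$c_exposure %||% NA_real_,
                        numeric(1)),
    k1 = vapply(recs, function(r) r$params$k1, numeric(1)),
    k2 = vapply(recs, function(r) r$params$k2, numeric(1)),
    sf = vapply(recs, function(r) r$params$sf, numeric(1)),
    adj_r2_reported = vapply(recs, function(r) r$adj_r2_reported %||% NA_real_,
                             numeric(1)),
    row.names = NULL
  )
}

#' Retrieve one scenario record
#'
#' @param id a scenario slug, as listed by [list_scenarios()].
#' @return the full record (class `"scenario_record"`), including the
#'   published fitted constants, unit labels and, where available, the
#'   literature comparison fit.
#' @examples
#' get_scenario("dmagna-graphene-aqueous-oc")$params
#' @export
get_scenario <- function(id) {
  recs <- load_registry()
  if (!is.character(id) || length(id) != 1L || !(id %in% names(recs))) {
    stop_biokin("biokin_lookup_error", paste0(
      "unknown scenario id", if (is.character(id) && length(id) == 1L)
        sprintf(" '%s'", id) else "",
      "; valid ids:\n  ", paste(names(recs), collapse = "\n  ")))
  }
  recs[[id]]
}

#' @export
print.scenario_record <- function(x, ...) {
  cat(sprintf("%s: %s / %s (%s), %s model\n", x$id, x$organism, x$material,
              x$exposure_type, x$model))
  cat(sprintf("  k1 = %g %s, k2 = %g %s, SF = %g\n", x$params$k1, x$k1_unit,
              x$params$k2, x$k2_unit, x$params$sf))
  if (!is.null(x$c_exposure)) {
    cat(sprintf("  C_exposure = %g %s\n", x$c_exposure, x$c_exposure_unit))
  }
  if (!is.null(x$adj_r2_reported)) {
    cat(sprintf("  reported adjusted R-squared = %g\n", x$adj_r2_reported))
  }
  invisible(x)
}

#' Simulate a registry scenario
#'
#' Convenience wrapper: builds an [exposure_scenario()] from a registry
#' record (filling in the pieces the record does not carry) and evaluates the
#' record's model with its published constants on the analytical-solution
#' grid.
#'
#' @param id a scenario slug.
#' @param t_e exposure end time; defaults to the record's `t_e` when present.
#' @param t_total simulation horizon; defaults to `2 * t_e`.
#' @param dt grid step.
#' @param c_exposure exposure-medium concentration; defaults to the record's
#'   value when present.
#' @param c_org0 initial body burden.
#' @return a [conc_series()] of predictions.
#' @export
scenario_series <- function(id, t_e = NULL, t_total = NULL, dt = NULL,
                            c_exposure = NULL, c_org0 = 0) {
  rec <- get_scenario(id)
  t_e <- t_e %||% rec$t_e
  if (is.null(t_e)) {
    stop_biokin("biokin_config_error",
      sprintf("scenario '%s' does not record an exposure time; supply t_e", id))
  }
  c_exposure <- c_exposure %||% rec$c_exposure
  if (is.null(c_exposure)) {
    stop_biokin("biokin_config_error", sprintf(
      "scenario '%s' does not record an exposure concentration; supply c_exposure",
      id))
  }
  t_total <- t_total %||% rec$t_total %||% (2 * t_e)
  dt <- dt %||% (t_total / 48)
  sc <- exposure_scenario(c_exposure = c_exposure, t_e = t_e,
                          t_total = t_total, dt = dt, c_org0 = c_org0,
                          time_unit = sub("^1/", "", rec$k2_unit),
                          medium_unit = rec$c_exposure_unit)
  simulate_series(rec$model, rec$params, sc)
}
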