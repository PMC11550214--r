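# Closed-form one-compartment biokinetic models.
#
# Uptake phase (0 <= t <= t_e, the transfer time to clean medium):
#   OC:    C(t) = C0 + Cexp * (k1/k2) * (1 - exp(-k2 t))
#   OC-SF: C(t) = C0 + SF*Cexp*k1*t + (1-SF)*Cexp*(k1/k2)*(1 - exp(-k2 t))
# Elimination phase (t > t_e):
#   OC:    C(t) = C0 + Cexp * (k1/k2) * (exp(-k2 (t - t_e)) - exp(-k2 t))
#   OC-SF: C(t) = C0 + SF*Cexp*k1*t_e
#                    + (1-SF)*Cexp*(k1/k2)*(exp(-k2 (t - t_e)) - exp(-k2 t))
#
# Both phases collapse to the single expression
#   C(t) = C0 + SF*Cexp*k1*min(t, t_e)
#             + (1-SF)*Cexp*(k1/k2)*(exp(-k2*max(t - t_e, 0)) - exp(-k2 t))
# because exp(-k2*max(t - t_e, 0)) = 1 on the uptake phase; the evaluators
# below use that form, which also makes continuity at t_e automatic.

#' Model kinds
#'
#' Canonical identifiers for the two biokinetic models: `"OC"` (plain
#' one-compartment, 2 fitted parameters) and `"OC-SF"` (one compartment with
#' a stored fraction, 3 fitted parameters).
#'
#' @param model a model label; the aliases `"oc"`, `"ocsf"`, `"oc_sf"` and
#'   `"oc-sf"` (any case) are accepted.
#' @return `model_kind()` returns the canonical label; `model_npar()` the
#'   number of fitted parameters (2 or 3).
#' @examples
#' model_kind("ocsf")
#' model_npar("OC")
#' @export
model_kind <- function(model) {
  if (!is.character(model) || length(model) != 1L || is.na(model)) {
    stop_biokin("biokin_parameter_error", "model must be a single string")
  }
  key <- gsub("[^a-z]", "", tolower(model))
  switch(key,
    oc = "OC",
    ocsf = "OC-SF",
    stop_biokin("biokin_parameter_error",
      sprintf("unknown model '%s'; expected 'OC' or 'OC-SF'", model))
  )
}

#' @rdname model_kind
#' @export
model_npar <- function(model) {
  if (model_kind(model) == "OC") 2L else 3L
}

#' Kinetic parameters of the one-compartment models
#'
#' @param k1 uptake rate constant (medium mass or volume per organism mass
#'   per time unit), `k1 >= 0`.
#' @param k2 elimination rate constant (per time unit), `k2 > 0`.
#' @param sf dimensionless stored fraction in `[0, 1]`; must be 0 for the OC
#'   model.
#' @return an object of class `"kinetic_params"`.
#' @examples
#' kinetic_params(k1 = 0.196, k2 = 0.033)
#' @export
kinetic_params <- function(k1, k2, sf = 0) {
  if (!is_number(k1) || k1 < 0) {
    stop_biokin("biokin_parameter_error", "k1 must be a finite number >= 0")
  }
  if (!is_number(k2) || k2 <= 0) {
    stop_biokin("biokin_parameter_error", "k2 must be a finite number > 0")
  }
  if (!is_number(sf) || sf < 0 || sf > 1) {
    stop_biokin("biokin_parameter_error", "sf must lie in [0, 1]")
  }
  structure(list(k1 = k1, k2 = k2, sf = sf), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic parameters: k1 = %g, k2 = %g, SF = %g\n",
              x$k1, x$k2, x$sf))
  invisible(x)
}

check_params_for_model <- function(model, params) {
  model <- model_kind(model)
  if (!inherits(params, "kinetic_params")) {
    params <- kinetic_params(params$k1, params$k2, params$sf %||% 0)
  }
  if (model == "OC" && params$sf != 0) {
    stop_biokin("biokin_parameter_error",
                "the OC model has no stored fraction; sf must be 0")
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exposure scenario
#'
#' Describes an uptake/elimination experiment: the organisms sit in a
#' contaminated medium until `t_e`, then in a clean medium until `t_total`.
#' Unit labels are metadata only; no conversion is ever performed, so `k1`
#' and `k2` are interpreted in whatever time and medium units the scenario
#' declares.
#'
#' @param c_exposure concentration in the exposure medium (e.g. mg/L or
#'   mg/kg), `>= 0`.
#' @param t_e exposure end time (transfer to clean medium), `0 < t_e <=
#'   t_total`.
#' @param t_total end of the simulated/observed period.
#' @param dt time step of the analytical solution grid used by
#'   [simulate_series()].
#' @param c_org0 initial concentration in the organism, `>= 0`.
#' @param time_unit,medium_unit free-text unit labels.
#' @return an object of class `"exposure_scenario"`.
#' @examples
#' exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = 1)
#' @export
exposure_scenario <- function(c_exposure, t_e, t_total = 2 * t_e, dt = t_e / 24,
                              c_org0 = 0, time_unit = "hour",
                              medium_unit = "mg/L") {
  if (!is_number(c_exposure) || c_exposure < 0) {
    stop_biokin("biokin_config_error", "c_exposure must be >= 0")
  }
  if (!is_number(c_org0) || c_org0 < 0) {
    stop_biokin("biokin_config_error", "c_org0 must be >= 0")
  }
  if (!is_number(t_e) || t_e <= 0) {
    stop_biokin("biokin_config_error", "t_e must be > 0")
  }
  if (!is_number(t_total) || t_total < t_e) {
    stop_biokin("biokin_config_error", "t_total must be >= t_e")
  }
  if (!is_number(dt) || dt <= 0) {
    stop_biokin("biokin_config_error", "dt must be > 0")
  }
  structure(
    list(c_org0 = c_org0, c_exposure = c_exposure, t_e = t_e,
         t_total = t_total, dt = dt, time_unit = time_unit,
         medium_unit = medium_unit),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    "exposure scenario: C_exposure = %g %s, C_org(0) = %g, t_e = %g, t_total = %g %s (dt = %g)\n",
    x$c_exposure, x$medium_unit, x$c_org0, x$t_e, x$t_total, x$time_unit, x$dt))
  invisible(x)
}

#' Time-concentration series
#'
#' A light container for observed or simulated concentration measurements:
#' a data frame with columns `time` and `concentration` (plus an optional
#' `replicate` column).  Times must be non-decreasing; duplicate times
#' (replicates) are allowed.
#'
#' @param time non-negative, non-decreasing time values.
#' @param concentration concentrations aligned with `time`.
#' @param replicate optional replicate labels aligned with `time`.
#' @param label free-text label stored as an attribute.
#' @return a data frame of class `"conc_series"`.
#' @export
conc_series <- function(time, concentration, replicate = NULL, label = "") {
  if (length(time) != length(concentration) || length(time) < 1L) {
    stop_biokin("biokin_input_error",
                "time and concentration must have equal length >= 1")
  }
  if (!is.numeric(time) || anyNA(time) || any(time < 0)) {
    stop_biokin("biokin_input_error", "times must be non-negative numbers")
  }
  if (is.unsorted(time)) {
    stop_biokin("biokin_input_error", "times must be non-decreasing")
  }
  if (!is.numeric(concentration) || anyNA(concentration)) {
    stop_biokin("biokin_input_error", "concentrations must be numeric")
  }
  if (any(concentration < 0)) {
    warning("series contains negative concentrations (blank-corrected data?)",
            call. = FALSE)
  }
  df <- data.frame(time = as.numeric(time),
                   concentration = as.numeric(concentration))
  if (!is.null(replicate)) {
    if (length(replicate) != length(time)) {
      stop_biokin("biokin_input_error",
                  "replicate must align with time/concentration")
    }
    df$replicate <- replicate
  }
  structure(df, label = label, class = c("conc_series", "data.frame"))
}

as_conc_series <- function(x) {
  if (inherits(x, "conc_series")) return(x)
  if (is.data.frame(x) && all(c("time", "concentration") %in% names(x))) {
    return(conc_series(x$time, x$concentration, x$replicate))
  }
  stop_biokin("biokin_input_error",
              "expected a conc_series or a data frame with time/concentration")
}

# Vectorised kernel shared by the scalar predictor, the grid simulator and
# the GA population evaluator.  `k1`, `k2`, `sf` may be vectors of equal
# length N (one column per parameter set); returns length(t) x N matrix.
oc_kernel <- function(t, k1, k2, sf, c_org0, c_exposure, t_e) {
  decay <- exp(-outer(t, k2))                       # exp(-k2 t)
  resid <- exp(-outer(pmax(t - t_e, 0), k2))        # 1 on the uptake phase
  labile <- sweep(resid - decay, 2L, c_exposure * (1 - sf) * k1 / k2, `*`)
  stored <- outer(pmin(t, t_e), c_exposure * sf * k1)
  c_org0 + stored + labile
}

#' Predict organism concentration under a one-compartment model
#'
#' Evaluates the closed-form solution of the chosen biokinetic model at time
#' `t`.  For `0 <= t <= t_e` the uptake-phase expression is used; for
#' `t > t_e` the elimination-phase expression (the two agree at `t = t_e`).
#'
#' @param model `"OC"` or `"OC-SF"` (see [model_kind()]).
#' @param params a [kinetic_params()] object (for OC, `sf` must be 0).
#' @param scenario an [exposure_scenario()].
#' @param t time value(s), `>= 0`; vectorised.
#' @return predicted concentration(s), same length as `t`.
#' @examples
#' sc <- exposure_scenario(c_exposure = 1, t_e = 1, t_total = 2)
#' predict_concentration("OC", kinetic_params(1, 1), sc, c(1, 2))
#' @export
predict_concentration <- function(model, params, scenario, t) {
  model <- model_kind(model)
  params <- check_params_for_model(model, params)
  if (!is.numeric(t) || length(t) < 1L || anyNA(t)) {
    stop_biokin("biokin_domain_error", "t must be numeric and non-missing")
  }
  if (any(t < 0)) {
    stop_biokin("biokin_domain_error", "negative times are outside the model domain")
  }
  drop(oc_kernel(as.numeric(t), params$k1, params$k2, params$sf,
                 scenario$c_org0, scenario$c_exposure, scenario$t_e))
}

#' Simulate a model on the scenario's analytical-solution grid
#'
#' Evaluates [predict_concentration()] on the grid `0, dt, 2*dt, ...` up to
#' `t_total`; `t_e` is appended when it does not fall on the grid, so the
#' kink at the phase boundary is always represented.
#'
#' @inheritParams predict_concentration
#' @return a [conc_series()] of predictions.
#' @export
simulate_series <- function(model, params, scenario) {
  if (scenario$dt > scenario$t_total) {
    stop_biokin("biokin_config_error", "dt must not exceed t_total")
  }
  grid <- seq(0, scenario$t_total, by = scenario$dt)
  if (scenario$t_e <= scenario$t_total && !any(grid == scenario$t_e)) {
    grid <- sort(c(grid, scenario$t_e))
  }
  conc_series(grid, predict_concentration(model, params, scenario, grid),
              label = sprintf("%s analytical solution", model_kind(model)))
}

#' Steady-state body burden of the OC model
#'
#' The plateau of the uptake phase under prolonged exposure:
#' `c_org0 + c_exposure * k1 / k2`.
#'
#' @inheritParams predict_concentration
#' @return the steady-state concentration.
#' @examples
#' steady_state_burden(kinetic_params(2766.4, 0.064),
#'                     exposure_scenario(c_exposure = 0.25, t_e = 24))
#' @export
steady_state_burden <- function(params, scenario) {
  if (!inherits(params, "kinetic_params")) {
    params <- kinetic_params(params$k1, params$k2, params$sf %||% 0)
  }
  scenario$c_org0 + scenario$c_exposure * params$k1 / params$k2
}
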