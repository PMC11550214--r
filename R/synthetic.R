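# Seeded synthetic two-phase uptake/elimination datasets.
#
# The generator evaluates a biokinetic model on a sampling design and adds
# Gaussian noise, either additive (fixed assay standard deviation in
# concentration units) or proportional (fixed coefficient of variation, the
# default: concentration measurements typically carry multiplicative error).
# Negative simulated values are clipped to zero by default (concentrations
# are physical); the clip count is recorded, and clipping can be disabled for
# statistical-purity recovery experiments.

#' Noise specification for the synthetic-data generator
#'
#' @param kind `"proportional"` (sigma is a coefficient of variation),
#'   `"additive"` (sigma is a standard deviation in concentration units) or
#'   `"none"`.
#' @param sigma noise scale, `>= 0`; ignored when `kind = "none"`.
#' @param replicates measurements per time point (`>= 1`).
#' @param seed integer seed for the noise draws.
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("proportional", "additive", "none"),
                       sigma = 0.05, replicates = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (!is_number(sigma) || sigma < 0) {
    stop_biokin("biokin_config_error", "sigma must be >= 0")
  }
  if (!is_number(replicates) || replicates < 1L ||
      replicates != round(replicates)) {
    stop_biokin("biokin_config_error", "replicates must be an integer >= 1")
  }
  structure(list(kind = kind, sigma = sigma,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default two-phase sampling design
#'
#' Ten uptake-phase points (from 0 to `t_e`) and ten elimination-phase
#' points (from just after `t_e` to `t_total`), evenly spaced -- the layout
#' of a typical regulatory-style toxicokinetic study.
#'
#' @param scenario an [exposure_scenario()].
#' @param n_uptake,n_elimination points per phase.
#' @return a sorted vector of sampling times.
#' @export
default_sample_times <- function(scenario, n_uptake = 10L,
                                 n_elimination = 10L) {
  up <- seq(0, scenario$t_e, length.out = n_uptake)
  el <- scenario$t_e +
    seq_len(n_elimination) / n_elimination * (scenario$t_total - scenario$t_e)
  c(up, el)
}

#' Generate a noisy synthetic time-concentration dataset
#'
#' Evaluates the model at `sample_times` and perturbs each value (per
#' replicate) with seeded Gaussian noise: `pred * (1 + eps)` for proportional
#' noise, `pred + eps` for additive noise, `eps ~ N(0, sigma)`.
#'
#' @inheritParams predict_concentration
#' @param sample_times sampling times within `[0, t_total]`; a warning is
#'   issued when a phase has no samples.
#' @param noise a [noise_spec()].
#' @param clip_negative clip negative simulated values to zero (default);
#'   the number of clipped values is stored in the `"n_clipped"` attribute.
#' @return a [conc_series()] with one row per time point and replicate.
#' @export
generate_dataset <- function(model, params, scenario,
                             sample_times = default_sample_times(scenario),
                             noise = noise_spec(), clip_negative = TRUE) {
  model <- model_kind(model)
  if (length(sample_times) < 1L) {
    stop_biokin("biokin_input_error", "sample_times must be non-empty")
  }
  if (any(sample_times < 0) || any(sample_times > scenario$t_total)) {
    stop_biokin("biokin_input_error",
                "sample_times must lie within [0, t_total]")
  }
  if (!any(sample_times <= scenario$t_e) ||
      !any(sample_times > scenario$t_e)) {
    warning("sampling design does not cover both the uptake and the ",
            "elimination phase", call. = FALSE)
  }
  times <- sort(as.numeric(sample_times))
  pred <- predict_concentration(model, params, scenario, times)
  reps <- noise$replicates
  all_times <- rep(times, each = reps)
  all_pred <- rep(pred, each = reps)
  values <- with_preserved_seed(noise$seed, {
    switch(noise$kind,
      none = all_pred,
      additive = all_pred + stats::rnorm(length(all_pred), 0, noise$sigma),
      proportional = all_pred *
        (1 + stats::rnorm(length(all_pred), 0, noise$sigma))
    )
  })
  n_clipped <- 0L
  if (clip_negative && any(values < 0)) {
    n_clipped <- sum(values < 0)
    values[values < 0] <- 0
    message(sprintf("clipped %d negative simulated value(s) to zero",
                    n_clipped))
  }
  out <- conc_series(all_times, values,
                     replicate = if (reps > 1L) rep(seq_len(reps),
                                                    length(times)),
                     label = sprintf("synthetic %s data", model))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Parameter-recovery study
#'
#' For each of `n_seeds` seeds: generate a noisy dataset from the true model,
#' fit both candidate models by [fit_model()], and compare them with
#' [compare_models()].  Summarises per-parameter bias and median relative
#' error (of the true-model fit) and how often each model wins the Akaike
#' weight.
#'
#' @inheritParams generate_dataset
#' @param true_params the generating [kinetic_params()].
#' @param n_seeds number of replicate datasets.
#' @param config a [fit_config()]; dataset `i` uses noise seed
#'   `noise$seed + i - 1` and fit seed `config$seed + i - 1`.
#' @param models candidate models fitted to every dataset.
#' @return an object of class `"recovery_study"`: `runs` (one row per seed:
#'   estimates, relative errors, Akaike-weight winner) and `summary`
#'   (per-parameter bias and median relative error, per-model selection
#'   frequency).
#' @export
recovery_study <- function(model, true_params, scenario,
                           sample_times = default_sample_times(scenario),
                           noise = noise_spec(), n_seeds = 20L,
                           config = fit_config(),
                           models = c("OC", "OC-SF")) {
  model <- model_kind(model)
  if (!is_number(n_seeds) || n_seeds < 1L) {
    stop_biokin("biokin_config_error", "n_seeds must be >= 1")
  }
  models <- vapply(models, model_kind, character(1), USE.NAMES = FALSE)
  par_names <- c("k1", "k2", if (model == "OC-SF") "sf")
  truth <- unlist(true_params[par_names])

  runs <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    ns <- noise
    ns$seed <- noise$seed + i - 1L
    dat <- generate_dataset(model, true_params, scenario, sample_times, ns)
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    fits <- lapply(models, function(m) fit_model(dat, m, scenario, cfg))
    cmp <- compare_models(dat, fits)
    own <- fits[[match(model, models)]]
    est <- unlist(own$params[par_names])
    rel <- ifelse(truth != 0, (est - truth) / truth, est)
    row <- c(est, rel)
    names(row) <- c(par_names, paste0(par_names, "_rel_err"))
    runs[[i]] <- data.frame(seed = ns$seed, t(row),
                            winner = cmp$labels[cmp$best_index],
                            winner_weight = cmp$weights[cmp$best_index])
  }
  runs <- do.call(rbind, runs)

  rel_cols <- paste0(par_names, "_rel_err")
  summary <- list(
    true_model = model,
    bias = vapply(rel_cols, function(cn) mean(runs[[cn]]), numeric(1)),
    median_rel_error = vapply(rel_cols,
                              function(cn) stats::median(abs(runs[[cn]])),
                              numeric(1)),
    selection_frequency = vapply(models,
                                 function(m) mean(runs$winner == m),
                                 numeric(1))
  )
  names(summary$bias) <- names(summary$median_rel_error) <- par_names
  names(summary$selection_frequency) <- models
  structure(list(runs = runs, summary = summary), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("recovery study, true model %s (%d seeds)\n", s$true_model,
              nrow(x$runs)))
  cat("  median |relative error|:",
      paste(sprintf("%s = %.3g", names(s$median_rel_error),
                    s$median_rel_error), collapse = ", "), "\n")
  cat("  Akaike-weight winner frequency:",
      paste(sprintf("%s = %.2f", names(s$selection_frequency),
                    s$selection_frequency), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical fitting test problems
#'
#' Five fixed estimation problems used to validate the genetic-algorithm
#' fitter against the grid-plus-polish reference fitter: silver-uptake-like
#' OC and OC-SF kinetics (slow elimination over a 48 h exposure), fast
#' graphene-like aqueous kinetics with a large k1, and a slow soil-exposure
#' problem on a day scale; three are noiseless, two carry 5 % proportional
#' noise with fixed seeds.
#'
#' @return a named list of problems, each with elements `data`, `model` and
#'   `scenario`.
#' @export
canonical_fit_problems <- function() {
  p <- list()

  sc_ag <- exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = 1)
  ts12 <- c(seq(6, 48, length.out = 6), seq(56, 96, length.out = 6))
  p$oc_silver_noiseless <- list(
    data = generate_dataset("OC", kinetic_params(0.196, 0.033), sc_ag,
                            ts12, noise_spec("none")),
    model = "OC", scenario = sc_ag)
  p$ocsf_silver_noiseless <- list(
    data = generate_dataset("OC-SF", kinetic_params(0.426, 0.155, 0.086),
                            sc_ag, ts12, noise_spec("none")),
    model = "OC-SF", scenario = sc_ag)

  sc_gr <- exposure_scenario(c_exposure = 0.25, t_e = 24, t_total = 48,
                             dt = 1)
  p$oc_graphene_noisy <- list(
    data = generate_dataset("OC", kinetic_params(2766.4, 0.064), sc_gr,
                            default_sample_times(sc_gr),
                            noise_spec("proportional", 0.05, seed = 101L)),
    model = "OC", scenario = sc_gr)
  p$ocsf_graphene_noisy <- list(
    data = generate_dataset("OC-SF", kinetic_params(4078.8, 0.162, 0.125),
                            sc_gr, default_sample_times(sc_gr),
                            noise_spec("proportional", 0.05, seed = 102L)),
    model = "OC-SF", scenario = sc_gr)

  sc_ew <- exposure_scenario(c_exposure = 10, t_e = 14, t_total = 28,
                             dt = 0.5, time_unit = "day",
                             medium_unit = "mg/kg")
  p$oc_soil_noiseless <- list(
    data = generate_dataset("OC", kinetic_params(0.060, 0.039), sc_ew,
                            default_sample_times(sc_ew), noise_spec("none")),
    model = "OC", scenario = sc_ew)

  p
}
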