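# Goodness-of-fit and information-theoretic model comparison.
#
# R2 = 1 - RSS/TSS; adjusted R2 = 1 - (n-1)/(n-p) * (1 - R2)  (note the
# denominator n-p, the convention this tool follows throughout); the profile
# Gaussian maximum log-likelihood of a least-squares fit,
#   ln L = 0.5 * (-n * (ln 2*pi + 1 - ln n + ln sum(x_i^2))),
# AIC = 2p - 2 ln L, AICc = AIC + 2p(p+1)/(n-p-1), and Akaike weights
#   w_i = exp(-delta_i/2) / sum_k exp(-delta_k/2),  delta_i = AICc_i - min AICc.
# p counts the fitted kinetic parameters only (2 for OC, 3 for OC-SF); the
# error variance is profiled out, not counted.

#' Coefficient of determination
#'
#' `1 - RSS/TSS`; may be negative when the fit is worse than the observed
#' mean.
#'
#' @param observed observed response values (n >= 2, not all identical).
#' @param fitted fitted values aligned with `observed`.
#' @return R-squared.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop_biokin("biokin_input_error",
                "observed and fitted must be aligned, length >= 2")
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    stop_biokin("biokin_degenerate_data_error",
                "all observations identical: TSS = 0, R-squared undefined")
  }
  1 - sum((observed - fitted)^2) / tss
}

#' Adjusted R-squared
#'
#' `1 - (n - 1)/(n - p) * (1 - r2)`, penalising the parameter count with
#' denominator `n - p`.
#'
#' @param r2 coefficient of determination.
#' @param n sample size (`n > p`).
#' @param p number of model parameters.
#' @return adjusted R-squared.
#' @examples
#' adjusted_r_squared(0.9, n = 10, p = 2)  # 0.8875
#' @export
adjusted_r_squared <- function(r2, n, p) {
  if (!is_number(n) || !is_number(p) || n <= p) {
    stop_biokin("biokin_dof_error", "adjusted R-squared requires n > p")
  }
  1 - (n - 1) / (n - p) * (1 - r2)
}

#' Profile Gaussian maximum log-likelihood of a least-squares fit
#'
#' For a nonlinear fit with normally distributed errors, with the error
#' variance profiled out at its maximum-likelihood value `RSS/n`:
#' `0.5 * (-n * (log(2*pi) + 1 - log(n) + log(sum(residuals^2))))`.
#'
#' @param residuals residual vector (observed minus fitted).
#' @param n sample size; defaults to `length(residuals)`.
#' @return the maximised log-likelihood; `Inf` signals the perfect-fit
#'   degeneracy (zero RSS), which callers must handle.
#' @export
gaussian_loglik <- function(residuals, n = length(residuals)) {
  if (!is_number(n) || n < 1L) {
    stop_biokin("biokin_input_error", "n must be a positive integer")
  }
  ss <- sum(residuals^2)
  if (ss == 0) return(Inf)
  0.5 * (-n * (log(2 * pi) + 1 - log(n) + log(ss)))
}

#' Akaike Information Criterion
#'
#' `AIC = 2p - 2 ln(L)`.
#'
#' @param p number of model parameters (`>= 1`).
#' @param loglik maximised log-likelihood.
#' @return the AIC value.
#' @export
aic <- function(p, loglik) {
  if (!is_number(p) || p < 1L) {
    stop_biokin("biokin_input_error", "p must be a positive integer")
  }
  2 * p - 2 * loglik
}

#' Bias-corrected AIC (AICc)
#'
#' `AICc = AIC + 2p(p + 1)/(n - p - 1)`, the small-sample correction
#' recommended whenever `n/p < 40`.
#'
#' @param aic AIC value.
#' @param n sample size (`n > p + 1`).
#' @param p number of model parameters.
#' @return the AICc value.
#' @export
aicc <- function(aic, n, p) {
  if (!is_number(n) || !is_number(p) || n <= p + 1) {
    stop_biokin("biokin_dof_error", "AICc requires n > p + 1")
  }
  aic + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights
#'
#' Normalised evidence `w_i = exp(-delta_i/2) / sum_k exp(-delta_k/2)` with
#' `delta_i = AICc_i - min(AICc)` (the minimum is subtracted for numerical
#' stability; algebraically the same weights).
#'
#' @param aicc_values vector of AICc values, one per candidate model.
#' @return weights summing to 1.
#' @examples
#' akaike_weights(c(10, 12))  # ~ c(0.731, 0.269)
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 1L || !is.numeric(aicc_values) ||
      anyNA(aicc_values) || any(!is.finite(aicc_values))) {
    stop_biokin("biokin_input_error",
                "aicc_values must be a non-empty finite numeric vector")
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit statistics for one model
#'
#' Bundles sample size, parameter count, RSS/TSS, R-squared, adjusted
#' R-squared, profile Gaussian log-likelihood, AIC and AICc for a single
#' fitted model.
#'
#' @param observed observed response values.
#' @param fitted fitted values aligned with `observed`.
#' @param p number of fitted parameters.
#' @return a list of class `"fit_statistics"`.
#' @export
fit_statistics <- function(observed, fitted, p) {
  n <- length(observed)
  rss <- sum((observed - fitted)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- r_squared(observed, fitted)
  ll <- gaussian_loglik(observed - fitted, n)
  a <- aic(p, ll)
  structure(
    list(n = n, p = p, rss = rss, tss = tss, r2 = r2,
         adj_r2 = adjusted_r_squared(r2, n, p), loglik = ll, aic = a,
         aicc = if (is.finite(a)) aicc(a, n, p) else a,
         degenerate = !is.finite(ll)),
    class = "fit_statistics"
  )
}

#' Compare fitted biokinetic models by AICc and Akaike weights
#'
#' Computes [fit_statistics()] for each fit (with `p = 2` for OC and `p = 3`
#' for OC-SF), AICc deltas and Akaike weights across the candidate set, and
#' identifies the best (minimum-AICc) model.  A perfect fit (zero RSS) makes
#' the Gaussian log-likelihood unbounded; such fits are reported as best with
#' the whole weight (split among ties) and flagged `degenerate`.
#'
#' @param data the shared [conc_series()] the models were fitted to.
#' @param fits a list of `"fit_result"` objects from [fit_model()] or
#'   [reference_fit()], all fitted to `data`.
#' @return an object of class `"model_comparison"`: `labels`, `statistics`,
#'   `aicc_values`, `deltas`, `weights`, `best_index`, `degenerate`.
#' @export
compare_models <- function(data, fits) {
  data <- as_conc_series(data)
  if (inherits(fits, "fit_result")) fits <- list(fits)
  if (length(fits) < 1L) {
    stop_biokin("biokin_input_error", "need at least one fit to compare")
  }
  obs <- data$concentration
  stats_list <- lapply(fits, function(f) {
    if (!inherits(f, "fit_result")) {
      stop_biokin("biokin_input_error", "fits must be fit_result objects")
    }
    if (f$n != length(obs)) {
      stop_biokin("biokin_input_error", "all fits must share the same data")
    }
    fit_statistics(obs, f$fitted_values, f$npar)
  })
  labels <- vapply(fits, function(f) f$model, character(1))
  av <- vapply(stats_list, function(s) s$aicc, numeric(1))
  degenerate <- any(!is.finite(av))
  if (degenerate) {
    perfect <- !is.finite(av)
    weights <- ifelse(perfect, 1 / sum(perfect), 0)
    deltas <- ifelse(perfect, 0, Inf)
    best_index <- which(perfect)[1L]
  } else {
    weights <- akaike_weights(av)
    deltas <- av - min(av)
    best_index <- which.min(av)
  }
  structure(
    list(labels = labels, statistics = stats_list, aicc_values = av,
         deltas = deltas, weights = weights, best_index = best_index,
         degenerate = degenerate),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  tab <- data.frame(
    model = x$labels,
    adj_r2 = vapply(x$statistics, function(s) s$adj_r2, numeric(1)),
    aicc = x$aicc_values, delta = x$deltas, weight = x$weights
  )
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("best model: %s%s\n", x$labels[x$best_index],
              if (x$degenerate) " (perfect-fit degeneracy)" else ""))
  invisible(x)
}
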