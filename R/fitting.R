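# Bounded real-coded genetic-algorithm nonlinear least squares.
#
# The estimation problem: given an observed time-concentration series and an
# exposure scenario, find the kinetic parameters (k1, k2 and, for OC-SF, SF)
# minimising the residual sum of squares against the closed-form model.  The
# search runs on a population of real-coded individuals (one gene per
# parameter) inside a bounded box, with tournament selection, single-point
# crossover and a mixed mutation operator, single-threaded so that a fixed
# seed reproduces the fit bit for bit.  The stopping rule is a steady-fitness
# limit: evolution halts once the best residual sum of squares has not
# improved for a fixed number of generations (with a hard generation cap as
# a safety net).

#' Genetic-algorithm fitting configuration
#'
#' Defaults follow the tool's operating point: a population of 1000
#' individuals, a steady-fitness limit of 300 generations and an elimination
#' rate constant bounded in `[0.001, 100]` per time unit (wide enough to
#' cover reported invertebrate elimination kinetics with a large safety
#' margin).  `k1` bounds default to `[0, 1e6]`, comfortably enclosing the
#' largest published uptake constants (~3.1e4), and the stored fraction is
#' confined to `[0, 1]` by definition.
#'
#' Mutation replaces a gene, with probability `resample_fraction`, by a fresh
#' uniform draw from its bounds (global exploration) and otherwise perturbs
#' it with a Gaussian step whose scale is the current population spread of
#' that gene (self-annealing local refinement).
#'
#' @param population_size number of individuals (`>= 2`).
#' @param steady_fitness_generations stop after this many generations without
#'   improvement of the best fitness.
#' @param max_generations hard cap on generations (`>=
#'   steady_fitness_generations`).
#' @param mutation_probability per-gene mutation probability.
#' @param crossover_probability per-pair single-point crossover probability.
#' @param tournament_size selection tournament size.
#' @param resample_fraction share of mutations drawn uniformly from the
#'   bounds rather than by Gaussian perturbation.
#' @param k1_bounds,k2_bounds,sf_bounds closed parameter intervals;
#'   `sf_bounds` must lie within `[0, 1]`.
#' @param seed integer seed driving the whole evolution.
#' @param track_population if `TRUE`, record the range of every gene over all
#'   evaluated individuals (used to audit bound compliance).
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(population_size = 1000L,
                       steady_fitness_generations = 300L,
                       max_generations = 10000L,
                       mutation_probability = 0.2,
                       crossover_probability = 0.5,
                       tournament_size = 3L,
                       resample_fraction = 0.2,
                       k1_bounds = c(0, 1e6),
                       k2_bounds = c(0.001, 100),
                       sf_bounds = c(0, 1),
                       seed = 1L,
                       track_population = FALSE) {
  chk_int <- function(x, lo, what) {
    if (!is_number(x) || x < lo || x != round(x)) {
      stop_biokin("biokin_config_error",
                  sprintf("%s must be an integer >= %d", what, lo))
    }
    as.integer(x)
  }
  population_size <- chk_int(population_size, 2L, "population_size")
  steady_fitness_generations <-
    chk_int(steady_fitness_generations, 1L, "steady_fitness_generations")
  max_generations <- chk_int(max_generations, 1L, "max_generations")
  if (max_generations < steady_fitness_generations) {
    stop_biokin("biokin_config_error",
                "max_generations must be >= steady_fitness_generations")
  }
  chk_prob <- function(x, what) {
    if (!is_number(x) || x < 0 || x > 1) {
      stop_biokin("biokin_config_error", sprintf("%s must lie in [0, 1]", what))
    }
    x
  }
  chk_bounds <- function(b, what) {
    if (!is.numeric(b) || length(b) != 2L || anyNA(b) || !all(is.finite(b)) ||
        b[1] >= b[2]) {
      stop_biokin("biokin_config_error",
                  sprintf("%s must be a finite interval (lower < upper)", what))
    }
    as.numeric(b)
  }
  k1_bounds <- chk_bounds(k1_bounds, "k1_bounds")
  k2_bounds <- chk_bounds(k2_bounds, "k2_bounds")
  sf_bounds <- chk_bounds(sf_bounds, "sf_bounds")
  if (k2_bounds[1] <= 0) {
    stop_biokin("biokin_config_error", "k2 lower bound must be > 0")
  }
  if (sf_bounds[1] < 0 || sf_bounds[2] > 1) {
    stop_biokin("biokin_config_error", "sf_bounds must lie within [0, 1]")
  }
  structure(
    list(population_size = population_size,
         steady_fitness_generations = steady_fitness_generations,
         max_generations = max_generations,
         mutation_probability = chk_prob(mutation_probability,
                                         "mutation_probability"),
         crossover_probability = chk_prob(crossover_probability,
                                          "crossover_probability"),
         tournament_size = chk_int(tournament_size, 2L, "tournament_size"),
         resample_fraction = chk_prob(resample_fraction, "resample_fraction"),
         k1_bounds = k1_bounds, k2_bounds = k2_bounds, sf_bounds = sf_bounds,
         seed = as.integer(seed), track_population = isTRUE(track_population)),
    class = "fit_config"
  )
}

config_bounds <- function(config, model) {
  b <- rbind(k1 = config$k1_bounds, k2 = config$k2_bounds)
  if (model_kind(model) == "OC-SF") b <- rbind(b, sf = config$sf_bounds)
  b
}

#' Residual sum of squares of a parameter set
#'
#' The least-squares objective minimised by [fit_model()]: the sum of squared
#' differences between observed concentrations and the model prediction at
#' each observed time, replicates included individually.
#'
#' @inheritParams predict_concentration
#' @param data a [conc_series()] of observations.
#' @return a non-negative number.
#' @export
rss_objective <- function(params, model, scenario, data) {
  data <- as_conc_series(data)
  if (nrow(data) < 1L) stop_biokin("biokin_input_error", "data must be non-empty")
  pred <- predict_concentration(model, params, scenario, data$time)
  sum((data$concentration - pred)^2)
}

# Population objective: theta is a p x N matrix (rows k1, k2[, sf]); returns
# N residual sums of squares, +Inf where the prediction overflows.
population_rss <- function(theta, model, scenario, times, obs) {
  sf <- if (nrow(theta) == 3L) theta[3L, ] else rep(0, ncol(theta))
  pred <- oc_kernel(times, theta[1L, ], theta[2L, ], sf,
                    scenario$c_org0, scenario$c_exposure, scenario$t_e)
  rss <- colSums((obs - pred)^2)
  rss[!is.finite(rss)] <- Inf
  rss
}

new_fit_result <- function(model, theta, rss, data, scenario, generations_run,
                           converged, seed, population_range = NULL) {
  model <- model_kind(model)
  params <- kinetic_params(theta[1L], theta[2L],
                           if (length(theta) == 3L) theta[3L] else 0)
  fitted <- predict_concentration(model, params, scenario, data$time)
  structure(
    list(model = model, params = params, rss = rss,
         fitted_values = fitted,
         residuals = data$concentration - fitted,
         generations_run = generations_run, converged = converged,
         seed = seed, n = nrow(data), npar = model_npar(model),
         scenario = scenario, population_range = population_range),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): k1 = %g, k2 = %g, SF = %g\n",
              x$model, x$n, x$params$k1, x$params$k2, x$params$sf))
  cat(sprintf("  RSS = %g after %d generations (%s)\n", x$rss,
              x$generations_run,
              if (isTRUE(x$converged)) "steady-fitness stop" else "generation cap"))
  invisible(x)
}

check_fit_data <- function(data, model) {
  data <- as_conc_series(data)
  p <- model_npar(model)
  if (nrow(data) < p + 1L) {
    stop_biokin("biokin_input_error",
      sprintf("need at least %d points to fit the %s model", p + 1L,
              model_kind(model)))
  }
  if (length(unique(data$time)) < 2L) {
    stop_biokin("biokin_input_error",
                "all observations share one time; kinetics are unidentifiable")
  }
  data
}

#' Fit a biokinetic model by genetic-algorithm least squares
#'
#' Minimises [rss_objective()] over the bounded parameter box of the chosen
#' model with a seeded, single-threaded real-coded genetic algorithm.  The
#' best individual ever evaluated is returned; evolution stops when the best
#' fitness has been steady for `config$steady_fitness_generations`
#' generations or when `config$max_generations` is reached.
#'
#' @inheritParams rss_objective
#' @param config a [fit_config()].
#' @return an object of class `"fit_result"`: estimated parameters, fitted
#'   values, residuals, `rss`, `generations_run`, `converged` and the seed.
#' @examples
#' sc <- exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = 4)
#' obs <- simulate_series("OC", kinetic_params(0.2, 0.03), sc)
#' fit <- fit_model(obs, "OC", sc, fit_config(population_size = 100,
#'                                            steady_fitness_generations = 50))
#' fit$params
#' @export
fit_model <- function(data, model, scenario, config = fit_config()) {
  model <- model_kind(model)
  data <- check_fit_data(data, model)
  if (!inherits(config, "fit_config")) {
    stop_biokin("biokin_config_error", "config must be a fit_config object")
  }
  if (any(data$concentration < 0)) {
    message("note: fitting data containing negative concentrations")
  }
  bounds <- config_bounds(config, model)
  p <- nrow(bounds)
  lower <- bounds[, 1L]; upper <- bounds[, 2L]
  span <- upper - lower
  N <- config$population_size
  times <- data$time; obs <- data$concentration

  with_preserved_seed(config$seed, {
    theta <- lower + span * matrix(stats::runif(p * N), nrow = p)
    rss <- population_rss(theta, model, scenario, times, obs)
    range_lo <- apply(theta, 1L, min); range_hi <- apply(theta, 1L, max)

    ib <- which.min(rss)
    best_theta <- theta[, ib]; best_rss <- rss[ib]
    stall <- 0L; gen <- 0L
    k <- config$tournament_size

    while (gen < config$max_generations &&
           stall < config$steady_fitness_generations) {
      gen <- gen + 1L

      # tournament selection (size k, with replacement)
      cand <- matrix(sample.int(N, N * k, replace = TRUE), nrow = k)
      fit_cand <- matrix(rss[cand], nrow = k)
      winners <- cand[cbind(max.col(-t(fit_cand), ties.method = "first"),
                            seq_len(N))]
      child <- theta[, winners, drop = FALSE]

      # single-point crossover on consecutive pairs: genes after the cut are
      # swapped between the two parents
      if (p > 1L) {
        n_pairs <- N %/% 2L
        do_cx <- stats::runif(n_pairs) < config$crossover_probability
        cuts <- sample.int(p - 1L, n_pairs, replace = TRUE)
        for (r in 2L:p) {
          sel <- which(do_cx & cuts < r)
          if (length(sel)) {
            a <- 2L * sel - 1L; b <- 2L * sel
            tmp <- child[r, a]
            child[r, a] <- child[r, b]
            child[r, b] <- tmp
          }
        }
      }

      # mutation, three moves per mutated gene: uniform resample within the
      # bounds (global exploration), a multiplicative log-normal step (rate
      # constants live on a scale spanning decades; a scale-aware step is
      # needed to traverse them), or an additive Gaussian step scaled by the
      # current population spread (self-annealing local refinement)
      mut <- matrix(stats::runif(p * N) < config$mutation_probability,
                    nrow = p)
      if (any(mut)) {
        # refinement scale: spread of the elite quartile, not of the whole
        # population (resampled wanderers would keep the spread inflated and
        # the step size would never anneal)
        elite <- theta[, order(rss)[seq_len(max(p + 1L, N %/% 20L))],
                       drop = FALSE]
        sds <- pmax(apply(elite, 1L, stats::sd), 1e-10 * span)
        u <- matrix(stats::runif(p * N), nrow = p)
        uni <- mut & u < config$resample_fraction
        mul <- mut & !uni & u < config$resample_fraction +
          (1 - config$resample_fraction) / 2
        gau <- mut & !uni & !mul
        if (any(uni)) {
          idx <- which(uni, arr.ind = TRUE)
          child[uni] <- lower[idx[, 1L]] +
            span[idx[, 1L]] * stats::runif(nrow(idx))
        }
        if (any(mul)) {
          child[mul] <- child[mul] * exp(0.7 * stats::rnorm(sum(mul)))
        }
        if (any(gau)) {
          idx <- which(gau, arr.ind = TRUE)
          child[gau] <- child[gau] +
            stats::rnorm(nrow(idx)) * sds[idx[, 1L]]
        }
        child <- pmin(pmax(child, lower), upper)
      }

      # elite-covariance moves: Gaussian steps drawn from the covariance of
      # the elite 5 %, so refinement can follow the correlated valleys of
      # the least-squares surface (a plain axis-aligned step is almost
      # always rejected there).  Step sizes are log-uniform over several
      # decades: coarse steps travel the valley, fine ones polish.
      elite <- theta[, order(rss)[seq_len(max(p + 1L, N %/% 20L))],
                     drop = FALSE]
      cv <- stats::cov(t(elite)) + diag((1e-10 * span)^2, p)
      ch <- tryCatch(chol(cv), error = function(e) NULL)
      cvm <- stats::runif(N) < config$mutation_probability
      if (!is.null(ch) && any(cvm)) {
        nc <- sum(cvm)
        steps <- t(ch) %*% matrix(stats::rnorm(p * nc), nrow = p)
        steps <- steps * rep(10^stats::runif(nc, -3, 0.5), each = p)
        child[, cvm] <- pmin(pmax(child[, cvm] + steps, lower), upper)
      }

      # correlated scale move: rescale k1 and k2 of an individual by one
      # common log-normal factor (and divide sf by it).  The fit surface has
      # narrow valleys along constant k1/k2 (the uptake plateau) and, for
      # OC-SF, constant sf*k1 (the stored-accrual slope); this move travels
      # along both at once, changing only the kinetic time scale, which
      # single-gene mutations cannot do.
      joint <- stats::runif(N) < config$mutation_probability / 2
      if (any(joint)) {
        nj <- sum(joint)
        big <- stats::runif(nj) < 0.5   # half the moves jump whole decades
        f <- ifelse(big, 10^stats::runif(nj, -2, 2),
                    exp(0.7 * stats::rnorm(nj)))
        child[1L, joint] <- child[1L, joint] * f
        child[2L, joint] <- child[2L, joint] * f
        if (p == 3L) child[3L, joint] <- child[3L, joint] / f
        child <- pmin(pmax(child, lower), upper)
      }

      # 1-elitism: the best-ever individual survives unchanged, and a small
      # block of offspring refines it with fine covariance-shaped steps
      # (hypermutation around the incumbent)
      child[, 1L] <- best_theta
      nref <- min(24L, N - 1L)
      half <- nref %/% 2L
      if (!is.null(ch) && half > 0L) {
        steps <- t(ch) %*% matrix(stats::rnorm(p * half), nrow = p)
        steps <- steps * rep(10^stats::runif(half, -4, 0), each = p)
        child[, 1L + seq_len(half)] <-
          pmin(pmax(best_theta + steps, lower), upper)
      }
      if (nref > half) {
        # scale-free relative polish: per-gene multiplicative jitter around
        # the incumbent, spanning many decades of step size
        nrel <- nref - half
        jit <- 1 + 10^stats::runif(p * nrel, -7, -1) *
          stats::rnorm(p * nrel)
        child[, 1L + half + seq_len(nrel)] <-
          pmin(pmax(best_theta * matrix(jit, nrow = p), lower), upper)
      }

      theta <- child
      rss <- population_rss(theta, model, scenario, times, obs)
      if (config$track_population) {
        range_lo <- pmin(range_lo, apply(theta, 1L, min))
        range_hi <- pmax(range_hi, apply(theta, 1L, max))
      }

      ib <- which.min(rss)
      if (rss[ib] < best_rss) {
        # fitness is judged steady up to a relative 1e-10: refinements below
        # float granularity should not postpone the steady-fitness stop
        if (rss[ib] < best_rss * (1 - 1e-10)) stall <- 0L
        else stall <- stall + 1L
        best_rss <- rss[ib]; best_theta <- theta[, ib]
      } else {
        stall <- stall + 1L
      }
    }

    pr <- if (config$track_population) {
      cbind(min = range_lo, max = range_hi)
    }
    new_fit_result(model, best_theta, best_rss, data, scenario,
                   generations_run = gen,
                   converged = stall >= config$steady_fitness_generations,
                   seed = config$seed, population_range = pr)
  })
}

#' Reference fitter: exhaustive grid search with local polish
#'
#' An independent least-squares fitter used to validate [fit_model()]: an
#' exhaustive log-spaced grid over the bounded parameter box, refined by a
#' derivative-free Nelder-Mead search on a logit-transformed (hence
#' bound-respecting) parametrisation.  Deterministic; intended as a test
#' oracle, not for routine use (its cost grows as `grid_density^p`).
#'
#' @inheritParams fit_model
#' @param grid_density number of grid points per parameter.
#' @param config a [fit_config()]; only the bounds are used.
#' @return a `"fit_result"` (with `generations_run = 0`).
#' @export
reference_fit <- function(data, model, scenario, grid_density = 25L,
                          config = fit_config()) {
  model <- model_kind(model)
  data <- check_fit_data(data, model)
  if (!is_number(grid_density) || grid_density < 2L) {
    stop_biokin("biokin_config_error", "grid_density must be >= 2")
  }
  bounds <- config_bounds(config, model)
  p <- nrow(bounds)
  lower <- bounds[, 1L]; upper <- bounds[, 2L]
  times <- data$time; obs <- data$concentration

  axis <- function(lo, hi, log_scale) {
    if (log_scale) {
      lo_pos <- max(lo, hi * 1e-8)
      pts <- exp(seq(log(lo_pos), log(hi), length.out = grid_density))
      unique(c(lo, pts))
    } else {
      seq(lo, hi, length.out = grid_density)
    }
  }
  axes <- list(axis(lower[1L], upper[1L], TRUE),   # k1 spans decades
               axis(lower[2L], upper[2L], TRUE))   # k2 spans decades
  if (p == 3L) axes <- c(axes, list(axis(lower[3L], upper[3L], FALSE)))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  rss <- population_rss(t(grid), model, scenario, times, obs)
  start <- grid[which.min(rss), ]

  # Nelder-Mead on z = qlogis((x - lo)/(hi - lo)); start nudged off the faces
  eps <- 1e-10
  frac <- pmin(pmax((start - lower) / (upper - lower), eps), 1 - eps)
  z0 <- stats::qlogis(frac)
  obj <- function(z) {
    x <- lower + (upper - lower) * stats::plogis(z)
    population_rss(matrix(x, ncol = 1L), model, scenario, times, obs)
  }
  opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000L, reltol = 1e-14))
  x_opt <- lower + (upper - lower) * stats::plogis(opt$par)
  if (opt$value <= min(rss)) {
    best <- x_opt; best_rss <- opt$value
  } else {
    best <- start; best_rss <- min(rss)
  }
  new_fit_result(model, best, best_rss, data, scenario,
                 generations_run = 0L, converged = TRUE, seed = NA_integer_)
}
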