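# MAP (empirical-Bayes) estimation of individual random effects and the
# population/individual prediction step, replicating NONMEM's posthoc
# behaviour (MAXEVAL=0): the full nonlinear objective is minimized in the
# etas with the population parameters fixed.

#' Bundle one patient's covariates, regimen and observations
#'
#' @param covariates An `mtx_covariates` record.
#' @param regimen An `mtx_regimen`.
#' @param observations `data.frame` with columns `time` (h), `conc`
#'   (umol/L) and `below_loq` (logical).  Times must be at or after the
#'   first dose; quantified concentrations must be positive.
#' @return Object of class `mtx_individual`.
#' @export
individual_data <- function(covariates, regimen, observations) {
  stopifnot(inherits(covariates, "mtx_covariates"),
            inherits(regimen, "mtx_regimen"),
            all(c("time", "conc", "below_loq") %in% names(observations)))
  observations <- observations[order(observations$time), , drop = FALSE]
  if (nrow(observations)) {
    if (min(observations$time) < min(regimen$events$start)) {
      stop("individual_data('", covariates$patient_id,
           "'): observation before first dose", call. = FALSE)
    }
    ok <- observations$below_loq | observations$conc > 0
    if (!all(ok)) {
      stop("individual_data('", covariates$patient_id,
           "'): non-positive quantified concentration", call. = FALSE)
    }
  }
  structure(list(covariates = covariates, regimen = regimen,
                 observations = observations),
            class = "mtx_individual")
}

# Quantified (non-BLQ) observations only; these drive fitting and metrics.
usable_obs <- function(data) {
  data$observations[!data$observations$below_loq, , drop = FALSE]
}

# Occasion index of each time point under the patient's regimen.
occasion_index <- function(regimen, times) {
  pmax(1L, findInterval(times, regimen$occasions))
}

# Fast individual-parameter realization from precomputed typical values:
# typical value x exp(eta [+ kappa]).  Used in the optimizer hot loop so
# the covariate relations are evaluated only once per patient.
scale_params <- function(tp, etas, kappas = NULL) {
  vals <- tp$values
  for (p in names(etas)) vals[[p]] <- vals[[p]] * exp(etas[[p]])
  if (!is.null(kappas)) {
    for (p in names(kappas)) vals[[p]] <- vals[[p]] * exp(kappas[[p]])
  }
  structure(list(model_name = tp$model_name, values = vals,
                 n_compartments = tp$n_compartments,
                 parameterization = tp$parameterization,
                 etas = etas, kappas = kappas),
            class = "mtx_params")
}

# Per-occasion parameter list for one eta vector and a kappa matrix
# (rows = occasions, cols = IOV parameters; NULL when the model has none).
occasion_params <- function(tp, model, regimen, etas, kappa_mat = NULL) {
  n_occ <- length(regimen$occasions)
  if (is.null(kappa_mat) || ncol(kappa_mat) == 0) {
    scale_params(tp, etas)
  } else {
    lapply(seq_len(n_occ), function(o) {
      scale_params(tp, etas, stats::setNames(kappa_mat[o, ], colnames(kappa_mat)))
    })
  }
}

# Model-predicted concentrations at arbitrary times for given random effects.
predict_conc <- function(model, data, etas, kappa_mat = NULL, tp = NULL) {
  if (is.null(tp)) tp <- typical_params(model, data$covariates)
  pars <- occasion_params(tp, model, data$regimen, etas, kappa_mat)
  concentration_profile(pars, data$regimen, data$observations$time)$conc
}

empty_kappa <- function(model, regimen) {
  matrix(0, nrow = length(regimen$occasions), ncol = length(model$iov),
         dimnames = list(NULL, names(model$iov)))
}

#' MAP objective function (-2 log posterior up to a constant)
#'
#' `sum_i [ log(2 pi sigma_i^2) + (y_i - f_i)^2 / sigma_i^2 ]
#'  + eta' Omega^-1 eta + sum_occ kappa' Omega_IOV^-1 kappa`,
#' where `sigma_i^2` is the residual variance evaluated at the individual
#' prediction `f_i(eta, kappa)` (standard posthoc behaviour) and only
#' quantified observations contribute.
#'
#' @param model An `mtx_model`.
#' @param data An `mtx_individual`.
#' @param etas Named eta vector (names = `names(model$iiv)`).
#' @param kappa_mat Matrix of kappas, rows = occasions of the regimen,
#'   columns = `names(model$iov)`; `NULL` for zero.
#' @param convention Omega convention, see [omega_matrix()].
#' @return Scalar objective; a large finite penalty (1e10) when a
#'   prediction is non-finite or the residual variance degenerates, so
#'   box-constrained quasi-Newton search remains well defined.
#' @export
map_objective <- function(model, data, etas, kappa_mat = NULL,
                          convention = "cv") {
  tp <- typical_params(model, data$covariates)
  map_objective_impl(model, data, etas, kappa_mat, tp,
                     omega_matrix(model, convention),
                     iov_variance(model, convention))
}

map_objective_impl <- function(model, data, etas, kappa_mat, tp,
                               omega, iov_var) {
  obs <- usable_obs(data)
  prior <- 0
  if (length(etas)) {
    prior <- prior + sum(etas * solve(omega, etas))
  }
  if (!is.null(kappa_mat) && ncol(kappa_mat)) {
    prior <- prior + sum(sweep(kappa_mat^2, 2, iov_var, "/"))
  }
  if (!nrow(obs)) return(prior)
  pars <- occasion_params(tp, model, data$regimen, etas, kappa_mat)
  f <- tryCatch(
    concentration_profile(pars, data$regimen, obs$time)$conc,
    error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f))) return(1e10)
  s2 <- residual_variance(model, f)
  if (any(s2 < 1e-300)) return(1e10)
  val <- sum(log(2 * pi * s2) + (obs$conc - f)^2 / s2) + prior
  if (!is.finite(val)) 1e10 else val
}

#' Optimizer configuration for MAP estimation
#'
#' @param n_starts Total optimization starts: one at eta = 0 plus
#'   `n_starts - 1` jittered starts (large published omegas - up to 137.6%
#'   CV - can create local minima).
#' @param jitter_sd SD of the Gaussian jitter applied to the extra starts.
#' @param seed Seed for the jitter draws (per-patient streams are derived
#'   from it deterministically).
#' @param pgtol Projected-gradient tolerance declaring convergence.
#' @param maxit Iteration cap per start.
#' @param convention Omega convention, see [omega_matrix()].
#' @return A list of class `mtx_map_config`.
#' @export
map_config <- function(n_starts = 5, jitter_sd = 0.5, seed = 20230208,
                       pgtol = 1e-8, maxit = 500, convention = "cv") {
  structure(list(n_starts = n_starts, jitter_sd = jitter_sd, seed = seed,
                 pgtol = pgtol, maxit = maxit, convention = convention),
            class = "mtx_map_config")
}

#' Read an optimizer configuration from YAML
#' @param path YAML file with any subset of the [map_config()] fields.
#' @return `mtx_map_config`.
#' @export
map_config_from_yaml <- function(path) {
  do.call(map_config, yaml::read_yaml(path))
}

# Run fn with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' MAP estimation of a patient's random effects
#'
#' Minimizes [map_objective()] by quasi-Newton (L-BFGS-B) from eta = 0
#' plus jittered multi-starts and returns the best solution.  With no
#' quantified observations the prior mode (all zeros) is returned exactly.
#' Kappas are estimated only for occasions carrying observations; the
#' others stay at zero.
#'
#' @param model An `mtx_model`.
#' @param data An `mtx_individual`.
#' @param config An [map_config()].
#' @return Object of class `mtx_eta_estimate`: `etas` (named vector),
#'   `kappas` (occasion x parameter matrix), `objective_value`,
#'   `converged`, `n_starts_used`, `n_obs_used`.
#' @export
estimate_etas <- function(model, data, config = map_config()) {
  stopifnot(inherits(model, "mtx_model"), inherits(data, "mtx_individual"))
  obs <- usable_obs(data)
  eta_names <- names(model$iiv)
  n_eta <- length(eta_names)
  kmat0 <- empty_kappa(model, data$regimen)
  if (!nrow(obs) || (n_eta == 0 && ncol(kmat0) == 0)) {
    return(structure(
      list(etas = stats::setNames(numeric(n_eta), eta_names),
           kappas = kmat0, objective_value = 0,
           converged = TRUE, n_starts_used = 0L, n_obs_used = nrow(obs)),
      class = "mtx_eta_estimate"))
  }
  tp <- typical_params(model, data$covariates)
  omega <- omega_matrix(model, config$convention)
  iov_var <- iov_variance(model, config$convention)
  occ_with_obs <- sort(unique(occasion_index(data$regimen, obs$time)))
  n_kap <- length(model$iov) * length(occ_with_obs)

  unpack <- function(theta) {
    etas <- stats::setNames(theta[seq_len(n_eta)], eta_names)
    kmat <- kmat0
    if (n_kap) {
      kmat[occ_with_obs, ] <- matrix(theta[n_eta + seq_len(n_kap)],
                                     nrow = length(occ_with_obs))
    }
    list(etas = etas, kmat = kmat)
  }
  objfn <- function(theta) {
    u <- unpack(theta)
    map_objective_impl(model, data, u$etas, u$kmat, tp, omega, iov_var)
  }

  # jittered starts depend only on the config seed so that identical
  # patients (whatever their id) yield identical estimates
  n_par <- n_eta + n_kap
  starts <- matrix(0, nrow = config$n_starts, ncol = n_par)
  if (config$n_starts > 1) {
    starts[-1, ] <- with_seed(config$seed, function()
      matrix(stats::rnorm((config$n_starts - 1) * n_par,
                          sd = config$jitter_sd),
             nrow = config$n_starts - 1))
  }

  best <- NULL
  n_used <- 0L
  for (s in seq_len(config$n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], objfn, method = "L-BFGS-B",
                   lower = rep(-8, n_par), upper = rep(8, n_par),
                   control = list(pgtol = config$pgtol,
                                  maxit = config$maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_used <- n_used + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("estimate_etas('", model$name, "', patient '",
         data$covariates$patient_id, "'): all ", config$n_starts,
         " optimization starts failed", call. = FALSE)
  }
  # never return a point worse than the prior mode
  f0 <- objfn(numeric(n_par))
  if (f0 < best$value) best <- list(par = numeric(n_par), value = f0,
                                    convergence = 0L)
  converged <- best$convergence == 0L
  if (!converged) {
    # line searches can abort on razor-sharp objectives after effectively
    # converging; accept the point if the central-difference gradient says so
    h <- 1e-5
    g <- vapply(seq_len(n_par), function(j) {
      e <- numeric(n_par); e[j] <- h
      (objfn(best$par + e) - objfn(best$par - e)) / (2 * h)
    }, numeric(1))
    converged <- max(abs(g)) < 1e-3
  }
  u <- unpack(best$par)
  structure(
    list(etas = u$etas, kappas = u$kmat, objective_value = best$value,
         converged = converged,
         n_starts_used = n_used, n_obs_used = nrow(obs)),
    class = "mtx_eta_estimate")
}

#' Population and individual predictions at the sampling times
#'
#' Evaluates the model at the patient's recorded (quantified) sampling
#' times twice: with all random effects at zero (PRED) and at their MAP
#' estimates (IPRED).
#'
#' @param model An `mtx_model`.
#' @param data An `mtx_individual`.
#' @param estimate An `mtx_eta_estimate` (or `NULL` for zero etas, in
#'   which case IPRED equals PRED).
#' @return `data.frame` with columns `patient_id`, `time`, `obs`, `pred`,
#'   `ipred`.
#' @export
prediction_series <- function(model, data, estimate = NULL) {
  obs <- usable_obs(data)
  tp <- typical_params(model, data$covariates)
  data_q <- data
  data_q$observations <- obs
  zero_eta <- stats::setNames(numeric(length(model$iiv)), names(model$iiv))
  pred <- predict_conc(model, data_q, zero_eta,
                       empty_kappa(model, data$regimen), tp = tp)
  if (is.null(estimate)) {
    ipred <- pred
  } else {
    ipred <- predict_conc(model, data_q, estimate$etas, estimate$kappas,
                          tp = tp)
  }
  data.frame(patient_id = data$covariates$patient_id,
             time = obs$time, obs = obs$conc, pred = pred, ipred = ipred)
}
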