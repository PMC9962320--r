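# Virtual pediatric ALL cohort generator: covariates matching the
# validation cohort's demographics, the standard HD-MTX dosing design,
# roughly daily sampling until washout, and assay censoring - with the
# generating random effects retained as ground truth for recovery tests.

#' Cohort simulation settings
#'
#' Defaults reproduce the validation cohort's design: 51 patients, ages
#' 1-13 y (median 5.5), weight 9.5-62 kg (median 19), height 73-168 cm
#' (median 113), serum creatinine 0.16-0.71 mg/dL (median 0.31), 40/51
#' male; risk-dependent dose of 3 g/m^2 (low risk) or 5 g/m^2
#' (intermediate/high risk) per course, each given as 10% over 0.5 h plus
#' 90% over 23.5 h; nominal sampling at 24/48/72/96 h after each course
#' start with ~1 h jitter; sampling stops after the first concentration
#' below 0.1 umol/L; assay LLOQ 0.05 umol/L.
#'
#' @param n_patients Number of virtual patients.
#' @param seed Mandatory RNG seed; per-patient substreams are derived from
#'   it and the patient index.
#' @param generating_model Catalog name of the data-generating model.
#' @param courses_per_patient HD-MTX courses per patient (occasions).
#' @param course_interval_h Time between course starts, h.
#' @param nominal_times_h Sampling times after each course start, h.
#' @param jitter_sd_h,jitter_max_h Gaussian sampling-time jitter SD and
#'   truncation bound, h.
#' @param lloq Lower limit of quantification, umol/L.
#' @param stop_threshold Concentration below which sampling stops, umol/L.
#' @param residual_scale Multiplier on the generating model's residual
#'   error (set near 0 for noise-free recovery experiments).
#' @param sample_etas Draw etas/kappas from the model's omega (`TRUE`) or
#'   fix them at zero.
#' @param age_range,weight_range,height_range,scr_range,oh_range Clipping
#'   ranges for the sampled covariates.
#' @param age_median,age_sdlog Median (years) and log-SD of the truncated
#'   log-normal age draw.
#' @param scr_median Median serum creatinine, mg/dL.
#' @param scr_sdlog Log-SD of the truncated log-normal creatinine draw.
#' @param size_sdlog Log-SD of the multiplicative noise around the
#'   age-interpolated height/weight medians.
#' @param p_male Probability of male sex.
#' @param risk_probs Named probabilities for LR/IR/HR risk groups.
#' @param dose_map Named dose levels (g/m^2) per risk group.
#' @param oh_median_ml,oh_sdlog Alkalinization-volume distribution
#'   (log-normal median and log-SD).
#' @param convention Omega convention used when drawing etas.
#' @return List of class `mtx_cohort_config`.
#' @export
cohort_config <- function(n_patients = 51, seed,
                          generating_model = "medellin",
                          courses_per_patient = 2,
                          course_interval_h = 336,
                          nominal_times_h = c(24, 48, 72, 96),
                          jitter_sd_h = 1, jitter_max_h = 3,
                          lloq = 0.05, stop_threshold = 0.1,
                          residual_scale = 1, sample_etas = TRUE,
                          age_range = c(1, 13),
                          age_median = 5.5, age_sdlog = 0.5,
                          weight_range = c(9.5, 62),
                          height_range = c(73, 168),
                          scr_range = c(0.16, 0.71),
                          scr_median = 0.31, scr_sdlog = 0.25,
                          size_sdlog = c(height = 0.03, weight = 0.12),
                          p_male = 40 / 51,
                          risk_probs = c(LR = 0.5, IR = 0.35, HR = 0.15),
                          dose_map = c(LR = 3, IR = 5, HR = 5),
                          oh_median_ml = 200, oh_sdlog = 0.4,
                          oh_range = c(50, 1000),
                          convention = "cv") {
  if (missing(seed)) stop("cohort_config(): a seed is mandatory", call. = FALSE)
  for (r in list(age_range, weight_range, height_range, scr_range, oh_range)) {
    if (r[1] <= 0 || r[1] > r[2]) {
      stop("cohort_config(): ranges must be positive with min <= max",
           call. = FALSE)
    }
  }
  if (lloq >= stop_threshold) {
    stop("cohort_config(): LLOQ must be below the stop threshold",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "mtx_cohort_config")
}

#' Read a cohort configuration from YAML
#' @param path YAML file with any subset of the [cohort_config()] fields.
#' @return `mtx_cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("risk_probs", "dose_map", "size_sdlog")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(cohort_config, args)
}

growth_anchors <- function() {
  utils::read.csv(system.file("extdata", "growth_anchors_synthetic.csv",
                              package = "mtxppk"))
}

rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), range[1]), range[2])
}

#' Sample a cohort's covariate records
#'
#' Age is a truncated log-normal centred on the cohort's median age
#' (clipped to the configured range); height and weight follow an
#' age-median growth table (a synthetic anchor table approximating
#' pediatric medians, tuned so age 5.5 y maps to 113 cm / ~19 kg) with
#' multiplicative log-normal noise; BSA is Mosteller; creatinine is a
#' truncated log-normal around its median; eGFR follows from the bedside
#' Schwartz formula.  All values are clipped to the configured ranges.
#'
#' @param config A [cohort_config()].
#' @return List of `mtx_covariates`, length `config$n_patients`.
#' @export
sample_covariates <- function(config) {
  anchors <- growth_anchors()
  with_seed(config$seed, function() {
    n <- config$n_patients
    age <- rlnorm_trunc(n, log(config$age_median), config$age_sdlog,
                        config$age_range)
    h_med <- stats::approx(anchors$age, anchors$height_cm, age, rule = 2)$y
    w_med <- stats::approx(anchors$age, anchors$weight_kg, age, rule = 2)$y
    height <- pmin(pmax(h_med * exp(stats::rnorm(n, 0, config$size_sdlog[["height"]])),
                        config$height_range[1]), config$height_range[2])
    weight <- pmin(pmax(w_med * exp(stats::rnorm(n, 0, config$size_sdlog[["weight"]])),
                        config$weight_range[1]), config$weight_range[2])
    scr <- rlnorm_trunc(n, log(config$scr_median), config$scr_sdlog,
                        config$scr_range)
    sex <- ifelse(stats::runif(n) < config$p_male, "M", "F")
    risk <- sample(names(config$risk_probs), n, replace = TRUE,
                   prob = config$risk_probs)
    oh <- rlnorm_trunc(n, log(config$oh_median_ml), config$oh_sdlog,
                       config$oh_range)
    lapply(seq_len(n), function(i) {
      covariate_record(patient_id = sprintf("sim%03d", i), sex = sex[i],
                       age_yr = age[i], weight_kg = weight[i],
                       height_cm = height[i], scr_mgdl = scr[i],
                       oh_ml = oh[i], risk_group = risk[i])
    })
  })
}

#' Simulate one patient's TDM courses
#'
#' Draws etas (and per-course kappas) from the generating model's omega,
#' builds the risk-driven multi-course regimen, simulates the true
#' concentration profile, samples it at jittered nominal times, adds
#' residual error, censors below the LLOQ, and stops sampling a course
#' after the first concentration below the follow-up threshold.
#'
#' @param cov An `mtx_covariates` record.
#' @param model The generating `mtx_model`.
#' @param config A [cohort_config()].
#' @param patient_index Index used to derive the patient's RNG substream.
#' @return Object of class `mtx_sim_patient`: an `mtx_individual` in
#'   `$data` plus `$true_etas` and `$true_kappas` (withheld ground truth).
#' @export
simulate_tdm_course <- function(cov, model, config, patient_index = 1L) {
  pseed <- (config$seed + 104729 * patient_index) %% 2147483647
  with_seed(pseed, function() {
    dose <- config$dose_map[[if (is.na(cov$risk_group)) "IR" else
      cov$risk_group]]
    n_courses <- config$courses_per_patient
    starts <- (seq_len(n_courses) - 1) * config$course_interval_h
    reg <- do.call(merge_regimens, lapply(starts, function(s)
      regimen_from_dose(dose, cov$bsa, course_start = s)))

    omega <- omega_matrix(model, config$convention)
    iov <- iov_variance(model, config$convention)
    etas <- stats::setNames(numeric(length(model$iiv)), names(model$iiv))
    kmat <- matrix(0, n_courses, length(model$iov),
                   dimnames = list(NULL, names(model$iov)))
    if (config$sample_etas) {
      if (length(etas)) {
        etas[] <- stats::rnorm(length(etas), 0, sqrt(diag(omega)))
      }
      if (length(iov)) {
        kmat[] <- stats::rnorm(length(kmat), 0,
                               rep(sqrt(iov), each = n_courses))
      }
    }
    tp <- typical_params(model, cov)
    pars <- occasion_params(tp, model, reg, etas, kmat)

    jit <- function(k) {
      j <- stats::rnorm(k, 0, config$jitter_sd_h)
      pmin(pmax(j, -config$jitter_max_h), config$jitter_max_h)
    }
    obs_list <- list()
    for (ci in seq_len(n_courses)) {
      tt <- sort(starts[ci] + config$nominal_times_h +
                   jit(length(config$nominal_times_h)))
      truth <- concentration_profile(pars, reg, tt)$conc
      s2 <- residual_variance(model, truth) * config$residual_scale^2
      y <- truth + stats::rnorm(length(tt), 0, sqrt(s2))
      stop_at <- which(y < config$stop_threshold)
      keep <- if (length(stop_at)) seq_len(min(stop_at)) else seq_along(tt)
      obs_list[[ci]] <- data.frame(time = tt[keep],
                                   conc = pmax(y[keep], 0),
                                   below_loq = y[keep] < config$lloq)
    }
    obs <- do.call(rbind, obs_list)
    structure(list(data = individual_data(cov, reg, obs),
                   true_etas = etas, true_kappas = kmat),
              class = "mtx_sim_patient")
  })
}

#' Simulate a full cohort (ground truth retained)
#'
#' @param config A [cohort_config()].
#' @param catalog Model catalog holding the generating model.
#' @return List of `mtx_sim_patient`.
#' @export
simulate_cohort <- function(config, catalog = build_model_catalog()) {
  model <- catalog[[config$generating_model]]
  if (is.null(model)) {
    stop("simulate_cohort(): unknown generating model '",
         config$generating_model, "'", call. = FALSE)
  }
  covs <- sample_covariates(config)
  lapply(seq_along(covs), function(i)
    simulate_tdm_course(covs[[i]], model, config, patient_index = i))
}

#' Simulate a validation-like dataset (ground truth stripped)
#'
#' Emits the same structure [read_dataset()] produces, so the evaluation
#' pipeline cannot distinguish synthetic from recorded input.
#'
#' @inheritParams simulate_cohort
#' @return List of `mtx_individual`.
#' @export
make_validation_like_dataset <- function(config,
                                         catalog = build_model_catalog()) {
  lapply(simulate_cohort(config, catalog), `[[`, "data")
}
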