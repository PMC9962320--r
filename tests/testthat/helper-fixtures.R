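# Shared fixture builders; everything is generated in code at test time.

# Reference child roughly matching the validation cohort medians.
ref_child <- function(scr_umol = 26) {
  covariate_record("ref", "M", age_yr = 5.5, weight_kg = 19,
                   height_cm = 113, scr_umol = scr_umol, oh_ml = 200)
}

# Hand-built structural parameter object (bypasses the catalog) for
# solver tests with arbitrary values.
raw_params <- function(values, n_cmt = 2L, parameterization = "cl_v") {
  structure(list(model_name = "raw", values = values,
                 n_compartments = as.integer(n_cmt),
                 parameterization = parameterization,
                 etas = NULL, kappas = NULL),
            class = "mtx_params")
}

# Random but physiologically-shaped parameter draw for property tests.
random_params <- function(three_cmt = FALSE) {
  v <- c(CL = stats::runif(1, 2, 10), V1 = stats::runif(1, 8, 40),
         Q = stats::runif(1, 0.2, 5), V2 = stats::runif(1, 3, 50))
  if (three_cmt) {
    v <- c(v[c("CL", "V1", "V2")], Q1 = v[["Q"]],
           V3 = stats::runif(1, 1, 10), Q2 = stats::runif(1, 0.05, 1))
  }
  raw_params(v, n_cmt = if (three_cmt) 3L else 2L)
}

# Single-eta toy model (clearance only) for grid-search oracles.
toy_model_1eta <- function(ruv_prop = 0.2) {
  model_spec("toy1", "toy 1-eta", 2L, "cl_v",
             params = list(CL = "6.5 * bsa^0.62", V1 = "0.36 * weight",
                           Q = "0.41", V2 = "3.2"),
             iiv = c(CL = 30), ruv_prop = ruv_prop,
             required_covariates = c("bsa", "weight"))
}

toy_model_2eta <- function(ruv_prop = 0.2) {
  model_spec("toy2", "toy 2-eta", 2L, "cl_v",
             params = list(CL = "6.5 * bsa^0.62", V1 = "0.36 * weight",
                           Q = "0.41", V2 = "3.2"),
             iiv = c(CL = 30, V1 = 30), ruv_prop = ruv_prop,
             required_covariates = c("bsa", "weight"))
}

# One patient with a standard course and given observations.
toy_patient <- function(obs_time, obs_conc, dose = 3, bsa = NULL,
                        cov = ref_child()) {
  reg <- regimen_from_dose(dose, if (is.null(bsa)) cov$bsa else bsa)
  individual_data(cov, reg,
                  data.frame(time = obs_time, conc = obs_conc,
                             below_loq = rep(FALSE, length(obs_time))))
}

# Dense, nearly noise-free recovery design: simulate from a small-RUV
# clone of a catalog model so the likelihood dominates the MAP prior.
recovery_setup <- function(model_name = "medellin", seed = 7, n = 6,
                           ruv_prop = 0.02, courses = 1) {
  cat_ <- build_model_catalog()
  m <- cat_[[model_name]]
  m$ruv_prop <- ruv_prop
  cat_[[model_name]] <- m
  cfg <- cohort_config(
    n_patients = n, seed = seed, generating_model = model_name,
    nominal_times_h = c(0.5, 1, 2, 4, 8, 12, 16, 20, 24, 24.5, 25, 26,
                        28, 32, 40, 48, 60, 72),
    jitter_sd_h = 0, stop_threshold = 1e-9, lloq = 1e-10,
    courses_per_patient = courses)
  list(model = m, patients = simulate_cohort(cfg, cat_))
}

# Two-stage brute-force grid minimization of a 1-D function: coarse pass
# over [lo, hi], then a fine pass (step `fine`) around the coarse minimum.
grid_min_1d <- function(f, lo = -3, hi = 3, coarse = 0.01, fine = 1e-4) {
  g1 <- seq(lo, hi, by = coarse)
  v1 <- vapply(g1, f, numeric(1))
  c1 <- g1[which.min(v1)]
  g2 <- seq(c1 - 2 * coarse, c1 + 2 * coarse, by = fine)
  v2 <- vapply(g2, f, numeric(1))
  g2[which.min(v2)]
}
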