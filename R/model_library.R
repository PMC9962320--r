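# Declarative catalog of published population-PK models of high-dose
# methotrexate in pediatric ALL, and the machinery turning covariates and
# random effects into individual structural parameters.
#
# Each model is stored declaratively: the covariate relations are R
# expressions (as strings) over a fixed covariate vocabulary
#   weight (kg), height (cm), age (years), bsa (m^2),
#   scr_umol / scr_mgdl (serum creatinine), egfr (mL/min/1.73 m^2),
#   sex_female (0/1), oh (alkalinization volume, mL)
# so the catalog round-trips through YAML and users can add models without
# touching code.

#' Construct a population-PK model specification
#'
#' Low-level constructor; most users want [build_model_catalog()].
#'
#' @param name Short identifier (e.g. `"gao"`).
#' @param label Human-readable study label.
#' @param n_compartments 2 or 3.
#' @param parameterization `"cl_v"` (clearances/volumes) or `"micro"`
#'   (central CL/V1 plus first-order micro constants K12/K21).
#' @param params Named list of covariate-relation strings, one per
#'   structural parameter (CL and volumes in L/h and L, Q in L/h,
#'   K12/K21 in 1/h).
#' @param iiv Named numeric, inter-individual variability as CV% per
#'   parameter carrying a log-normal eta.
#' @param iov Named numeric, inter-occasion variability as CV%.
#' @param ruv_prop Proportional residual error (fraction, e.g. 0.302).
#' @param ruv_add Additive residual error (umol/L).
#' @param required_covariates Character vector of covariate names the
#'   relations reference.
#' @param covariate_defaults Named list of fallback values substituted when
#'   a required covariate is missing from the data.
#' @return An object of class `mtx_model`.
#' @export
model_spec <- function(name, label, n_compartments, parameterization,
                       params, iiv = numeric(), iov = numeric(),
                       ruv_prop = 0, ruv_add = 0,
                       required_covariates = character(),
                       covariate_defaults = list()) {
  stopifnot(n_compartments %in% c(2L, 3L))
  parameterization <- match.arg(parameterization, c("cl_v", "micro"))
  bad <- setdiff(c(names(iiv), names(iov)), names(params))
  if (length(bad)) {
    stop("model_spec('", name, "'): random effect on unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (ruv_prop < 0 || ruv_add < 0 || (ruv_prop == 0 && ruv_add == 0)) {
    stop("model_spec('", name, "'): residual error must be non-negative ",
         "with at least one positive component", call. = FALSE)
  }
  structure(
    list(name = name, label = label,
         n_compartments = as.integer(n_compartments),
         parameterization = parameterization,
         params = params, iiv = iiv, iov = iov,
         ruv_prop = ruv_prop, ruv_add = ruv_add,
         required_covariates = required_covariates,
         covariate_defaults = covariate_defaults),
    class = "mtx_model"
  )
}

#' @export
print.mtx_model <- function(x, ...) {
  cat(sprintf("<mtx_model> %s (%s), %d-compartment, %s parameterization\n",
              x$name, x$label, x$n_compartments, x$parameterization))
  for (p in names(x$params)) cat("  ", p, " = ", x$params[[p]], "\n", sep = "")
  if (length(x$iiv)) cat("  IIV (CV%):",
    paste(sprintf("%s=%.1f", names(x$iiv), x$iiv), collapse = " "), "\n")
  if (length(x$iov)) cat("  IOV (CV%):",
    paste(sprintf("%s=%.1f", names(x$iov), x$iov), collapse = " "), "\n")
  cat(sprintf("  RUV: prop=%.3f add=%.4f umol/L\n", x$ruv_prop, x$ruv_add))
  invisible(x)
}

#' Catalog of the six published methotrexate models
#'
#' Builds the six externally evaluated PopPK models of HD-MTX in pediatric
#' ALL: Aumente, Gao, Hui, Medellin-Garibay, Zhang and Jonsson.  All are
#' two-compartment disposition models except Gao (three compartments).
#' Aumente is parameterized with micro rate constants (fixed K12 = 0.0155,
#' K21 = 0.0724 1/h) and age-branched CL/V1 relations; the branch boundary
#' assigns age exactly 10 years to the older-age equations.  Jonsson does
#' not report residual error, so a 30% proportional error is assumed.
#'
#' @param hui_renal How to read the Hui renal-function term
#'   `(eGFR x 1.73/192 x BSA)^0.256`: `"physiological"` (default) treats it
#'   as absolute GFR normalized to 192 mL/min, i.e.
#'   `((eGFR x BSA / 1.73) / 192)^0.256`; `"literal"` evaluates the printed
#'   expression left to right.
#' @param zhang_female_code Numeric code the Zhang gender covariate assigns
#'   to females (default 1; males get `1 - zhang_female_code`).  The
#'   negative coefficient then lowers clearance for girls.
#' @param zhang_oh_default Fallback alkalinization volume (mL) for the
#'   Zhang model when the dataset lacks it.  The source publication's
#'   central value is not reproduced here, so there is no built-in default:
#'   leave `NA` to require the covariate.
#' @return A named list of six [model_spec()] objects.
#' @examples
#' cat <- build_model_catalog()
#' names(cat)
#' @export
build_model_catalog <- function(hui_renal = c("physiological", "literal"),
                                zhang_female_code = 1,
                                zhang_oh_default = NA_real_) {
  hui_renal <- match.arg(hui_renal)
  hui_renal_expr <- if (hui_renal == "physiological") {
    "((egfr * bsa / 1.73) / 192)^0.256"
  } else {
    "(egfr * 1.73 / 192 * bsa)^0.256"
  }
  sex_term <- if (zhang_female_code == 1) "sex_female" else "(1 - sex_female)"
  zhang_defaults <- if (is.na(zhang_oh_default)) list() else
    list(oh = zhang_oh_default)

  list(
    aumente = model_spec(
      name = "aumente", label = "Aumente et al.",
      n_compartments = 2L, parameterization = "micro",
      params = list(
        CL  = "if (age >= 10) 0.149 * weight else 0.287 * weight^0.876",
        V1  = "if (age >= 10) 0.437 * weight else 0.465 * weight",
        K12 = "0.0155",
        K21 = "0.0724"
      ),
      iiv = c(CL = 41.7, V1 = 41.6, K12 = 20.8, K21 = 35.2),
      ruv_prop = 0.162, ruv_add = 0.0035,
      required_covariates = c("age", "weight")
    ),
    gao = model_spec(
      name = "gao", label = "Gao et al.",
      n_compartments = 3L, parameterization = "cl_v",
      params = list(
        CL = "6.9 * (weight / 19)^0.75 * (1 + (scr_umol - 26) * (-0.0097))",
        V1 = "20.7 * (weight / 19)",
        V2 = "41.0 * (weight / 19)",
        Q1 = "0.255 * (weight / 19)^0.75",
        V3 = "3.17 * (weight / 19)",
        Q2 = "0.217 * (weight / 19)^0.75"
      ),
      # random effects follow the structural equations (eta on CL and V2)
      iiv = c(CL = 17.9, V2 = 26.2),
      ruv_prop = 0.354,  # exponential error ~ proportional
      required_covariates = c("weight", "scr_umol")
    ),
    hui = model_spec(
      name = "hui", label = "Hui et al.",
      n_compartments = 2L, parameterization = "cl_v",
      params = list(
        CL = paste0("7.73 * (bsa / 0.735)^0.721 * ", hui_renal_expr),
        V1 = "19.0 * (bsa / 0.735)^0.985",
        Q  = "0.283 * (age / 5.29)^0.278",
        V2 = "6.63"
      ),
      iiv = c(CL = 14.3, V2 = 34.6),
      iov = c(CL = 14.9),
      ruv_prop = 0.302,
      required_covariates = c("bsa", "egfr", "age")
    ),
    medellin = model_spec(
      name = "medellin", label = "Medellin-Garibay et al.",
      n_compartments = 2L, parameterization = "cl_v",
      params = list(
        CL = "6.5 * bsa^0.62",
        V1 = "0.36 * weight",
        Q  = "0.41",
        V2 = "3.2"
      ),
      iiv = c(CL = 8.2, V1 = 25.9, V2 = 26.7),
      ruv_prop = 0.201,
      required_covariates = c("bsa", "weight")
    ),
    zhang = model_spec(
      name = "zhang", label = "Zhang et al.",
      n_compartments = 2L, parameterization = "cl_v",
      params = list(
        CL = paste0("5.04 * (1 - 0.278 * ", sex_term,
                    ") * bsa^0.777 + (oh / 100)^0.514"),
        V1 = "16.1",
        Q  = "0.203 * (age / 10)^1.56",
        V2 = "7.05 * (age / 10)^1.76"
      ),
      iiv = c(CL = 49.6, V1 = 29.4, Q = 137.6, V2 = 107.7),
      ruv_prop = 0.190, ruv_add = 0.0872,
      required_covariates = c("bsa", "sex", "age", "oh"),
      covariate_defaults = zhang_defaults
    ),
    jonsson = model_spec(
      name = "jonsson", label = "Jonsson et al.",
      n_compartments = 2L, parameterization = "cl_v",
      params = list(
        CL = "weight * 0.185",
        V1 = "weight * 1.27",
        Q  = "weight * 0.017",
        V2 = "weight * 1.02"
      ),
      iiv = c(CL = 109.0, V1 = 26.0, Q = 22.0, V2 = 44.0),
      ruv_prop = 0.30,  # assumed: residual error not reported
      required_covariates = c("weight")
    )
  )
}

# Build the evaluation environment for covariate relations, applying
# configured defaults and erroring on missing required covariates.
cov_env <- function(model, cov) {
  e <- new.env(parent = baseenv())
  vals <- list(
    weight = cov$weight, height = cov$height, age = cov$age,
    bsa = cov$bsa, scr_umol = cov$scr_umol, scr_mgdl = cov$scr_mgdl,
    egfr = cov$egfr, oh = cov$oh,
    sex_female = if (is.na(cov$sex)) NA_real_ else as.numeric(cov$sex == "F")
  )
  for (nm in model$required_covariates) {
    key <- if (nm == "sex") "sex_female" else nm
    if (is.na(vals[[key]])) {
      if (!is.null(model$covariate_defaults[[nm]])) {
        vals[[key]] <- model$covariate_defaults[[nm]]
      } else {
        stop("model '", model$name, "': required covariate '", nm,
             "' is missing for patient '", cov$patient_id,
             "' and no default is configured", call. = FALSE)
      }
    }
  }
  list2env(vals, envir = e)
  e
}

#' Typical (population) structural parameters
#'
#' Evaluates every covariate relation of a model at a patient's covariates
#' with all random effects at zero.
#'
#' @param model An `mtx_model`.
#' @param cov An `mtx_covariates` record (see [covariate_record()]).
#' @return An object of class `mtx_params`: named parameter values
#'   (clearances L/h, volumes L, micro constants 1/h) plus the etas applied.
#' @examples
#' cat <- build_model_catalog()
#' cov <- covariate_record("p1", "M", age_yr = 5, weight_kg = 19,
#'                         height_cm = 113, scr_mgdl = 26 / 88.42)
#' typical_params(cat$gao, cov)$values[["CL"]]  # 6.9 L/h
#' @export
typical_params <- function(model, cov) {
  individual_params(model, cov, etas = NULL, kappas = NULL)
}

#' Individual structural parameters from covariates and random effects
#'
#' Each parameter carrying inter-individual variability is multiplied by
#' `exp(eta)` (log-normal), and parameters with inter-occasion variability
#' additionally by `exp(kappa)` for the active occasion.  Parameters
#' without a listed random effect stay at their typical values.
#'
#' @inheritParams typical_params
#' @param etas Named numeric vector of eta deviations, names matching
#'   `names(model$iiv)`; `NULL` means all zero.
#' @param kappas Named numeric vector of occasion deviations for the
#'   active occasion, names matching `names(model$iov)`; `NULL` = zero.
#' @return `mtx_params` object.
#' @export
individual_params <- function(model, cov, etas = NULL, kappas = NULL) {
  stopifnot(inherits(model, "mtx_model"))
  if (is.null(etas)) etas <- stats::setNames(numeric(length(model$iiv)),
                                             names(model$iiv))
  if (is.null(kappas)) kappas <- stats::setNames(numeric(length(model$iov)),
                                                 names(model$iov))
  if (!setequal(names(etas), names(model$iiv)) ||
      length(etas) != length(model$iiv)) {
    stop("individual_params('", model$name, "'): etas must be named exactly ",
         "for parameters with IIV: ", paste(names(model$iiv), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(names(kappas), names(model$iov)) ||
      length(kappas) != length(model$iov)) {
    stop("individual_params('", model$name, "'): kappas must be named ",
         "exactly for parameters with IOV: ",
         paste(names(model$iov), collapse = ", "), call. = FALSE)
  }
  e <- cov_env(model, cov)
  vals <- vapply(model$params, function(expr_str) {
    v <- eval(parse(text = expr_str)[[1]], envir = e)
    as.numeric(v)
  }, numeric(1))
  for (p in names(etas))   vals[[p]] <- vals[[p]] * exp(etas[[p]])
  for (p in names(kappas)) vals[[p]] <- vals[[p]] * exp(kappas[[p]])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("model '", model$name, "': non-positive or non-finite structural ",
         "parameter for patient '", cov$patient_id, "'", call. = FALSE)
  }
  structure(
    list(model_name = model$name, values = vals,
         n_compartments = model$n_compartments,
         parameterization = model$parameterization,
         etas = etas, kappas = kappas),
    class = "mtx_params"
  )
}

#' Inter-individual covariance matrix of the etas
#'
#' The catalog stores variability as CV%.  By default the CV is read as the
#' standard deviation of the log-normal eta (omega = CV/100), the only
#' self-consistent reading for the large published values (up to 137.6%).
#' The exact log-normal convention omega^2 = ln(1 + CV^2) is available.
#'
#' @param model An `mtx_model`.
#' @param convention `"cv"` (default) or `"lognormal"`.
#' @return Diagonal covariance matrix (possibly 0 x 0) with dimnames equal
#'   to the eta parameter names.
#' @export
omega_matrix <- function(model, convention = c("cv", "lognormal")) {
  convention <- match.arg(convention)
  om2 <- omega_sq(model$iiv, convention)
  diag(om2, nrow = length(om2)) |>
    `dimnames<-`(list(names(model$iiv), names(model$iiv)))
}

#' Inter-occasion variances of the kappas
#'
#' @inheritParams omega_matrix
#' @return Named numeric vector of kappa variances (length 0 if no IOV).
#' @export
iov_variance <- function(model, convention = c("cv", "lognormal")) {
  convention <- match.arg(convention)
  omega_sq(model$iov, convention)
}

omega_sq <- function(cv_pct, convention) {
  cv <- cv_pct / 100
  switch(convention, cv = cv^2, lognormal = log(1 + cv^2))
}

#' Residual error variance at a predicted concentration
#'
#' Combined proportional + additive model:
#' `(prop x ipred)^2 + add^2`, in (umol/L)^2.
#'
#' @param model An `mtx_model`.
#' @param ipred Predicted concentration(s), umol/L (>= 0).
#' @return Variance(s), (umol/L)^2.
#' @export
residual_variance <- function(model, ipred) {
  stopifnot(all(ipred >= 0))
  (model$ruv_prop * ipred)^2 + model$ruv_add^2
}

#' Write / read a model catalog as YAML
#'
#' One YAML document per model, mirroring the `mtx_model` fields, so a
#' catalog can be edited or extended without code changes.
#'
#' @param catalog Named list of `mtx_model` objects.
#' @param path File path.
#' @return `models_from_yaml()` returns the catalog; `models_to_yaml()`
#'   returns `path` invisibly.
#' @export
models_to_yaml <- function(catalog, path) {
  docs <- lapply(catalog, function(m) {
    list(name = m$name, label = m$label,
         n_compartments = m$n_compartments,
         parameterization = m$parameterization,
         params = m$params,
         iiv = as.list(m$iiv), iov = as.list(m$iov),
         ruv_prop = m$ruv_prop, ruv_add = m$ruv_add,
         required_covariates = as.list(m$required_covariates),
         covariate_defaults = m$covariate_defaults)
  })
  txt <- paste(vapply(docs, function(d) yaml::as.yaml(d), character(1)),
               collapse = "---\n")
  writeLines(c("---", txt), path)
  invisible(path)
}

#' @rdname models_to_yaml
#' @export
models_from_yaml <- function(path) {
  # multi-document file: split on document separators and parse each
  txt <- paste(readLines(path), collapse = "\n")
  chunks <- strsplit(txt, "(^|\n)---\n")[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  cat_list <- lapply(chunks, function(ch) {
    d <- yaml::yaml.load(ch)
    model_spec(
      name = d$name, label = d$label,
      n_compartments = d$n_compartments,
      parameterization = d$parameterization,
      params = d$params,
      iiv = unlist(d$iiv) %||% numeric(),
      iov = unlist(d$iov) %||% numeric(),
      ruv_prop = d$ruv_prop, ruv_add = d$ruv_add,
      required_covariates = unlist(d$required_covariates) %||% character(),
      covariate_defaults = d$covariate_defaults %||% list()
    )
  })
  names(cat_list) <- vapply(cat_list, `[[`, character(1), "name")
  cat_list
}

`%||%` <- function(a, b) if (is.null(a)) b else a
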