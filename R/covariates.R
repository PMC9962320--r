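# Covariate derivation: renal function and body size.

#' Estimated glomerular filtration rate (Bedside Schwartz)
#'
#' eGFR = 0.413 x height / Scr, the bedside Schwartz formula for children,
#' in mL/min/1.73 m^2.
#'
#' @param height_cm Height in cm (> 0).
#' @param scr_mgdl Serum creatinine in mg/dL (> 0).
#' @return eGFR in mL/min/1.73 m^2 (vectorised).
#' @examples
#' compute_egfr(113, 0.31)
#' @export
compute_egfr <- function(height_cm, scr_mgdl) {
  if (any(!is.finite(height_cm)) || any(!is.finite(scr_mgdl)) ||
      any(height_cm <= 0) || any(scr_mgdl <= 0)) {
    stop("compute_egfr(): height and serum creatinine must be finite and > 0",
         call. = FALSE)
  }
  0.413 * height_cm / scr_mgdl
}

#' Body surface area
#'
#' BSA in m^2 from height and weight.  Mosteller is the default;
#' DuBois-DuBois is available for comparison.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @param formula One of `"mosteller"` (sqrt(H x W / 3600)) or
#'   `"dubois"` (0.007184 x H^0.725 x W^0.425).
#' @return BSA in m^2 (vectorised).
#' @examples
#' compute_bsa(113, 19)
#' @export
compute_bsa <- function(height_cm, weight_kg, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("compute_bsa(): height and weight must be finite and > 0",
         call. = FALSE)
  }
  switch(formula,
    mosteller = sqrt(height_cm * weight_kg / 3600),
    dubois    = 0.007184 * height_cm^0.725 * weight_kg^0.425
  )
}

# mg/dL -> umol/L conversion factor for creatinine
SCR_MGDL_TO_UMOL <- 88.42

#' Construct a patient covariate record
#'
#' Bundles the demographic and laboratory covariates used by the model
#' catalog.  Serum creatinine may be supplied in mg/dL or umol/L; the
#' missing unit is derived (x 88.42).  BSA and eGFR are derived from
#' height/weight/creatinine when not supplied.
#'
#' @param patient_id Identifier.
#' @param sex `"M"` or `"F"`.
#' @param age_yr Age in years.
#' @param weight_kg Weight in kg.
#' @param height_cm Height in cm.
#' @param bsa BSA in m^2, derived via [compute_bsa()] when `NA`.
#' @param scr_mgdl,scr_umol Serum creatinine; supply at least one.
#' @param egfr eGFR in mL/min/1.73 m^2, derived via [compute_egfr()] when `NA`.
#' @param oh_ml Pre-chemotherapy alkalinization (hydration) volume in mL
#'   (covariate of the Zhang model); may be `NA`.
#' @param risk_group `"LR"`, `"IR"` or `"HR"` (dose-assignment label only).
#' @param bsa_formula BSA formula used when `bsa` is derived.
#' @return An object of class `mtx_covariates` (a named list).
#' @export
covariate_record <- function(patient_id, sex, age_yr, weight_kg, height_cm,
                             bsa = NA_real_, scr_mgdl = NA_real_,
                             scr_umol = NA_real_, egfr = NA_real_,
                             oh_ml = NA_real_, risk_group = NA_character_,
                             bsa_formula = "mosteller") {
  sex <- match.arg(sex, c("M", "F"))
  if (!is.na(risk_group)) risk_group <- match.arg(risk_group, c("LR", "IR", "HR"))
  stopifnot(age_yr > 0, weight_kg > 0, height_cm > 0)
  if (is.na(scr_mgdl) && !is.na(scr_umol)) scr_mgdl <- scr_umol / SCR_MGDL_TO_UMOL
  if (is.na(scr_umol) && !is.na(scr_mgdl)) scr_umol <- scr_mgdl * SCR_MGDL_TO_UMOL
  if (!is.na(scr_mgdl) && !is.na(scr_umol) &&
      abs(scr_umol - scr_mgdl * SCR_MGDL_TO_UMOL) > 1e-9 * scr_umol) {
    stop("covariate_record(): inconsistent creatinine units (mg/dL vs umol/L)",
         call. = FALSE)
  }
  if (is.na(bsa)) bsa <- compute_bsa(height_cm, weight_kg, bsa_formula)
  if (is.na(egfr) && !is.na(scr_mgdl)) egfr <- compute_egfr(height_cm, scr_mgdl)
  for (nm in c("bsa", "scr_mgdl", "scr_umol", "egfr", "oh_ml")) {
    v <- get(nm)
    if (!is.na(v) && v <= 0) stop("covariate_record(): ", nm, " must be > 0",
                                  call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, sex = sex, age = age_yr,
         weight = weight_kg, height = height_cm, bsa = bsa,
         scr_mgdl = scr_mgdl, scr_umol = scr_umol, egfr = egfr,
         oh = oh_ml, risk_group = risk_group),
    class = "mtx_covariates"
  )
}
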