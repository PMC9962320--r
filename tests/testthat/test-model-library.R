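cat_ <- build_model_catalog()

test_that("catalog has the six published models with the right structure", {
  expect_length(cat_, 6)
  expect_setequal(names(cat_),
                  c("aumente", "gao", "hui", "medellin", "zhang", "jonsson"))
  expect_equal(cat_$gao$n_compartments, 3L)
  for (m in cat_[setdiff(names(cat_), "gao")]) {
    expect_equal(m$n_compartments, 2L)
  }
  expect_equal(cat_$aumente$parameterization, "micro")
  expect_equal(cat_$jonsson$iiv[["CL"]], 109.0)
  expect_equal(cat_$jonsson$ruv_prop, 0.30)  # assumed, not reported
  expect_equal(cat_$hui$iov[["CL"]], 14.9)
})

test_that("typical parameters reproduce the published reference evaluations", {
  cov <- ref_child(scr_umol = 26)
  expect_equal(typical_params(cat_$gao, cov)$values[["CL"]], 6.9)
  jon <- typical_params(cat_$jonsson, cov)$values
  expect_equal(jon[["CL"]], 3.515)
  expect_equal(jon[["V1"]], 24.13)
  cov_b1 <- covariate_record("b1", "M", age_yr = 5, weight_kg = 10,
                             height_cm = 100, bsa = 1, scr_mgdl = 0.3)
  med <- typical_params(cat_$medellin, cov_b1)$values
  expect_equal(med[["CL"]], 6.5)
  expect_equal(med[["V1"]], 3.6)
  # Hui at its centering covariates: renal factor exactly 1
  cov_h <- covariate_record("h", "M", age_yr = 5.29, weight_kg = 19,
                            height_cm = 113, bsa = 0.735,
                            egfr = 192 * 1.73 / 0.735, scr_mgdl = 0.31)
  hui <- typical_params(cat_$hui, cov_h)$values
  expect_equal(hui[["CL"]], 7.73)
  expect_equal(hui[["V1"]], 19.0)
  expect_equal(hui[["Q"]], 0.283)
})

test_that("typical values sit inside the published cross-study ranges", {
  cov <- ref_child(scr_umol = 26)
  cls <- vapply(cat_, function(m) typical_params(m, cov)$values[["CL"]],
                numeric(1))
  expect_true(all(cls >= 3.5 & cls <= 7.8))
  v1s <- vapply(cat_[setdiff(names(cat_), "gao")],
                function(m) typical_params(m, cov)$values[["V1"]], numeric(1))
  expect_true(all(v1s >= 3.5 & v1s <= 24.2))
})

test_that("Aumente age branch assigns age 10 to the older-age equations", {
  mk <- function(age) covariate_record("a", "M", age_yr = age,
                                       weight_kg = 30, height_cm = 130,
                                       scr_mgdl = 0.4)
  young <- typical_params(cat_$aumente, mk(9.99))$values
  at10 <- typical_params(cat_$aumente, mk(10))$values
  older <- typical_params(cat_$aumente, mk(10.01))$values
  expect_equal(young[["CL"]], 0.287 * 30^0.876)
  expect_equal(at10[["CL"]], 0.149 * 30)
  expect_equal(at10[["V1"]], older[["V1"]])
  expect_equal(at10[["K12"]], 0.0155)
  expect_equal(at10[["K21"]], 0.0724)
})

test_that("log-normal etas scale parameters and respect log-symmetry", {
  cov <- ref_child()
  tv <- typical_params(cat_$jonsson, cov)$values
  up <- individual_params(cat_$jonsson, cov,
                          etas = c(CL = log(2), V1 = 0, Q = 0, V2 = 0))
  expect_equal(up$values[["CL"]], tv[["CL"]] * 2)
  expect_equal(up$values[["V1"]], tv[["V1"]])
  eta <- c(CL = 0.4, V1 = -0.7, Q = 0.2, V2 = 1.1)
  a <- individual_params(cat_$jonsson, cov, etas = eta)$values
  b <- individual_params(cat_$jonsson, cov, etas = -eta)$values
  expect_equal(a * b, tv^2)
  expect_equal(individual_params(cat_$jonsson, cov)$values, tv)
  expect_error(individual_params(cat_$jonsson, cov, etas = c(CL = 0.1)),
               "named exactly")
})

test_that("typical parameters are monotone in the body-size covariate", {
  sizes <- data.frame(w = c(10, 15, 20, 30, 45, 60),
                      h = c(80, 100, 112, 130, 150, 165))
  for (m in cat_) {
    cl <- vapply(seq_len(nrow(sizes)), function(i) {
      cov <- covariate_record("s", "M", age_yr = 6, weight_kg = sizes$w[i],
                              height_cm = sizes$h[i], scr_umol = 26,
                              oh_ml = 200)
      typical_params(m, cov)$values[["CL"]]
    }, numeric(1))
    expect_true(all(diff(cl) > 0), label = paste(m$name, "CL monotone"))
  }
})

test_that("omega matrices follow the CV-as-SD convention with an exact alternative", {
  om <- omega_matrix(cat_$jonsson)
  expect_equal(dim(om), c(4L, 4L))
  expect_equal(diag(om),
               c(CL = 1.09^2, V1 = 0.26^2, Q = 0.22^2, V2 = 0.44^2))
  expect_true(all(om[upper.tri(om)] == 0))
  expect_equal(iov_variance(cat_$hui), c(CL = 0.149^2))
  expect_equal(dim(omega_matrix(toy_model_1eta())), c(1L, 1L))
  om_ln <- omega_matrix(cat_$jonsson, convention = "lognormal")
  expect_equal(diag(om_ln)[["CL"]], log(1 + 1.09^2))
})

test_that("residual variance combines proportional and additive parts", {
  expect_equal(residual_variance(cat_$aumente, 1.0), 0.162^2 + 0.0035^2)
  expect_equal(residual_variance(cat_$gao, 0), 0)  # pure proportional
  expect_equal(residual_variance(cat_$jonsson, 2.0), (0.30 * 2)^2)
  expect_error(residual_variance(cat_$gao, -1))
})

test_that("missing required covariates error by name unless defaulted", {
  no_oh <- covariate_record("z", "F", age_yr = 6, weight_kg = 20,
                            height_cm = 115, scr_mgdl = 0.4)
  expect_error(typical_params(cat_$zhang, no_oh), "zhang.*'oh'")
  cat_def <- build_model_catalog(zhang_oh_default = 200)
  expect_silent(typical_params(cat_def$zhang, no_oh))
  with_oh <- covariate_record("z2", "F", age_yr = 6, weight_kg = 20,
                              height_cm = 115, scr_mgdl = 0.4, oh_ml = 200)
  expect_equal(typical_params(cat_def$zhang, no_oh)$values,
               typical_params(cat_$zhang, with_oh)$values)
})

test_that("Zhang gender coding lowers clearance for the configured code", {
  mk <- function(sex) covariate_record("z", sex, age_yr = 6, weight_kg = 20,
                                       height_cm = 115, scr_mgdl = 0.4,
                                       oh_ml = 200)
  cl_f <- typical_params(cat_$zhang, mk("F"))$values[["CL"]]
  cl_m <- typical_params(cat_$zhang, mk("M"))$values[["CL"]]
  expect_lt(cl_f, cl_m)
  swapped <- build_model_catalog(zhang_female_code = 0)
  expect_gt(typical_params(swapped$zhang, mk("F"))$values[["CL"]],
            typical_params(swapped$zhang, mk("M"))$values[["CL"]])
})

test_that("the Hui renal-term reading is configurable", {
  cov <- covariate_record("h", "M", age_yr = 5, weight_kg = 19,
                          height_cm = 113, bsa = 0.8, egfr = 150,
                          scr_mgdl = 0.31)
  phys <- typical_params(cat_$hui, cov)$values[["CL"]]
  lit <- typical_params(build_model_catalog(hui_renal = "literal")$hui,
                        cov)$values[["CL"]]
  base <- 7.73 * (0.8 / 0.735)^0.721
  expect_equal(phys, base * ((150 * 0.8 / 1.73) / 192)^0.256)
  expect_equal(lit, base * (150 * 1.73 / 192 * 0.8)^0.256)
})

test_that("the catalog round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  models_to_yaml(cat_, path)
  back <- models_from_yaml(path)
  expect_setequal(names(back), names(cat_))
  cov <- ref_child(scr_umol = 26)
  for (nm in names(cat_)) {
    expect_equal(typical_params(back[[nm]], cov)$values,
                 typical_params(cat_[[nm]], cov)$values, label = nm)
    expect_equal(back[[nm]]$iiv, cat_[[nm]]$iiv)
    expect_equal(back[[nm]]$ruv_prop, cat_[[nm]]$ruv_prop)
  }
})

test_that("model specs reject inconsistent random-effect or error settings", {
  expect_error(
    model_spec("bad", "bad", 2L, "cl_v",
               params = list(CL = "5", V1 = "10", Q = "1", V2 = "5"),
               iiv = c(KA = 30), ruv_prop = 0.2),
    "unknown parameter")
  expect_error(
    model_spec("bad", "bad", 2L, "cl_v",
               params = list(CL = "5", V1 = "10", Q = "1", V2 = "5"),
               ruv_prop = 0),
    "residual error")
})
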