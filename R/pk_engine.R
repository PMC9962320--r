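# Linear mammillary 2-/3-compartment kinetics under piecewise-constant
# infusion input.  Amounts are carried in umol so concentration = amount/V1
# is in umol/L; unit conversion happens at the I/O boundary.

#' Methotrexate molar mass (g/mol)
#' @export
MTX_MOLAR_MASS <- 454.44

#' Convert a methotrexate mass to umol
#'
#' @param mg,g Dose mass.
#' @return Amount in umol.
#' @export
mg_to_umol <- function(mg) mg * 1000 / MTX_MOLAR_MASS

#' @rdname mg_to_umol
#' @export
g_to_umol <- function(g) g * 1e6 / MTX_MOLAR_MASS

#' Construct an infusion regimen
#'
#' @param events `data.frame` with columns `start` (h), `duration` (h, > 0)
#'   and `amount` (umol, >= 0).  Events may overlap; the linear system
#'   superposes them.
#' @param occasions Numeric vector of occasion (treatment-course) start
#'   times, used by models with inter-occasion variability.  Defaults to a
#'   single occasion opening at the first event.
#' @return An object of class `mtx_regimen`.
#' @export
regimen <- function(events, occasions = NULL) {
  stopifnot(is.data.frame(events),
            all(c("start", "duration", "amount") %in% names(events)))
  if (any(events$duration <= 0) || any(events$amount < 0) ||
      any(events$start < 0)) {
    stop("regimen(): event starts must be >= 0, durations > 0, amounts >= 0",
         call. = FALSE)
  }
  events <- events[order(events$start), , drop = FALSE]
  if (is.null(occasions)) occasions <- min(events$start, 0)
  occasions <- sort(unique(occasions))
  structure(list(events = events, occasions = occasions),
            class = "mtx_regimen")
}

#' Build the standard HD-MTX course regimen from a dose level
#'
#' One high-dose methotrexate course delivers 10% of the total dose as a
#' 0.5-h loading infusion followed immediately by the remaining 90% over
#' 23.5 h (total 24 h).  The dose level is expressed per body surface area
#' and converted to umol internally.
#'
#' @param dose_g_m2 Dose level in g/m^2 (the observed range is 1-5; values
#'   outside it trigger a warning).
#' @param bsa Body surface area, m^2.
#' @param course_start Start time of the course, h.
#' @return An `mtx_regimen` with two events and one occasion boundary at
#'   `course_start`.
#' @examples
#' reg <- regimen_from_dose(3, bsa = 1)
#' reg$events  # 660.15 umol over 0.5 h, then 5941.4 umol over 23.5 h
#' @export
regimen_from_dose <- function(dose_g_m2, bsa, course_start = 0) {
  if (!is.finite(dose_g_m2) || dose_g_m2 <= 0 || !is.finite(bsa) || bsa <= 0) {
    stop("regimen_from_dose(): dose and BSA must be > 0", call. = FALSE)
  }
  if (dose_g_m2 < 1 || dose_g_m2 > 5) {
    warning("regimen_from_dose(): dose ", dose_g_m2,
            " g/m^2 is outside the evaluated 1-5 g/m^2 range")
  }
  total <- g_to_umol(dose_g_m2 * bsa)
  ev <- data.frame(
    start = course_start + c(0, 0.5),
    duration = c(0.5, 23.5),
    amount = total * c(0.1, 0.9)
  )
  regimen(ev, occasions = course_start)
}

#' Merge single-course regimens into a multi-course regimen
#'
#' @param ... `mtx_regimen` objects.
#' @return One `mtx_regimen` whose occasions are the union of the inputs'.
#' @export
merge_regimens <- function(...) {
  rs <- list(...)
  regimen(do.call(rbind, lapply(rs, `[[`, "events")),
          occasions = unlist(lapply(rs, `[[`, "occasions")))
}

#' First-order rate matrix of a mammillary compartment model
#'
#' Builds M for dA/dt = M A + input.  Clearance/volume parameterization
#' uses k10 = CL/V1, k1j = Qj/V1, kj1 = Qj/Vj (peripheral compartments
#' exchange only with the central one); the micro-constant
#' parameterization uses k10 = CL/V1 with the given K12/K21.
#'
#' @param params An `mtx_params` object (see [individual_params()]).
#' @return Square matrix (1/h), dimension = number of compartments.
#' @export
rate_matrix <- function(params) {
  stopifnot(inherits(params, "mtx_params"))
  v <- params$values
  if (any(v <= 0)) stop("rate_matrix(): non-positive parameter", call. = FALSE)
  if (params$parameterization == "micro") {
    k10 <- v[["CL"]] / v[["V1"]]
    M <- matrix(c(-(k10 + v[["K12"]]), v[["K21"]],
                  v[["K12"]], -v[["K21"]]), 2, 2, byrow = TRUE)
  } else if (params$n_compartments == 2L) {
    k10 <- v[["CL"]] / v[["V1"]]
    k12 <- v[["Q"]] / v[["V1"]]
    k21 <- v[["Q"]] / v[["V2"]]
    M <- matrix(c(-(k10 + k12), k21,
                  k12, -k21), 2, 2, byrow = TRUE)
  } else {
    k10 <- v[["CL"]] / v[["V1"]]
    k12 <- v[["Q1"]] / v[["V1"]]
    k21 <- v[["Q1"]] / v[["V2"]]
    k13 <- v[["Q2"]] / v[["V1"]]
    k31 <- v[["Q2"]] / v[["V3"]]
    M <- matrix(c(-(k10 + k12 + k13), k21, k31,
                  k12, -k21, 0,
                  k13, 0, -k31), 3, 3, byrow = TRUE)
  }
  M
}

# Symmetrized eigendecomposition of a mammillary rate matrix.  With
# s_j = sqrt(k1j/kj1) the similarity diag(1/s) M diag(s) is symmetric, so
# the eigenvalues are real and the decomposition numerically stable.
# Returns everything needed to propagate a segment in closed form.
rate_decomp <- function(M) {
  n <- nrow(M)
  s <- c(1, sqrt(M[2:n, 1] / M[1, 2:n]))
  B <- M * tcrossprod(1 / s, s)
  eig <- eigen(B, symmetric = TRUE)
  list(M = M, n = n, s = s, U = eig$vectors, lambda = eig$values,
       minv1 = solve(M)[, 1])
}

# Advance amounts over one segment of length h with constant central input
# rate (umol/h).  Exact for the linear system:
#   A(h) = Ass + e^{Mh} (A0 - Ass),  Ass = -M^{-1} r.
propagate_segment <- function(dec, a0, rate_in, h) {
  ass <- if (rate_in > 0) -dec$minv1 * rate_in else numeric(dec$n)
  d <- (a0 - ass) / dec$s
  w <- crossprod(dec$U, d)
  d2 <- dec$U %*% (exp(dec$lambda * h) * w)
  ass + dec$s * as.numeric(d2)
}

# Shared segmentation of the time axis: breakpoints at every event edge,
# occasion boundary and query time.
profile_breaks <- function(regimen, times) {
  ev <- regimen$events
  sort(unique(c(0, regimen$occasions, ev$start, ev$start + ev$duration, times)))
}

segment_rate <- function(regimen, t_mid) {
  ev <- regimen$events
  act <- ev$start <= t_mid & t_mid < ev$start + ev$duration
  sum(ev$amount[act] / ev$duration[act])
}

normalize_params_list <- function(params, n_occ) {
  if (inherits(params, "mtx_params")) {
    rep(list(params), n_occ)
  } else {
    stopifnot(is.list(params), length(params) == n_occ)
    params
  }
}

#' Concentration-time profile by exact piecewise propagation
#'
#' Propagates the linear compartment system through the segments defined
#' by infusion edges and occasion boundaries using the matrix-exponential
#' solution (via a symmetrized eigendecomposition), which is exact for
#' piecewise-constant input.  Query times falling on a segment boundary
#' are evaluated as the end of the completed segment.
#'
#' @param params An `mtx_params` object, or a list of them (one per
#'   occasion of `regimen`) for models with inter-occasion variability.
#' @param regimen An `mtx_regimen`.
#' @param times Sorted, non-negative query times (h).
#' @param amounts If `TRUE`, attach the per-compartment amounts (umol) as
#'   an `"amounts"` attribute (matrix, one row per time).
#' @return `data.frame` with columns `time` (h) and `conc` (umol/L).
#' @export
concentration_profile <- function(params, regimen, times, amounts = FALSE) {
  stopifnot(inherits(regimen, "mtx_regimen"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("concentration_profile(): times must be sorted and >= 0",
         call. = FALSE)
  }
  occ <- regimen$occasions
  plist <- normalize_params_list(params, length(occ))
  breaks <- profile_breaks(regimen, times)
  breaks <- breaks[breaks <= max(times)]
  n <- plist[[1]]$n_compartments
  decs <- vector("list", length(occ))

  a <- numeric(n)
  conc_at <- numeric(length(breaks))
  amt_at <- if (amounts) matrix(0, length(breaks), n) else NULL
  v1_first <- plist[[1]]$values[["V1"]]
  conc_at[1] <- a[1] / v1_first
  for (i in seq_along(breaks)[-1]) {
    h <- breaks[i] - breaks[i - 1]
    mid <- (breaks[i] + breaks[i - 1]) / 2
    io <- max(1L, findInterval(mid, occ))
    if (is.null(decs[[io]])) decs[[io]] <- rate_decomp(rate_matrix(plist[[io]]))
    a <- propagate_segment(decs[[io]], a, segment_rate(regimen, mid), h)
    conc_at[i] <- a[1] / plist[[io]]$values[["V1"]]
    if (amounts) amt_at[i, ] <- a
  }
  idx <- match(times, breaks)
  out <- data.frame(time = times, conc = pmax(conc_at[idx], 0))
  if (amounts) attr(out, "amounts") <- amt_at[idx, , drop = FALSE]
  out
}

#' Concentration-time profile by adaptive ODE integration
#'
#' Independent reference solver: integrates the same system with
#' `deSolve::lsoda` segment by segment at tight tolerances.  Used to
#' cross-check [concentration_profile()]; it is not meant for production
#' use.
#'
#' @inheritParams concentration_profile
#' @param rtol,atol Integration tolerances.
#' @return `data.frame` with columns `time` and `conc`.
#' @export
ode_reference <- function(params, regimen, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(regimen, "mtx_regimen"))
  occ <- regimen$occasions
  plist <- normalize_params_list(params, length(occ))
  breaks <- profile_breaks(regimen, times)
  breaks <- breaks[breaks <= max(times)]
  n <- plist[[1]]$n_compartments

  a <- numeric(n)
  conc_at <- numeric(length(breaks))
  conc_at[1] <- a[1] / plist[[1]]$values[["V1"]]
  for (i in seq_along(breaks)[-1]) {
    mid <- (breaks[i] + breaks[i - 1]) / 2
    io <- max(1L, findInterval(mid, occ))
    M <- rate_matrix(plist[[io]])
    r <- segment_rate(regimen, mid)
    deriv <- function(t, y, p) list(as.numeric(M %*% y) + c(r, numeric(n - 1)))
    sol <- deSolve::lsoda(a, c(breaks[i - 1], breaks[i]), deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    a <- as.numeric(sol[nrow(sol), -1])
    conc_at[i] <- a[1] / plist[[io]]$values[["V1"]]
  }
  data.frame(time = times, conc = pmax(conc_at[match(times, breaks)], 0))
}
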