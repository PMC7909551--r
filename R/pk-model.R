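#' Dose-event table
#'
#' Builds a validated tibble of intravenous infusion events. Times are hours
#' since the start of the first infusion; amounts are milligrams.
#'
#' @param start_time Numeric vector, infusion start times (h), non-negative,
#'   sorted increasing.
#' @param amount Numeric vector, dose amounts (mg), strictly positive.
#' @param infusion_duration Numeric vector, infusion durations (h), strictly
#'   positive. Recycled to the length of `start_time`.
#'
#' @return A tibble with columns `start_time`, `amount`, `infusion_duration`.
#' @examples
#' dose_events(c(0, 24, 48), 400, 0.5)
#' @export
dose_events <- function(start_time, amount, infusion_duration = 0.5) {
  n <- length(start_time)
  amount <- rep_len(amount, n)
  infusion_duration <- rep_len(infusion_duration, n)
  if (any(!is.finite(start_time)) || any(start_time < 0)) {
    abort("dose start times must be finite and non-negative")
  }
  if (is.unsorted(start_time)) {
    abort("dose events must be sorted by start_time")
  }
  if (any(amount <= 0)) abort("dose amounts must be strictly positive")
  if (any(infusion_duration <= 0)) {
    abort("infusion durations must be strictly positive")
  }
  tibble::tibble(
    start_time = as.numeric(start_time),
    amount = as.numeric(amount),
    infusion_duration = as.numeric(infusion_duration)
  )
}

#' Covariate model for clearance
#'
#' The final structural model scales clearance by renal function:
#' `CL = CLs * (CCr / reference)`, where `CLs` is the clearance of a subject
#' at the reference creatinine clearance. The default reference is the study
#' population mean CCr of 52.9 mL/min (the cohort median, 52.1 mL/min, may
#' be selected instead).
#'
#' @param covariate Name of the cohort column carrying the covariate
#'   (default `"ccr"`).
#' @param reference Reference covariate value at which `CLs` is expressed
#'   (default 52.9 mL/min).
#'
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(covariate = "ccr", reference = 52.9) {
  if (!is.character(covariate) || length(covariate) != 1L) {
    abort("`covariate` must be a single column name")
  }
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    abort("`reference` must be a single positive number")
  }
  structure(
    list(covariate = covariate, reference = as.numeric(reference)),
    class = "covariate_model"
  )
}

#' @export
print.covariate_model <- function(x, ...) {
  cat(sprintf(
    "<covariate_model> CL = CLs * (%s / %g)\n", x$covariate, x$reference
  ))
  invisible(x)
}

#' Individual clearance under the renal covariate model
#'
#' @param CLs Clearance at the reference covariate value (L/h).
#' @param CCr Creatinine clearance of the individual (mL/min).
#' @param reference_ccr Reference creatinine clearance (mL/min), default
#'   52.9.
#'
#' @return Individual clearance `CLs * CCr / reference_ccr` (L/h).
#' @examples
#' individual_clearance(2.25, 40) # reduced renal function
#' @export
individual_clearance <- function(CLs, CCr, reference_ccr = 52.9) {
  if (any(CLs <= 0) || any(CCr <= 0) || any(reference_ccr <= 0)) {
    abort("CLs, CCr and reference_ccr must be strictly positive")
  }
  CLs * CCr / reference_ccr
}

#' First-order elimination rate constant
#'
#' @param CL Clearance (L/h).
#' @param V Volume of distribution (L).
#' @return `ke = CL / V` (1/h).
#' @export
elimination_rate <- function(CL, V) {
  if (any(CL <= 0) || any(V <= 0)) {
    abort("CL and V must be strictly positive")
  }
  CL / V
}

# Closed-form one-compartment infusion model, vectorised over a parameter
# grid. CL, V: length-K vectors; returns a K x length(times) matrix of
# central concentrations (mg/L) by superposition over dose events.
conc1_matrix <- function(CL, V, doses, times) {
  K <- length(CL)
  ke <- CL / V
  out <- matrix(0, nrow = K, ncol = length(times))
  for (j in seq_len(nrow(doses))) {
    t0 <- doses$start_time[j]
    dur <- doses$infusion_duration[j]
    R0 <- doses$amount[j] / dur
    for (ti in seq_along(times)) {
      tau <- times[ti] - t0
      if (tau <= 0) next
      if (tau <= dur) {
        out[, ti] <- out[, ti] + (R0 / CL) * (1 - exp(-ke * tau))
      } else {
        out[, ti] <- out[, ti] +
          (R0 / CL) * (1 - exp(-ke * dur)) * exp(-ke * (tau - dur))
      }
    }
  }
  out
}

# Closed-form two-compartment infusion model (central concentration),
# vectorised over a parameter grid like conc1_matrix.
conc2_matrix <- function(CL, V, Q, Vp, doses, times) {
  K <- length(CL)
  k10 <- CL / V
  k12 <- Q / V
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  out <- matrix(0, nrow = K, ncol = length(times))
  for (j in seq_len(nrow(doses))) {
    t0 <- doses$start_time[j]
    dur <- doses$infusion_duration[j]
    R0 <- doses$amount[j] / dur
    for (ti in seq_along(times)) {
      tau <- times[ti] - t0
      if (tau <= 0) next
      if (tau <= dur) {
        out[, ti] <- out[, ti] + (R0 / V) * (
          (A / alpha) * (1 - exp(-alpha * tau)) +
            (B / beta) * (1 - exp(-beta * tau))
        )
      } else {
        out[, ti] <- out[, ti] + (R0 / V) * (
          (A / alpha) * (1 - exp(-alpha * dur)) * exp(-alpha * (tau - dur)) +
            (B / beta) * (1 - exp(-beta * dur)) * exp(-beta * (tau - dur))
        )
      }
    }
  }
  out
}

#' One-compartment concentration-time profile
#'
#' Closed-form central concentrations for a linear one-compartment model with
#' zero-order (constant-rate) infusion input and first-order elimination,
#' superposed over an arbitrary dose history. No ODE solver is involved: the
#' analytic solution is exact, which matters for Monte Carlo simulation at
#' scale.
#'
#' @param CL Clearance (L/h), a single positive number.
#' @param V Volume of distribution (L), a single positive number.
#' @param doses A dose-event tibble from [dose_events()].
#' @param times Numeric vector of times (h since first infusion start),
#'   non-negative.
#'
#' @return A tibble with columns `time_h` and `conc_mg_L`.
#' @examples
#' concentration_profile(2.25, 18, dose_events(0, 800, 0.5), c(1, 23.5))
#' @export
concentration_profile <- function(CL, V, doses, times) {
  check_profile_inputs(CL, V, doses, times)
  conc <- conc1_matrix(CL, V, doses, times)[1L, ]
  tibble::tibble(time_h = as.numeric(times), conc_mg_L = conc)
}

#' Two-compartment concentration-time profile
#'
#' Bi-exponential closed form (macro rate constants derived from `CL`, `V`,
#' `Q`, `Vp`) with infusion input and superposition. Retained as the model
#' comparator: with sparse peak/trough sampling the one-compartment model is
#' typically the selected structure, and no covariates are placed on `Q` or
#' `Vp`.
#'
#' @inheritParams concentration_profile
#' @param Q Intercompartmental clearance (L/h), positive.
#' @param Vp Peripheral volume of distribution (L), positive.
#'
#' @return A tibble with columns `time_h` and `conc_mg_L` (central
#'   compartment).
#' @export
two_compartment_profile <- function(CL, V, Q, Vp, doses, times) {
  if (missing(Q) || missing(Vp) || is.null(Q) || is.null(Vp)) {
    abort("two-compartment profile requires Q and Vp")
  }
  if (!is.numeric(Q) || !is.numeric(Vp) || Q <= 0 || Vp <= 0) {
    abort("Q and Vp must be strictly positive")
  }
  check_profile_inputs(CL, V, doses, times)
  conc <- conc2_matrix(CL, V, Q, Vp, doses, times)[1L, ]
  tibble::tibble(time_h = as.numeric(times), conc_mg_L = conc)
}

check_profile_inputs <- function(CL, V, doses, times) {
  if (!is.numeric(CL) || length(CL) != 1L || CL <= 0) {
    abort("CL must be a single positive number")
  }
  if (!is.numeric(V) || length(V) != 1L || V <= 0) {
    abort("V must be a single positive number")
  }
  if (!is.data.frame(doses) ||
      !all(c("start_time", "amount", "infusion_duration") %in% names(doses))) {
    abort("`doses` must be a dose_events() tibble")
  }
  if (any(times < 0)) abort("times must be non-negative")
  invisible(TRUE)
}
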