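# Independent numerical oracle: piecewise integration of the compartment
# ODEs with deSolve, segment by segment between infusion on/off switches so
# the input discontinuities never cross an integration step.
ode_conc_oracle <- function(CL, V, doses, times, Q = NULL, Vp = NULL) {
  testthat::skip_if_not_installed("deSolve")
  two <- !is.null(Q)
  k10 <- CL / V
  deriv <- function(t, y, parms) {
    r <- parms$rate
    if (two) {
      k12 <- Q / V
      k21 <- Q / Vp
      list(c(r - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    } else {
      list(c(r - k10 * y[1]))
    }
  }
  switches <- sort(unique(c(
    0, doses$start_time, doses$start_time + doses$infusion_duration, times
  )))
  y <- if (two) c(A1 = 0, A2 = 0) else c(A1 = 0)
  out <- setNames(numeric(length(times)), as.character(times))
  if (any(times == 0)) out[as.character(0)] <- 0
  for (i in seq_len(length(switches) - 1)) {
    t0 <- switches[i]
    t1 <- switches[i + 1]
    mid <- (t0 + t1) / 2
    rate <- sum(
      doses$amount / doses$infusion_duration *
        (mid >= doses$start_time &
           mid < doses$start_time + doses$infusion_duration)
    )
    sol <- deSolve::lsoda(
      y, c(t0, t1), deriv, parms = list(rate = rate),
      rtol = 1e-12, atol = 1e-12
    )
    y <- sol[nrow(sol), -1]
    if (length(y) == 1) names(y) <- "A1"
    if (t1 %in% times) out[as.character(t1)] <- unname(y["A1"]) / V
  }
  unname(out[as.character(times)])
}

# Deterministic single-subject cohort tibble from explicit pieces; defaults
# give a typical elderly subject at the reference creatinine clearance.
make_subject <- function(id = "S1", dose_times = 0, amount = 800,
                         infusion = 0.5, obs_times = c(1, 23.5),
                         conc = NULL, blq = FALSE, ccr = 52.9,
                         CL = 2.25, V = 18) {
  doses <- dose_events(dose_times, amount, infusion)
  if (is.null(conc)) {
    conc <- concentration_profile(CL, V, doses, obs_times)$conc_mg_L
  }
  dplyr::bind_rows(
    tibble::tibble(
      id = id, time_h = doses$start_time, event_type = "dose",
      amount_mg = doses$amount, infusion_h = doses$infusion_duration,
      conc_mg_L = NA_real_, blq_flag = NA
    ),
    tibble::tibble(
      id = id, time_h = obs_times, event_type = "obs",
      amount_mg = NA_real_, infusion_h = NA_real_,
      conc_mg_L = conc, blq_flag = rep_len(blq, length(obs_times))
    )
  ) |>
    dplyr::arrange(time_h, event_type) |>
    dplyr::mutate(ccr = ccr, age = 80, sex = "female", weight_kg = 44.8,
                  height_m = 1.53, scr = 0.8)
}

# Informative six-point schedule used by the recovery experiments: peaks,
# mid-interval washout samples and a trough, all above the assay LOD for
# fast-clearance subjects.
recovery_design <- function() {
  sampling_design(schedule = c(1, 4, 8, 12, 23.75, 25))
}
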