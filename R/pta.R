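#' Dosing regimen
#'
#' @param dose Dose amount (mg), positive.
#' @param interval Dosing interval (h): 24, 48 or 72.
#' @param infusion_duration Infusion duration (h), default 0.5.
#'
#' @return An object of class `regimen`.
#' @examples
#' regimen(1800, 72)
#' @export
regimen <- function(dose, interval, infusion_duration = 0.5) {
  if (!is.numeric(dose) || dose <= 0) abort("dose must be positive")
  if (!interval %in% c(24, 48, 72)) {
    abort("interval must be one of 24, 48, 72 h")
  }
  if (infusion_duration <= 0 || infusion_duration >= interval) {
    abort("infusion_duration must be positive and shorter than the interval")
  }
  structure(
    list(dose = dose, interval = interval,
         infusion_duration = infusion_duration),
    class = "regimen"
  )
}

#' Pharmacodynamic target definition
#'
#' Efficacy: peak-to-MIC ratio of at least `efficacy_ratio` (default 8).
#' Safety: first-course trough below `safety_cmin` mg/L (default 4; strict
#' `<` by default, `<=` selectable — indistinguishable in practice for a
#' continuous simulation).
#'
#' @param efficacy_ratio Cmax/MIC threshold, positive.
#' @param safety_cmin Trough safety threshold (mg/L), positive.
#' @param safety_strict Use strict `<` for the safety comparison?
#'
#' @return An object of class `target_definition`.
#' @export
target_definition <- function(efficacy_ratio = 8, safety_cmin = 4,
                              safety_strict = TRUE) {
  if (efficacy_ratio <= 0 || safety_cmin <= 0) {
    abort("thresholds must be positive")
  }
  structure(
    list(efficacy_ratio = efficacy_ratio, safety_cmin = safety_cmin,
         safety_strict = safety_strict),
    class = "target_definition"
  )
}

#' Simulate first-course exposures for a regimen
#'
#' Draws `n` virtual subjects from the population distribution at a fixed
#' creatinine clearance and evaluates, in closed form, the peak 1 h after the
#' start of the first infusion and the trough just before the second dose
#' (at `interval - 0.5` h after the start of the first infusion, i.e. 23.5,
#' 47.5 or 71.5 h for q24h/q48h/q72h): first-course exposures, matching an
#' initial-dose nomogram's question, not steady state.
#'
#' @param pop A `pop_model` (parametric or fitted discrete).
#' @param regimen A [regimen()].
#' @param ccr Creatinine clearance (mL/min), a single positive value.
#' @param n Number of virtual subjects (default 1000).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `CLs`, `V`, `CL`, `cmax`, `cmin`.
#' @examples
#' simulate_exposures(population_model(), regimen(1800, 72), ccr = 50,
#'                    n = 100, seed = 1)
#' @export
simulate_exposures <- function(pop, regimen, ccr, n = 1000, seed = NULL) {
  stopifnot(inherits(pop, "pop_model"), inherits(regimen, "regimen"))
  if (!is.numeric(ccr) || length(ccr) != 1L || ccr <= 0) {
    abort("ccr must be a single positive value")
  }
  if (n < 1) abort("n must be at least 1")
  if (!is.null(seed)) withr::local_seed(seed)
  draws <- sample_population(pop, covariates = rep(ccr, n))
  CL <- if (is.null(pop$covariate_model)) draws$CLs else draws$CL
  doses <- dose_events(0, regimen$dose, regimen$infusion_duration)
  times <- c(1, regimen$interval - 0.5)
  conc <- conc1_matrix(CL, draws$V, doses, times)
  tibble::tibble(
    CLs = draws$CLs, V = draws$V, CL = CL,
    cmax = conc[, 1], cmin = conc[, 2]
  )
}

#' Probability of target attainment from simulated exposures
#'
#' @param samples An exposure tibble from [simulate_exposures()] (columns
#'   `cmax`, `cmin`).
#' @param mic Minimum inhibitory concentration (mg/L), positive.
#' @param targets A [target_definition()].
#'
#' @return A one-row tibble: `mic`, `efficacy_pct` (% with
#'   `cmax/mic >= efficacy_ratio`), `safety_pct` (% with `cmin` below the
#'   safety threshold), `joint_pct` (% satisfying both on the same draw),
#'   `n`.
#' @export
pta <- function(samples, mic, targets = target_definition()) {
  if (!is.data.frame(samples) || nrow(samples) == 0L ||
      !all(c("cmax", "cmin") %in% names(samples))) {
    abort("samples must be a non-empty tibble with cmax and cmin columns")
  }
  if (!is.numeric(mic) || length(mic) != 1L || mic <= 0) {
    abort("mic must be a single positive value")
  }
  eff <- samples$cmax / mic >= targets$efficacy_ratio
  safe <- if (targets$safety_strict) {
    samples$cmin < targets$safety_cmin
  } else {
    samples$cmin <= targets$safety_cmin
  }
  tibble::tibble(
    mic = mic,
    efficacy_pct = 100 * mean(eff),
    safety_pct = 100 * mean(safe),
    joint_pct = 100 * mean(eff & safe),
    n = nrow(samples)
  )
}

#' Full PTA grid over doses, intervals, renal function and MICs
#'
#' Factorial Monte Carlo evaluation with common random numbers: one set of
#' `n` population draws `(CLs, V)` is taken once per table (seeded,
#' recorded in the `cell_seed` column) and shared by every cell.
#' Individual clearance, peak and trough follow deterministically from a
#' draw given the cell's CCr, dose and interval, so sharing draws removes
#' between-cell Monte Carlo noise: attainment is then exactly monotone in
#' dose, MIC, CCr and interval wherever the underlying exposure is, which
#' is what a dosing table is read for.
#'
#' @param pop A `pop_model`.
#' @param doses Dose grid (mg), default 200-2000 by 200.
#' @param intervals Dosing intervals (h), default `c(24, 48, 72)`.
#' @param ccr_values Creatinine clearances (mL/min), default 10-90 by 10.
#' @param mics MICs to evaluate (mg/L), default `c(4, 8, 16)`.
#' @param targets A [target_definition()].
#' @param n Virtual subjects per cell (default 1000).
#' @param seed Integer seed for the shared population draws.
#' @param infusion_duration Infusion duration (h), default 0.5.
#'
#' @return A tibble of class `amik_pta_grid` with columns `ccr`, `dose`,
#'   `interval`, `mic`, `efficacy_pct`, `safety_pct`, `joint_pct`, `n`,
#'   `cell_seed`.
#' @export
pta_table <- function(pop,
                      doses = seq(200, 2000, by = 200),
                      intervals = c(24, 48, 72),
                      ccr_values = seq(10, 90, by = 10),
                      mics = c(4, 8, 16),
                      targets = target_definition(),
                      n = 1000,
                      seed = 1,
                      infusion_duration = 0.5) {
  if (length(doses) == 0L || length(intervals) == 0L ||
      length(ccr_values) == 0L || length(mics) == 0L) {
    abort("dose, interval, ccr and mic grids must be non-empty")
  }
  withr::local_seed(seed)
  base_draws <- draw_support(pop, n)
  cm <- pop$covariate_model
  cells <- tidyr::expand_grid(ccr = ccr_values, dose = doses,
                              interval = intervals)
  out <- purrr::pmap_dfr(
    list(cells$ccr, cells$dose, cells$interval),
    function(ccr, dose, interval) {
      CL <- if (is.null(cm)) {
        base_draws$CLs
      } else {
        individual_clearance(base_draws$CLs, ccr, cm$reference)
      }
      conc <- conc1_matrix(CL, base_draws$V,
                           dose_events(0, dose, infusion_duration),
                           c(1, interval - 0.5))
      samples <- tibble::tibble(cmax = conc[, 1], cmin = conc[, 2])
      purrr::map_dfr(mics, function(m) {
        dplyr::bind_cols(
          tibble::tibble(ccr = ccr, dose = dose, interval = interval),
          pta(samples, m, targets),
          tibble::tibble(cell_seed = seed)
        )
      })
    }
  )
  class(out) <- c("amik_pta_grid", class(out))
  attr(out, "targets") <- targets
  out
}

#' Fractional target attainment
#'
#' Weighted average of joint attainment over an observed MIC frequency
#' distribution: `FTA = sum_m freq(m) * jointPTA(m)`. Every MIC of the
#' distribution must have a computed PTA entry; nothing is interpolated or
#' extrapolated.
#'
#' @param pta_by_mic A tibble with columns `mic` and `joint_pct` (one row per
#'   MIC), e.g. one regimen's rows of a [pta_table()].
#' @param dist A [mic_distribution()].
#'
#' @return The fractional target attainment (%), a single number.
#' @examples
#' fta(tibble::tibble(mic = c(4, 8), joint_pct = c(80, 100)),
#'     mic_distribution(c(4, 8), c(0.5, 0.5)))
#' @export
fta <- function(pta_by_mic, dist) {
  stopifnot(inherits(dist, "mic_distribution"))
  if (abs(sum(dist$frequency) - 1) > 1e-9) {
    abort("MIC distribution frequencies must sum to 1")
  }
  idx <- match(dist$mic, pta_by_mic$mic)
  if (anyNA(idx)) {
    abort(sprintf(
      "no PTA entry for MIC(s): %s",
      paste(dist$mic[is.na(idx)], collapse = ", ")
    ))
  }
  sum(dist$frequency * pta_by_mic$joint_pct[idx])
}

#' Fractional target attainment per regimen over a PTA grid
#'
#' @param grid A [pta_table()] result whose `mic` column covers the
#'   distribution's MICs.
#' @param dist A [mic_distribution()].
#'
#' @return A tibble `ccr`, `dose`, `interval`, `fta_pct`.
#' @export
fta_table <- function(grid, dist) {
  grid |>
    dplyr::group_by(.data$ccr, .data$dose, .data$interval) |>
    dplyr::group_modify(~ tibble::tibble(fta_pct = fta(.x, dist))) |>
    dplyr::ungroup()
}

#' Reshape a PTA grid to the wide dose-by-renal-function layout
#'
#' @param grid A [pta_table()] result.
#' @param mic Which MIC's rows to spread.
#' @param interval Which dosing interval to spread.
#' @param measure `"joint_pct"`, `"efficacy_pct"` or `"safety_pct"`.
#'
#' @return A wide tibble: one row per CCr, one column per dose.
#' @export
pta_wide <- function(grid, mic, interval, measure = "joint_pct") {
  measure <- match.arg(measure,
                       c("joint_pct", "efficacy_pct", "safety_pct"))
  grid |>
    dplyr::filter(.data$mic == .env$mic,
                  .data$interval == .env$interval) |>
    dplyr::select("ccr", "dose", dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "dose",
                       values_from = dplyr::all_of(measure),
                       names_prefix = "mg_")
}
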