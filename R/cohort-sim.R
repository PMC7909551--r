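#' Body-size metrics
#'
#' Body mass index, ideal body weight (`22 * height^2`), and lean body weight
#' by the sex-specific Janmahasatian formula:
#' males `9270 * weight / (6680 + 216 * BMI)`,
#' females `9270 * weight / (8780 + 244 * BMI)`.
#'
#' @param height_m Height in metres, positive.
#' @param weight_kg Total body weight in kg, positive.
#' @param sex `"male"` or `"female"` (recycled).
#'
#' @return A tibble with columns `bmi` (kg/m^2), `ibw` (kg), `lbw` (kg).
#' @examples
#' derive_body_metrics(1.6, 56.32, "male")
#' @export
derive_body_metrics <- function(height_m, weight_kg, sex) {
  n <- max(length(height_m), length(weight_kg), length(sex))
  height_m <- rep_len(height_m, n)
  weight_kg <- rep_len(weight_kg, n)
  sex <- rep_len(tolower(as.character(sex)), n)
  if (any(height_m <= 0) || any(weight_kg <= 0)) {
    abort("height and weight must be strictly positive")
  }
  if (!all(sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  bmi <- weight_kg / height_m^2
  ibw <- 22 * height_m^2
  lbw <- ifelse(
    sex == "male",
    9270 * weight_kg / (6680 + 216 * bmi),
    9270 * weight_kg / (8780 + 244 * bmi)
  )
  tibble::tibble(bmi = bmi, ibw = ibw, lbw = lbw)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CCr = (140 - age) * weight / (72 * sCr)`, multiplied by 0.85 for
#' females. The preferred renal-function estimate for elderly patients and
#' the sole clearance covariate in the final model.
#'
#' @param age Age in years, positive and at most 140.
#' @param weight_kg Total body weight (kg), positive.
#' @param scr Serum creatinine (mg/dL), strictly positive.
#' @param sex `"male"` or `"female"`.
#'
#' @return Creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(80, 42.6, 0.59, "male")
#' @export
cockcroft_gault <- function(age, weight_kg, scr, sex) {
  n <- max(length(age), length(weight_kg), length(scr), length(sex))
  age <- rep_len(age, n)
  weight_kg <- rep_len(weight_kg, n)
  scr <- rep_len(scr, n)
  sex <- rep_len(tolower(as.character(sex)), n)
  if (any(scr <= 0)) abort("serum creatinine must be strictly positive")
  if (any(age <= 0) || any(age > 140)) abort("age must be in (0, 140]")
  if (any(weight_kg <= 0)) abort("weight must be strictly positive")
  if (!all(sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  ccr <- (140 - age) * weight_kg / (72 * scr)
  ifelse(sex == "female", 0.85 * ccr, ccr)
}

#' Sparse TDM sampling design
#'
#' Describes how the synthetic cohort generator doses and samples virtual
#' subjects. The defaults emulate an elderly hospital TDM cohort: once-daily
#' 30-min to 1-h infusions of 200-1000 mg, a peak drawn about 1 h after the
#' infusion starts and troughs drawn shortly before a subsequent dose, two to
#' three samples per subject, and covariates spanning the observed ranges
#' (age 71-95 y, weight 32.5-67.3 kg, BMI 14.9-25.6 kg/m^2, CCr 10.9-94.9
#' mL/min, 9 of 15 subjects female).
#'
#' Samples are allocated per dosing occasion in the order peak after dose 1,
#' trough before dose 2, peak after dose 2, trough before dose 3, ...; the
#' first `n_samples` entries are used, so `n_samples = 2` gives the classic
#' peak/trough pair and `n_samples = 6` a rich three-occasion design.
#'
#' @param n_doses Number of administrations per subject.
#' @param interval Dosing interval (h).
#' @param dose_choices Candidate dose amounts (mg), sampled uniformly per
#'   subject.
#' @param infusion_choices Candidate infusion durations (h).
#' @param p_infusion Sampling probabilities for `infusion_choices`.
#' @param n_samples_choices Candidate numbers of observations per subject.
#' @param p_samples Sampling probabilities for `n_samples_choices`.
#' @param peak_offset Peak sampling time after infusion start (h).
#' @param trough_lead Trough sampling lead before the next dose (h).
#' @param covariate_ranges Named list of `c(min, max)` uniform ranges for
#'   `age`, `weight`, `bmi`, `ccr`.
#' @param p_female Probability a virtual subject is female.
#' @param schedule Optional explicit numeric vector of sampling times (h
#'   since first infusion start), overriding the peak/trough allocation;
#'   every subject is then sampled at exactly these times. Use an
#'   informative spread (e.g. `c(1, 4, 8, 12, 23.75, 25)`) for parameter
#'   recovery studies, where mid-interval samples keep fast-clearance
#'   subjects above the assay LOD.
#'
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(n_doses = 3,
                            interval = 24,
                            dose_choices = seq(200, 1000, by = 100),
                            infusion_choices = c(0.5, 1),
                            p_infusion = c(2 / 3, 1 / 3),
                            n_samples_choices = c(2, 3),
                            p_samples = c(0.8, 0.2),
                            peak_offset = 1,
                            trough_lead = 0.25,
                            covariate_ranges = list(
                              age = c(71, 95),
                              weight = c(32.5, 67.3),
                              bmi = c(14.9, 25.6),
                              ccr = c(10.9, 94.9)
                            ),
                            p_female = 0.6,
                            schedule = NULL) {
  stopifnot(
    n_doses >= 1, interval > 0, all(dose_choices > 0),
    all(infusion_choices > 0), peak_offset > 0, trough_lead > 0,
    trough_lead < interval, max(n_samples_choices) <= 2 * n_doses
  )
  if (!is.null(schedule)) {
    stopifnot(is.numeric(schedule), all(schedule > 0),
              !is.unsorted(schedule, strictly = TRUE))
  }
  structure(
    list(
      n_doses = n_doses, interval = interval, dose_choices = dose_choices,
      infusion_choices = infusion_choices, p_infusion = p_infusion,
      n_samples_choices = n_samples_choices, p_samples = p_samples,
      peak_offset = peak_offset, trough_lead = trough_lead,
      covariate_ranges = covariate_ranges, p_female = p_female,
      schedule = schedule
    ),
    class = "sampling_design"
  )
}

# Observation times for k samples under a design: alternating peak/trough
# per occasion (peak j at (j-1)*interval + peak_offset, trough j just
# before dose j+1 at j*interval - trough_lead).
design_sample_times <- function(design, k) {
  if (!is.null(design$schedule)) {
    return(tibble::tibble(time_h = design$schedule,
                          sample_type = "scheduled"))
  }
  occ <- seq_len(design$n_doses)
  peaks <- (occ - 1) * design$interval + design$peak_offset
  troughs <- occ * design$interval - design$trough_lead
  times <- as.vector(rbind(peaks, troughs))
  types <- rep(c("peak", "trough"), times = design$n_doses)
  idx <- seq_len(k)
  tibble::tibble(time_h = times[idx], sample_type = types[idx]) |>
    dplyr::arrange(.data$time_h)
}

#' Draw covariate sets for virtual subjects
#'
#' Age, weight and BMI are drawn uniformly within the configured ranges and
#' height derived from BMI; the target creatinine clearance is drawn
#' uniformly and serum creatinine back-solved through the Cockcroft-Gault
#' equation, so every generated covariate set is internally consistent
#' (BMI = weight/height^2 and CCr = Cockcroft-Gault hold exactly).
#'
#' @param n Number of subjects.
#' @param design A [sampling_design()] supplying ranges and the female
#'   fraction.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `id`, `age`, `sex`, `weight_kg`, `height_m`,
#'   `bmi`, `ibw`, `lbw`, `scr`, `ccr`.
#' @export
simulate_covariates <- function(n, design = sampling_design(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rng <- design$covariate_ranges
  age <- runif(n, rng$age[1], rng$age[2])
  weight <- runif(n, rng$weight[1], rng$weight[2])
  bmi <- runif(n, rng$bmi[1], rng$bmi[2])
  height <- sqrt(weight / bmi)
  sex <- ifelse(runif(n) < design$p_female, "female", "male")
  ccr <- runif(n, rng$ccr[1], rng$ccr[2])
  scr <- (140 - age) * weight * ifelse(sex == "female", 0.85, 1) / (72 * ccr)
  metrics <- derive_body_metrics(height, weight, sex)
  tibble::tibble(
    id = paste0("S", sprintf("%03d", seq_len(n))),
    age = age, sex = sex, weight_kg = weight, height_m = height,
    bmi = metrics$bmi, ibw = metrics$ibw, lbw = metrics$lbw,
    scr = scr, ccr = ccr
  )
}

#' Draw individual PK parameters from a population model
#'
#' Draws `(CLs_i, V_i)` pairs from the population distribution and scales
#' clearance by the covariate model: `CL_i = CLs_i * CCr_i / reference`.
#' For a parametric population model the configured family (default
#' log-normal matched to the population mean and CV, truncated at 0.1x-10x
#' the mean) is sampled; for a fitted discrete (nonparametric) model,
#' support points are resampled according to their probabilities.
#'
#' @param pop A [population_model()] or fitted `npag_fit` object.
#' @param covariates A covariate tibble with a column named after the
#'   covariate model's covariate (usually `ccr`), or a bare numeric vector of
#'   covariate values.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `CLs`, `V`, `CL`, one row per covariate row.
#' @examples
#' sample_population(population_model(), covariates = c(40, 52.9, 90), seed = 1)
#' @export
sample_population <- function(pop, covariates, seed = NULL) {
  stopifnot(inherits(pop, "pop_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  cm <- pop$covariate_model
  if (is.numeric(covariates)) {
    cov_values <- covariates
  } else {
    cov_col <- if (is.null(cm)) "ccr" else cm$covariate
    if (!cov_col %in% names(covariates)) {
      abort(sprintf("covariates must contain a '%s' column", cov_col))
    }
    cov_values <- covariates[[cov_col]]
  }
  n <- length(cov_values)
  draws <- draw_support(pop, n)
  CL <- if (is.null(cm)) {
    draws$CLs
  } else {
    individual_clearance(draws$CLs, cov_values, cm$reference)
  }
  tibble::tibble(CLs = draws$CLs, V = draws$V, CL = CL)
}

# Dispatch-free sampler over the two population-model flavours.
draw_support <- function(pop, n) {
  if (identical(pop$type, "discrete")) {
    idx <- sample.int(nrow(pop$support), n, replace = TRUE,
                      prob = pop$support$prob)
    list(CLs = pop$support$CLs[idx], V = pop$support$V[idx])
  } else if (identical(pop$type, "parametric")) {
    list(
      CLs = draw_param(n, pop$cl_mean, pop$cl_cv, pop$family, pop$truncation),
      V = draw_param(n, pop$v_mean, pop$v_cv, pop$family, pop$truncation)
    )
  } else {
    abort("unknown population model type")
  }
}

draw_param <- function(n, mean, cv, family, truncation) {
  lo <- truncation[1] * mean
  hi <- truncation[2] * mean
  draw1 <- function(m) {
    if (family == "lognormal") {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(m, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    } else if (family == "normal") {
      rnorm(m, mean = mean, sd = cv * mean)
    } else {
      abort(sprintf("unknown distribution family '%s'", family))
    }
  }
  x <- draw1(n)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- draw1(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
  }
  x
}

#' Simulate a sparse TDM cohort
#'
#' Generates a synthetic therapeutic-drug-monitoring cohort: covariates via
#' [simulate_covariates()], individual parameters via [sample_population()],
#' noise-free concentrations from the one-compartment infusion model,
#' perturbed by the assay error model `N(0, SD(C)^2)` with
#' `SD(C) = intercept_sd + proportional_sd * C`. Negative noisy draws are
#' resampled (truncation at zero); observations below the limit of detection
#' are flagged `blq` and stored as `LOD / 2`.
#'
#' @param pop A [population_model()] (or fitted model) to generate from.
#' @param n_subjects Number of subjects.
#' @param design A [sampling_design()].
#' @param error_model An [assay_error_model()]. Set both SD components to
#'   zero for noise-free data.
#' @param seed Optional integer seed.
#' @param n_samples Optional fixed number of observations per subject,
#'   overriding the design's random choice.
#'
#' @return A cohort tibble in long event form, one row per dose or
#'   observation, with columns `id`, `time_h`, `event_type`, `amount_mg`,
#'   `infusion_h`, `conc_mg_L`, `blq_flag`, `ccr`, `age`, `sex`, `weight_kg`,
#'   `height_m`, `scr`. The true individual parameters are attached as the
#'   `"truth"` attribute (a tibble `id`, `CLs`, `V`, `CL`) for recovery
#'   studies.
#' @examples
#' cohort <- simulate_tdm_cohort(population_model(), n_subjects = 3, seed = 1)
#' dplyr::count(cohort, event_type)
#' @export
simulate_tdm_cohort <- function(pop = population_model(),
                                n_subjects = 15,
                                design = sampling_design(),
                                error_model = assay_error_model(),
                                seed = NULL,
                                n_samples = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  covs <- simulate_covariates(n_subjects, design)
  pars <- sample_population(pop, covs)
  n_obs <- if (is.null(n_samples)) {
    sample(design$n_samples_choices, n_subjects, replace = TRUE,
           prob = design$p_samples)
  } else {
    rep_len(n_samples, n_subjects)
  }
  dose_amt <- sample(design$dose_choices, n_subjects, replace = TRUE)
  inf_dur <- sample(design$infusion_choices, n_subjects, replace = TRUE,
                    prob = design$p_infusion)
  rows <- vector("list", n_subjects)
  truth <- dplyr::bind_cols(covs["id"], pars)
  for (i in seq_len(n_subjects)) {
    doses <- dose_events(
      start_time = (seq_len(design$n_doses) - 1) * design$interval,
      amount = dose_amt[i],
      infusion_duration = inf_dur[i]
    )
    samp <- design_sample_times(design, n_obs[i])
    pred <- concentration_profile(pars$CL[i], pars$V[i], doses,
                                  samp$time_h)$conc_mg_L
    obs <- perturb_obs(pred, error_model)
    cov_i <- covs[i, ]
    dose_rows <- tibble::tibble(
      id = cov_i$id, time_h = doses$start_time, event_type = "dose",
      amount_mg = doses$amount, infusion_h = doses$infusion_duration,
      conc_mg_L = NA_real_, blq_flag = NA
    )
    obs_rows <- tibble::tibble(
      id = cov_i$id, time_h = samp$time_h, event_type = "obs",
      amount_mg = NA_real_, infusion_h = NA_real_,
      conc_mg_L = obs$value, blq_flag = obs$blq
    )
    rows[[i]] <- dplyr::bind_rows(dose_rows, obs_rows) |>
      dplyr::arrange(.data$time_h, .data$event_type) |>
      dplyr::mutate(
        ccr = cov_i$ccr, age = cov_i$age, sex = cov_i$sex,
        weight_kg = cov_i$weight_kg, height_m = cov_i$height_m,
        scr = cov_i$scr
      )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  out
}

# Additive+proportional Gaussian noise, truncated at zero by resampling;
# below-LOD values flagged and imputed at LOD/2.
perturb_obs <- function(pred, error_model) {
  sds <- assay_sd(error_model, pred)
  value <- pred
  if (any(sds > 0)) {
    value <- rnorm(length(pred), mean = pred, sd = sds)
    bad <- which(value < 0)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      value[bad] <- rnorm(length(bad), mean = pred[bad], sd = sds[bad])
      bad <- bad[value[bad] < 0]
      guard <- guard + 1L
    }
    value[value < 0] <- 0
  }
  blq <- value < error_model$lod
  value[blq] <- error_model$lod / 2
  list(value = value, blq = blq)
}
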