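#' Covariate scan for clearance
#'
#' Refits the population model with each candidate covariate scaling
#' clearance as `CL = CLs * (value / center)`, where the center is the cohort
#' median of the candidate, and reports the change in `-2LL` and AIC against
#' the covariate-free base model plus the coefficient of determination of
#' the base model's posterior clearances regressed on the candidate. A
#' candidate is included when it improves `-2LL` by more than 3.84 (the 5%
#' chi-square point on one degree of freedom) and decreases the AIC; ties
#' are broken by the largest `-2LL` improvement.
#'
#' @param cohort A cohort tibble in long event form.
#' @param base_model A fitted covariate-free `npag_fit`
#'   (`covariate_model = NULL`).
#' @param candidates Character vector of cohort column names to scan
#'   (e.g. `c("ccr", "age", "weight_kg")`).
#' @param options A [fit_options()] used for the candidate refits.
#' @param error_model An [assay_error_model()].
#'
#' @return A tibble with one row per candidate: `candidate`, `center`,
#'   `delta_neg2LL`, `delta_AIC`, `r2`, `included`, `note`; the winning
#'   candidate's refit is attached as attribute `"best_fit"` (or `NULL`).
#' @export
covariate_scan <- function(cohort, base_model, candidates,
                           options = fit_options(),
                           error_model = assay_error_model()) {
  stopifnot(inherits(base_model, "npag_fit"))
  if (!is.null(base_model$covariate_model)) {
    abort("base_model must be fitted without a covariate model")
  }
  subj_cov <- cohort |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
  post_cl <- base_model$posterior_means |>
    dplyr::left_join(subj_cov, by = "id")
  base_neg2LL <- -2 * base_model$logLik

  fits <- list()
  rows <- purrr::map_dfr(candidates, function(cand) {
    if (!cand %in% names(subj_cov)) {
      return(tibble::tibble(
        candidate = cand, center = NA_real_, delta_neg2LL = NA_real_,
        delta_AIC = NA_real_, r2 = NA_real_, included = FALSE,
        note = "missing column"
      ))
    }
    values <- subj_cov[[cand]]
    if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
      return(tibble::tibble(
        candidate = cand, center = NA_real_, delta_neg2LL = NA_real_,
        delta_AIC = NA_real_, r2 = NA_real_, included = FALSE,
        note = "non-positive or non-numeric"
      ))
    }
    center <- median(values)
    if (diff(range(values)) < .Machine$double.eps^0.5 * center) {
      return(tibble::tibble(
        candidate = cand, center = center, delta_neg2LL = NA_real_,
        delta_AIC = NA_real_, r2 = NA_real_, included = FALSE,
        note = "constant covariate, skipped"
      ))
    }
    cm <- covariate_model(covariate = cand, reference = center)
    fit <- npag_fit(cohort, options = options, error_model = error_model,
                    covariate_model = cm, model = base_model$model,
                    blq = base_model$blq %||% "censored")
    fits[[cand]] <<- fit
    r2 <- summary(lm(post_cl$CLs ~ post_cl[[cand]]))$r.squared
    d_neg2LL <- base_neg2LL - (-2 * fit$logLik)
    d_AIC <- fit$AIC - base_model$AIC
    tibble::tibble(
      candidate = cand, center = center, delta_neg2LL = d_neg2LL,
      delta_AIC = d_AIC, r2 = r2,
      included = d_neg2LL > 3.84 && d_AIC < 0,
      note = ""
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$included),
                         dplyr::desc(.data$delta_neg2LL))
  best <- rows$candidate[rows$included][1]
  attr(rows, "best_fit") <- if (!is.na(best) && length(best) == 1L) {
    fits[[best]]
  } else {
    NULL
  }
  class(rows) <- c("amik_covariate_scan", class(rows))
  rows
}
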