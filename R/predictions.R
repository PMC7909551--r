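#' Population and individual posterior predictions
#'
#' For every observation: the population prediction (probability-weighted
#' mean prediction over the support points), the individual posterior
#' prediction (weights proportional to prior probability times the subject's
#' likelihood, normalised per subject), and weighted residuals
#' `(obs - pred) / SD(pred)`. Cohort-level predictive performance is
#' summarised as bias (mean weighted prediction error) and imprecision
#' (mean squared weighted prediction error minus bias squared), for both the
#' population and the individual predictions.
#'
#' @param model A fitted `npag_fit` object (or any discrete population
#'   model with `support`/`prob`).
#' @param cohort A cohort tibble in long event form.
#' @param error_model An [assay_error_model()]; defaults to the one carried
#'   by the fit.
#'
#' @return A tibble with one row per observation: `id`, `time_h`, `obs`,
#'   `pop_pred`, `ind_pred`, `wres_pop`, `wres_ind`, plus attributes
#'   `bias_pop`, `imprecision_pop`, `bias_ind`, `imprecision_ind` and
#'   `posterior_weights` (per-subject posterior over support points).
#' @export
predictions <- function(model, cohort, error_model = NULL) {
  stopifnot(inherits(model, "pop_model"), identical(model$type, "discrete"))
  if (is.null(error_model)) error_model <- model$error_model
  if (is.null(error_model)) error_model <- assay_error_model()
  mdl <- model$model %||% "one_cpt"
  # residuals are undefined for censored observations: quantified obs only
  subjects <- prep_subjects(cohort, error_model, blq = "exclude")
  grid <- as.matrix(tibble::as_tibble(model$support)[param_names(mdl)])
  lambda <- model$support$prob
  rows <- vector("list", length(subjects))
  post_w <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (length(s$times) == 0L) {
      post_w[[i]] <- lambda
      next
    }
    CLs <- grid[, "CLs"]
    V <- grid[, "V"]
    cm <- model$covariate_model
    CL <- if (is.null(cm)) CLs else {
      CLs * s$covariates[[cm$covariate]] / cm$reference
    }
    pred <- if (mdl == "one_cpt") {
      conc1_matrix(CL, V, s$doses, s$times)
    } else {
      conc2_matrix(CL, V, grid[, "Q"], grid[, "Vp"], s$doses, s$times)
    }
    ll <- subject_loglik_grid(s, grid, cm, error_model, mdl)
    a <- max(ll)
    w <- lambda * exp(ll - a)
    w <- w / sum(w)
    post_w[[i]] <- w
    pop_pred <- as.vector(lambda %*% pred)
    ind_pred <- as.vector(w %*% pred)
    rows[[i]] <- tibble::tibble(
      id = s$id, time_h = s$times, obs = s$obs,
      pop_pred = pop_pred, ind_pred = ind_pred,
      wres_pop = (s$obs - pop_pred) / assay_sd(error_model, pop_pred),
      wres_ind = (s$obs - ind_pred) / assay_sd(error_model, ind_pred)
    )
  }
  out <- dplyr::bind_rows(rows)
  bias_pop <- mean(out$wres_pop)
  bias_ind <- mean(out$wres_ind)
  attr(out, "bias_pop") <- bias_pop
  attr(out, "imprecision_pop") <- mean(out$wres_pop^2) - bias_pop^2
  attr(out, "bias_ind") <- bias_ind
  attr(out, "imprecision_ind") <- mean(out$wres_ind^2) - bias_ind^2
  names(post_w) <- vapply(subjects, `[[`, character(1), "id")
  attr(out, "posterior_weights") <- post_w
  class(out) <- c("amik_predictions", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
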