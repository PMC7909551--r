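#' Parametric population model
#'
#' A parametric stand-in for the population distribution of the structural
#' parameters, parameterised by mean and coefficient of variation per
#' parameter. Defaults are the final-model estimates for amikacin in elderly
#' patients: clearance 2.25 L/h (CV 34.6%) at the reference creatinine
#' clearance and volume 18.0 L (CV 18.9%), log-normal and truncated at
#' 0.1x-10x the mean to guarantee positivity and sane tails.
#'
#' This object drives the synthetic cohort generator and the Monte Carlo
#' dosing simulations; fitted nonparametric models ([npag_fit()]) share its
#' `pop_model` class and can be used interchangeably wherever a population
#' distribution is sampled.
#'
#' @param cl_mean Mean clearance at the reference covariate value (L/h).
#' @param cl_cv Coefficient of variation of clearance (fraction, e.g. 0.346).
#' @param v_mean Mean volume of distribution (L).
#' @param v_cv Coefficient of variation of volume (fraction).
#' @param family `"lognormal"` (default) or `"normal"` (truncated).
#' @param covariate_model A [covariate_model()] (default CCr, reference
#'   52.9 mL/min), or `NULL` for no covariate scaling.
#' @param truncation Lower/upper truncation bounds as multiples of the mean.
#'
#' @return An object of class `c("parametric_pop", "pop_model")`.
#' @examples
#' population_model()
#' @export
population_model <- function(cl_mean = 2.25, cl_cv = 0.346,
                             v_mean = 18.0, v_cv = 0.189,
                             family = c("lognormal", "normal"),
                             covariate_model = amikelder::covariate_model(),
                             truncation = c(0.1, 10)) {
  family <- match.arg(family)
  stopifnot(
    cl_mean > 0, v_mean > 0, cl_cv > 0, v_cv > 0,
    length(truncation) == 2, truncation[1] < 1, truncation[2] > 1
  )
  structure(
    list(
      type = "parametric",
      cl_mean = cl_mean, cl_cv = cl_cv, v_mean = v_mean, v_cv = v_cv,
      family = family, covariate_model = covariate_model,
      truncation = truncation
    ),
    class = c("parametric_pop", "pop_model")
  )
}

#' @export
print.parametric_pop <- function(x, ...) {
  cat(sprintf(
    "<parametric population model (%s)>\n  CLs: mean %g L/h, CV %.1f%%\n  V:   mean %g L,   CV %.1f%%\n",
    x$family, x$cl_mean, 100 * x$cl_cv, x$v_mean, 100 * x$v_cv
  ))
  if (!is.null(x$covariate_model)) print(x$covariate_model)
  invisible(x)
}

#' Discrete population model from explicit support points
#'
#' Mostly useful in tests and for loading a previously fitted distribution:
#' a nonparametric population distribution is a set of support points with
#' probabilities.
#'
#' @param support A data frame with parameter columns (`CLs`, `V`, optionally
#'   `Q`, `Vp`).
#' @param prob Probabilities, one per row, non-negative, summing to 1 within
#'   1e-9.
#' @param covariate_model A [covariate_model()] or `NULL`.
#'
#' @return An object of class `c("discrete_pop", "pop_model")`.
#' @export
discrete_population <- function(support, prob,
                                covariate_model = amikelder::covariate_model()) {
  stopifnot(is.data.frame(support), nrow(support) == length(prob))
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-9) {
    abort("probabilities must be non-negative and sum to 1 (within 1e-9)")
  }
  support <- tibble::as_tibble(support)
  support$prob <- as.numeric(prob)
  structure(
    list(type = "discrete", support = support,
         covariate_model = covariate_model),
    class = c("discrete_pop", "pop_model")
  )
}

# Probability-weighted moments of a discrete distribution.
weighted_moments <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord])
  j <- which(cw >= 0.5 - 1e-12)[1]
  med <- if (abs(cw[j] - 0.5) < 1e-12 && j < length(xs)) {
    (xs[j] + xs[j + 1]) / 2
  } else {
    xs[j]
  }
  list(mean = m, sd = sqrt(v), median = med, var = v,
       cv_pct = 100 * sqrt(v) / m)
}

#' Parameter summary of a fitted population model
#'
#' Probability-weighted mean, SD, median, CV% and variance per structural
#' parameter, plus shrinkage, defined as
#' `100 * (1 - SD(posterior individual means) / SD(population))`: 0 when the
#' data pin every subject's parameters (no shrinkage), approaching 100 when
#' individual posteriors collapse onto the population distribution.
#'
#' @param model A fitted `npag_fit` object.
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `median`, `cv_pct`, `var`, `shrink_pct`.
#' @export
fit_summary <- function(model) {
  stopifnot(inherits(model, "npag_fit"))
  pars <- setdiff(names(model$support), "prob")
  w <- model$support$prob
  purrr::map_dfr(pars, function(p) {
    mom <- weighted_moments(model$support[[p]], w)
    post_sd <- if (!is.null(model$posterior_means) &&
                   p %in% names(model$posterior_means)) {
      sd(model$posterior_means[[p]])
    } else {
      NA_real_
    }
    shrink <- if (is.na(post_sd) || mom$sd == 0) {
      NA_real_
    } else {
      # clamped to [0, 100]: sampling noise can push the posterior-mean
      # spread a hair past the population SD under rich designs
      min(max(100 * (1 - post_sd / mom$sd), 0), 100)
    }
    tibble::tibble(
      parameter = p, mean = mom$mean, sd = mom$sd, median = mom$median,
      cv_pct = mom$cv_pct, var = mom$var, shrink_pct = shrink
    )
  })
}

#' @rdname fit_summary
#' @param x A fitted `npag_fit` object.
#' @param ... Unused.
#' @method tidy npag_fit
#' @export
tidy.npag_fit <- function(x, ...) {
  fit_summary(x)
}

#' One-row fit overview
#'
#' @param x A fitted `npag_fit` object.
#' @param ... Unused.
#' @return A tibble with `logLik`, `neg2LL`, `AIC`, `n_support`, `cycles`,
#'   `converged`, `n_subjects`, `n_obs`.
#' @method glance npag_fit
#' @export
glance.npag_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, neg2LL = -2 * x$logLik, AIC = x$AIC,
    n_support = nrow(x$support), cycles = x$cycles,
    converged = x$converged, n_subjects = x$n_subjects, n_obs = x$n_obs
  )
}

#' @export
print.npag_fit <- function(x, ...) {
  cat(sprintf(
    "<npag_fit: %s, %d subjects, %d observations>\n",
    x$model, x$n_subjects, x$n_obs
  ))
  cat(sprintf(
    "  -2LL = %.3f, AIC = %.3f, %d support points, %d cycles (%s)\n",
    -2 * x$logLik, x$AIC, nrow(x$support), x$cycles,
    if (x$converged) "converged" else "not converged"
  ))
  print(fit_summary(x))
  invisible(x)
}
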