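#' Fitting options for the nonparametric adaptive grid estimator
#'
#' @param bounds Named list of `c(lower, upper)` search bounds per parameter.
#'   Defaults bracket the published estimates by more than four SDs:
#'   `CLs` in `[0.1, 10]` L/h, `V` in `[1, 60]` L (and `Q` in `[0.01, 10]`,
#'   `Vp` in `[1, 60]` for the two-compartment comparator).
#' @param n_grid Number of initial low-discrepancy grid points (default 250).
#' @param tol Convergence tolerance on the total log-likelihood gain over one
#'   adaptive cycle (default 0.01).
#' @param max_cycles Maximum adaptive cycles (default 100).
#' @param prob_drop Support points with probability below `prob_drop` times
#'   the maximum are condensed away (default 1e-8).
#' @param em_tol Inner tolerance for the expectation-maximisation weight
#'   update fixed point (default 1e-10).
#' @param em_max_iter Maximum EM iterations per cycle (default 2000).
#' @param radius Initial local-expansion radius as a fraction of each
#'   parameter's range (default 0.1); halved whenever a cycle fails to
#'   improve the log-likelihood by `tol`.
#' @param min_radius Expansion stops shrinking below this fraction (default
#'   1e-4); reaching it ends adaptation.
#' @param adapt If `FALSE`, no condensation/expansion is performed: weights
#'   are optimised on the fixed initial grid only.
#' @param initial_grid Optional matrix/data frame of starting support points
#'   (columns named after the parameters), replacing the random grid.
#' @param seed Optional integer seed for the initial grid.
#'
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(bounds = list(CLs = c(0.1, 10), V = c(1, 60),
                                      Q = c(0.01, 10), Vp = c(1, 60)),
                        n_grid = 250,
                        tol = 0.01,
                        max_cycles = 100,
                        prob_drop = 1e-8,
                        em_tol = 1e-10,
                        em_max_iter = 2000,
                        radius = 0.1,
                        min_radius = 1e-4,
                        adapt = TRUE,
                        initial_grid = NULL,
                        seed = NULL) {
  for (b in bounds) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      abort("each bound must be a finite c(lower, upper) with lower < upper")
    }
  }
  stopifnot(tol > 0, n_grid >= 1, max_cycles >= 0, radius > 0)
  structure(
    list(
      bounds = bounds, n_grid = n_grid, tol = tol, max_cycles = max_cycles,
      prob_drop = prob_drop, em_tol = em_tol, em_max_iter = em_max_iter,
      radius = radius, min_radius = min_radius, adapt = adapt,
      initial_grid = initial_grid, seed = seed
    ),
    class = "fit_options"
  )
}

# Split a long event cohort into per-subject dose/observation structures.
# blq: "censored" keeps below-LOD rows and marks them for a censored
# likelihood term; "impute" keeps them at their stored LOD/2 value as if
# quantified; "exclude" drops them.
prep_subjects <- function(cohort, error_model,
                          blq = c("censored", "exclude", "impute")) {
  blq <- match.arg(blq)
  validate_cohort(cohort)
  ids <- unique(cohort$id)
  purrr::map(ids, function(sid) {
    rows <- cohort[cohort$id == sid, ]
    dose_rows <- rows[rows$event_type == "dose", ]
    obs_rows <- rows[rows$event_type == "obs", ]
    is_blq <- isTRUE_vec(obs_rows$blq_flag)
    if (blq == "exclude") {
      obs_rows <- obs_rows[!is_blq, , drop = FALSE]
      is_blq <- rep(FALSE, nrow(obs_rows))
    } else if (blq == "impute") {
      is_blq <- rep(FALSE, nrow(obs_rows))
    }
    list(
      id = sid,
      doses = dose_events(dose_rows$time_h, dose_rows$amount_mg,
                          dose_rows$infusion_h),
      times = obs_rows$time_h,
      obs = obs_rows$conc_mg_L,
      blq = is_blq,
      covariates = rows[1, setdiff(names(rows), c(
        "time_h", "event_type", "amount_mg", "infusion_h",
        "conc_mg_L", "blq_flag"
      ))]
    )
  })
}

isTRUE_vec <- function(x) !is.na(x) & x

# Per-subject log-likelihood over a grid of candidate support points.
# grid: matrix with named columns (CLs, V [, Q, Vp]); returns length-K vector.
subject_loglik_grid <- function(subject, grid, covariate_model, error_model,
                                model = "one_cpt") {
  if (length(subject$times) == 0L) {
    return(rep(0, nrow(grid)))
  }
  CLs <- grid[, "CLs"]
  V <- grid[, "V"]
  CL <- if (is.null(covariate_model)) {
    CLs
  } else {
    cov_value <- subject$covariates[[covariate_model$covariate]]
    CLs * cov_value / covariate_model$reference
  }
  pred <- if (model == "one_cpt") {
    conc1_matrix(CL, V, subject$doses, subject$times)
  } else {
    conc2_matrix(CL, V, grid[, "Q"], grid[, "Vp"], subject$doses,
                 subject$times)
  }
  sds <- error_model$intercept_sd + error_model$proportional_sd * pred
  if (any(sds <= 0)) {
    return(rep(-Inf, nrow(grid)))
  }
  res <- sweep(pred, 2, subject$obs, FUN = function(p, o) o - p)
  # Gaussian log-density per observation; censored (M3) term for BLQ rows
  ll <- -0.5 * log(2 * pi) - log(sds) - 0.5 * (res / sds)^2
  is_blq <- subject$blq %||% rep(FALSE, length(subject$times))
  if (any(is_blq)) {
    for (j in which(is_blq)) {
      ll[, j] <- pnorm(error_model$lod, mean = pred[, j], sd = sds[, j],
                       log.p = TRUE)
    }
  }
  rowSums(ll)
}

#' Log-likelihood of one subject's observations at a candidate parameter set
#'
#' Gaussian observation model implied by the assay-error weighting: the sum
#' over observations of `log N(obs | pred, SD(pred)^2)` with predictions from
#' the one-compartment infusion model and `CL` obtained from `CLs` through
#' the covariate model (if any). Below-LOD observations contribute a
#' censored term by default (see `blq`).
#'
#' @param CLs Clearance at the reference covariate value (L/h).
#' @param V Volume of distribution (L).
#' @param subject A one-subject cohort tibble (long event form).
#' @param covariate_model A [covariate_model()] or `NULL` for no scaling.
#' @param error_model An [assay_error_model()].
#' @param blq Below-LOD policy: `"censored"` (default) adds the censored
#'   Gaussian term `log P(C < LOD)` for flagged observations, `"exclude"`
#'   drops them, `"impute"` treats their stored LOD/2 value as quantified.
#'
#' @return The log-likelihood (scalar); `-Inf` for impossible inputs.
#' @export
subject_loglik <- function(CLs, V, subject,
                           covariate_model = amikelder::covariate_model(),
                           error_model = assay_error_model(),
                           blq = c("censored", "exclude", "impute")) {
  if (!is.numeric(CLs) || !is.numeric(V) || CLs <= 0 || V <= 0) {
    return(-Inf)
  }
  subj <- prep_subjects(subject, error_model, blq = blq)
  if (length(subj) != 1L) abort("`subject` must contain exactly one id")
  grid <- matrix(c(CLs, V), nrow = 1,
                 dimnames = list(NULL, c("CLs", "V")))
  as.numeric(subject_loglik_grid(subj[[1]], grid, covariate_model,
                                 error_model))
}

# EM fixed-point iteration for mixture weights on a fixed grid.
# Mlog: n_subjects x K matrix of per-subject log-likelihoods.
em_weights <- function(Mlog, lambda0 = NULL, tol = 1e-10, max_iter = 2000) {
  n <- nrow(Mlog)
  K <- ncol(Mlog)
  a <- apply(Mlog, 1, max)
  if (any(!is.finite(a))) {
    bad <- which(!is.finite(a))[1]
    abort(sprintf(
      "no grid point has finite likelihood for subject index %d", bad
    ), class = "amikelder_no_support")
  }
  L <- exp(Mlog - a)
  lambda <- if (is.null(lambda0)) rep(1 / K, K) else lambda0 / sum(lambda0)
  ll_old <- -Inf
  ll <- -Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    denom <- as.vector(L %*% lambda)
    if (any(denom <= 0)) {
      abort("zero mixture likelihood for a subject",
            class = "amikelder_no_support")
    }
    ll <- sum(log(denom) + a)
    iters <- it
    if (it > 1L && ll - ll_old < tol) break
    ll_old <- ll
    lambda <- lambda * as.vector(crossprod(L, 1 / denom)) / n
    lambda <- lambda / sum(lambda)
  }
  list(lambda = lambda, loglik = ll, iters = iters)
}

#' Mixture log-likelihood of a cohort under a discrete population model
#'
#' Sum over subjects of `log( sum_k prob_k * L(subject | theta_k) )`. This is
#' the objective the nonparametric estimator maximises; it is exposed so that
#' fits can be verified against brute-force evaluation.
#'
#' @param cohort A cohort tibble in long event form.
#' @param support A data frame of support points (columns `CLs`, `V`, ...).
#' @param prob Support-point probabilities (summing to 1).
#' @inheritParams npag_fit
#'
#' @return The total mixture log-likelihood (scalar).
#' @export
mixture_loglik <- function(cohort, support, prob,
                           covariate_model = amikelder::covariate_model(),
                           error_model = assay_error_model(),
                           model = c("one_cpt", "two_cpt"),
                           blq = c("censored", "exclude", "impute")) {
  model <- match.arg(model)
  subjects <- prep_subjects(cohort, error_model, blq = blq)
  grid <- as.matrix(tibble::as_tibble(support)[param_names(model)])
  Mlog <- t(vapply(
    subjects,
    function(s) subject_loglik_grid(s, grid, covariate_model, error_model,
                                    model),
    numeric(nrow(grid))
  ))
  if (nrow(grid) == 1L) Mlog <- matrix(Mlog, ncol = 1L)
  a <- apply(Mlog, 1, max)
  sum(log(as.vector(exp(Mlog - a) %*% (prob / sum(prob)))) + a)
}

param_names <- function(model) {
  if (model == "two_cpt") c("CLs", "V", "Q", "Vp") else c("CLs", "V")
}

# Low-discrepancy initial grid within bounds.
initial_grid_lhs <- function(bounds, n_grid, pars) {
  u <- lhs::randomLHS(n_grid, length(pars))
  grid <- vapply(seq_along(pars), function(j) {
    b <- bounds[[pars[j]]]
    b[1] + u[, j] * (b[2] - b[1])
  }, numeric(n_grid))
  grid <- matrix(grid, nrow = n_grid, dimnames = list(NULL, pars))
  grid
}

#' Nonparametric adaptive-grid population fit
#'
#' Maximum-likelihood estimation of a discrete population distribution
#' (support points with probabilities) for the structural PK parameters from
#' sparse concentration data. The estimator alternates:
#'
#' 1. probability-weight optimisation over the current candidate grid by an
#'    expectation-maximisation fixed-point iteration of the mixture
#'    likelihood;
#' 2. grid condensation, dropping points whose probability falls below
#'    `prob_drop` times the maximum;
#' 3. local grid expansion around the surviving support points with a
#'    radius that shrinks whenever a cycle fails to improve the
#'    log-likelihood.
#'
#' Iteration stops when the log-likelihood gain over a full cycle is below
#' `tol` and the expansion radius has reached its floor, or after
#' `max_cycles` cycles. `AIC = -2LL + 2 * (number of support-point
#' coordinates + estimated error parameters)`, where the coordinate count is
#' the number of structural dimensions (2 for one-compartment, 4 for the
#' comparator); the assay error model is fixed (not estimated) here.
#'
#' @param cohort A cohort tibble in long event form (see
#'   [simulate_tdm_cohort()] / [read_cohort()]).
#' @param options A [fit_options()] object.
#' @param error_model An [assay_error_model()]; its parameters are fixed
#'   during estimation.
#' @param covariate_model A [covariate_model()] scaling clearance, or `NULL`
#'   to fit clearance without covariates (the base model).
#' @param model `"one_cpt"` (default) or `"two_cpt"` for the two-compartment
#'   comparator.
#' @param blq Below-LOD policy: `"censored"` (default, the M3 convention:
#'   flagged observations contribute `log P(C < LOD)`), `"exclude"`, or
#'   `"impute"` (stored LOD/2 value treated as quantified). Exclusion
#'   censors exactly the fast-clearance subjects and biases the population
#'   clearance low; the censored term keeps their information honestly.
#'
#' @return An object of class `c("npag_fit", "discrete_pop", "pop_model")`
#'   with elements `support` (tibble of support points and `prob`), `logLik`,
#'   `AIC`, `cycles`, `converged`, `logl_trace`, `posterior_means`, and the
#'   models/options used. Works with [tidy()], [glance()], [fit_summary()],
#'   [predictions()], [vpc()] and the Monte Carlo simulators.
#' @examples
#' cohort <- simulate_tdm_cohort(population_model(), n_subjects = 8,
#'                               seed = 7, n_samples = 3)
#' fit <- npag_fit(cohort, fit_options(n_grid = 60, max_cycles = 15, seed = 1))
#' glance(fit)
#' @export
npag_fit <- function(cohort,
                     options = fit_options(),
                     error_model = assay_error_model(),
                     covariate_model = amikelder::covariate_model(),
                     model = c("one_cpt", "two_cpt"),
                     blq = c("censored", "exclude", "impute")) {
  model <- match.arg(model)
  blq <- match.arg(blq)
  pars <- param_names(model)
  subjects <- prep_subjects(cohort, error_model, blq = blq)
  if (length(subjects) < 1L) abort("cohort contains no subjects")
  n_obs <- sum(vapply(subjects, function(s) length(s$times), integer(1)))
  if (n_obs == 0L) abort("cohort contains no usable observations")
  if (!is.null(covariate_model)) {
    for (s in subjects) {
      v <- s$covariates[[covariate_model$covariate]]
      if (is.null(v) || !is.finite(v) || v <= 0) {
        abort(sprintf(
          "subject %s lacks a positive '%s' covariate value",
          s$id, covariate_model$covariate
        ))
      }
    }
  }

  if (!is.null(options$initial_grid)) {
    grid <- as.matrix(tibble::as_tibble(options$initial_grid)[pars])
  } else {
    if (!is.null(options$seed)) withr::local_seed(options$seed)
    grid <- initial_grid_lhs(options$bounds, options$n_grid, pars)
  }

  loglik_mat <- function(g) {
    M <- t(vapply(
      subjects,
      function(s) subject_loglik_grid(s, g, covariate_model, error_model,
                                      model),
      numeric(nrow(g))
    ))
    if (nrow(g) == 1L) M <- matrix(M, ncol = 1L) else M
  }

  Mlog <- loglik_mat(grid)
  em <- em_weights(Mlog, tol = options$em_tol,
                   max_iter = options$em_max_iter)
  lambda <- em$lambda
  ll <- em$loglik
  trace <- ll
  ranges <- vapply(pars, function(p) diff(options$bounds[[p]]), numeric(1))
  radius <- options$radius
  cycles <- 0L
  converged <- !options$adapt

  condense <- function(grid, lambda, Mlog) {
    keep <- lambda > options$prob_drop * max(lambda)
    grid <- grid[keep, , drop = FALSE]
    lambda <- lambda[keep]
    Mlog <- Mlog[, keep, drop = FALSE]
    key <- apply(round(sweep(grid, 2, ranges, "/"), 8), 1, paste,
                 collapse = "|")
    first <- !duplicated(key)
    if (any(!first)) {
      # fold duplicate mass into the first occurrence
      lam_sum <- rowsum(lambda, group = key)
      grid <- grid[first, , drop = FALSE]
      Mlog <- Mlog[, first, drop = FALSE]
      lambda <- as.numeric(lam_sum[match(key[first], rownames(lam_sum)), 1])
    }
    list(grid = grid, lambda = lambda / sum(lambda), Mlog = Mlog)
  }

  if (options$adapt && options$max_cycles > 0L) {
    for (cy in seq_len(options$max_cycles)) {
      cycles <- cy
      st <- condense(grid, lambda, Mlog)
      grid <- st$grid; lambda <- st$lambda; Mlog <- st$Mlog
      # expand: +/- radius per dimension around each surviving point
      K <- nrow(grid)
      cand <- vector("list", 2L * length(pars))
      idx <- 1L
      for (j in seq_along(pars)) {
        for (sgn in c(-1, 1)) {
          g2 <- grid
          g2[, j] <- g2[, j] + sgn * radius * ranges[j]
          b <- options$bounds[[pars[j]]]
          g2[, j] <- pmin(pmax(g2[, j], b[1]), b[2])
          cand[[idx]] <- g2
          idx <- idx + 1L
        }
      }
      cand <- do.call(rbind, cand)
      # drop candidates that duplicate existing or other candidate points
      all_grid <- rbind(grid, cand)
      scaled <- round(sweep(all_grid, 2, ranges, "/"), 8)
      keep_new <- !duplicated(scaled)
      keep_new[seq_len(K)] <- FALSE
      cand <- all_grid[keep_new, , drop = FALSE]
      if (nrow(cand) > 0L) {
        Mnew <- loglik_mat(cand)
        grid <- rbind(grid, cand)
        Mlog <- cbind(Mlog, Mnew)
        eps <- 1e-6
        lambda <- c(lambda * (1 - eps),
                    rep(eps / nrow(cand), nrow(cand)))
      }
      em <- em_weights(Mlog, lambda0 = lambda, tol = options$em_tol,
                       max_iter = options$em_max_iter)
      lambda <- em$lambda
      gain <- em$loglik - ll
      ll <- max(em$loglik, ll)
      trace <- c(trace, ll)
      if (gain < options$tol) {
        radius <- radius / 2
        if (radius < options$min_radius) {
          converged <- TRUE
          break
        }
      }
    }
    st <- condense(grid, lambda, Mlog)
    grid <- st$grid; lambda <- st$lambda; Mlog <- st$Mlog
  }

  support <- tibble::as_tibble(as.data.frame(grid))
  support$prob <- lambda
  # AIC counts the estimated structural dimensions (2 or 4) plus estimated
  # error parameters (none here: the assay polynomial is fixed), not the
  # support-point count: the discrete distribution is the estimand, not a
  # parameter vector of free knots.
  d <- length(pars)
  aic <- -2 * ll + 2 * d

  # posterior individual means (for shrinkage and diagnostics)
  a <- apply(Mlog, 1, max)
  W <- exp(Mlog - a) * rep(lambda, each = nrow(Mlog))
  W <- W / rowSums(W)
  posterior_means <- tibble::as_tibble(as.data.frame(W %*% grid))
  names(posterior_means) <- pars
  posterior_means <- dplyr::bind_cols(
    tibble::tibble(id = vapply(subjects, `[[`, character(1), "id")),
    posterior_means
  )

  structure(
    list(
      type = "discrete",
      support = support,
      logLik = ll,
      AIC = aic,
      cycles = cycles,
      converged = converged,
      logl_trace = trace,
      posterior_means = posterior_means,
      covariate_model = covariate_model,
      error_model = error_model,
      model = model,
      options = options,
      blq = blq,
      n_subjects = length(subjects),
      n_obs = n_obs
    ),
    class = c("npag_fit", "discrete_pop", "pop_model")
  )
}
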