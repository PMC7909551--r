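#' Visual predictive check
#'
#' Simulates `n_sim` virtual replicates of every subject under that
#' subject's own dose history and sampling times (parameters drawn from the
#' population distribution with the subject's covariates, observation noise
#' from the assay error model), computes simulated percentile bands at each
#' observation time, and reports the proportion of observations falling
#' inside the 5th-95th percentile band. The check is constructed per dose
#' history, not binned by time after dose.
#'
#' Below-LOD handling is symmetric: flagged observations are excluded from
#' the check, and the percentile bands are computed from the quantifiable
#' (at or above LOD) simulated values only. Conditioning both sides the same
#' way keeps the nominal 90% inclusion interpretable; unconditional bands
#' against LOD-truncated observations would systematically overcount
#' above-band troughs.
#'
#' @param model A `pop_model` (parametric or fitted discrete).
#' @param cohort A cohort tibble in long event form.
#' @param error_model An [assay_error_model()].
#' @param n_sim Number of simulated replicates per subject (>= 100,
#'   default 1000).
#' @param seed Optional integer seed.
#' @param probs Percentiles for the bands.
#'
#' @return An object of class `amik_vpc`: a list with `bands` (tibble `id`,
#'   `time_h`, `obs`, one column per percentile, `inside`), `inclusion_pct`,
#'   `n_sim`. Has an [autoplot()] method.
#' @export
vpc <- function(model, cohort, error_model = assay_error_model(),
                n_sim = 1000, seed = NULL,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(model, "pop_model"))
  if (n_sim < 100) abort("n_sim must be at least 100")
  if (!is.null(seed)) withr::local_seed(seed)
  subjects <- prep_subjects(cohort, error_model, blq = "exclude")
  cm <- model$covariate_model
  bands <- purrr::map_dfr(subjects, function(s) {
    if (length(s$times) == 0L) return(NULL)
    cov_value <- if (is.null(cm)) NULL else s$covariates[[cm$covariate]]
    draws <- sample_population(
      model,
      covariates = if (is.null(cov_value)) rep(1, n_sim) else
        rep(cov_value, n_sim)
    )
    CL <- if (is.null(cm)) draws$CLs else draws$CL
    pred <- conc1_matrix(CL, draws$V, s$doses, s$times)
    sds <- assay_sd(error_model, pred)
    sim <- pred
    if (any(sds > 0)) {
      sim <- matrix(
        rnorm(length(pred), mean = pred, sd = sds),
        nrow = nrow(pred)
      )
      neg <- which(sim < 0)
      guard <- 0L
      while (length(neg) > 0L && guard < 1000L) {
        sim[neg] <- rnorm(length(neg), mean = pred[neg], sd = sds[neg])
        neg <- neg[sim[neg] < 0]
        guard <- guard + 1L
      }
      sim[sim < 0] <- 0
    }
    qs <- apply(sim, 2, function(col) {
      quantifiable <- col[col >= error_model$lod]
      if (length(quantifiable) < 20L) quantifiable <- col
      quantile(quantifiable, probs = probs, names = FALSE)
    })
    qs <- matrix(qs, nrow = length(probs))
    band <- tibble::as_tibble(as.data.frame(t(qs)))
    names(band) <- paste0("p", probs * 100)
    dplyr::bind_cols(
      tibble::tibble(id = s$id, time_h = s$times, obs = s$obs),
      band
    )
  })
  lo <- paste0("p", min(probs) * 100)
  hi <- paste0("p", max(probs) * 100)
  bands$inside <- bands$obs >= bands[[lo]] & bands$obs <= bands[[hi]]
  structure(
    list(
      bands = bands,
      inclusion_pct = 100 * mean(bands$inside),
      n_sim = n_sim,
      probs = probs
    ),
    class = "amik_vpc"
  )
}

#' @export
print.amik_vpc <- function(x, ...) {
  cat(sprintf(
    "<visual predictive check: %d observations, n_sim = %d>\n", nrow(x$bands),
    x$n_sim
  ))
  cat(sprintf(
    "  %.1f%% of observations inside the %g-%g percentile band\n",
    x$inclusion_pct, 100 * min(x$probs), 100 * max(x$probs)
  ))
  invisible(x)
}

#' Bootstrap stability of the population fit
#'
#' Resamples subjects with replacement, refits the model on each replicate,
#' and summarises the replicate population means per parameter: bootstrap
#' mean, SE (the SD of replicate means) and percentile confidence intervals.
#' Replicates whose fit fails are dropped and counted.
#'
#' @param cohort A cohort tibble in long event form.
#' @param options A [fit_options()] for the replicate fits.
#' @param n_boot Number of bootstrap replicates (>= 10; 1000 for a
#'   publication-grade run, far fewer suffices for smoke checks).
#' @param seed Optional integer seed governing the resampling.
#' @param error_model An [assay_error_model()].
#' @param covariate_model A [covariate_model()] or `NULL`.
#' @param model `"one_cpt"` or `"two_cpt"`.
#' @param conf_level Confidence level for the percentile interval.
#' @param resample_ids Optional list of id vectors, one per replicate,
#'   overriding the random resampling (each replicate refits exactly those
#'   subjects).
#'
#' @return An object of class `amik_bootstrap`: a list with `summary`
#'   (tibble `parameter`, `estimate`, `se`, `ci_lo`, `ci_hi`), `replicates`
#'   (tibble of per-replicate means), `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(cohort, options = fit_options(), n_boot = 1000,
                         seed = NULL, error_model = assay_error_model(),
                         covariate_model = amikelder::covariate_model(),
                         model = c("one_cpt", "two_cpt"),
                         conf_level = 0.95,
                         resample_ids = NULL) {
  model <- match.arg(model)
  if (is.null(resample_ids) && n_boot < 10) {
    abort("n_boot must be at least 10")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- unique(cohort$id)
  n <- length(ids)
  if (is.null(resample_ids)) {
    resample_ids <- purrr::map(seq_len(n_boot), ~ sample(ids, n,
                                                         replace = TRUE))
  }
  n_boot <- length(resample_ids)
  reps <- purrr::imap(resample_ids, function(rid, b) {
    boot_cohort <- purrr::imap_dfr(rid, function(one, k) {
      rows <- cohort[cohort$id == one, ]
      rows$id <- paste0("B", k, "_", one)
      rows
    })
    tryCatch({
      fit <- npag_fit(boot_cohort, options = options,
                      error_model = error_model,
                      covariate_model = covariate_model, model = model)
      s <- fit_summary(fit)
      tibble::tibble(replicate = b, parameter = s$parameter, mean = s$mean)
    }, error = function(e) NULL)
  })
  failed <- sum(vapply(reps, is.null, logical(1)))
  reps <- dplyr::bind_rows(reps)
  if (nrow(reps) == 0L) abort("all bootstrap replicates failed")
  alpha <- (1 - conf_level) / 2
  summary <- reps |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      estimate = mean(.data$mean),
      se = sd(.data$mean),
      ci_lo = quantile(.data$mean, alpha, names = FALSE),
      ci_hi = quantile(.data$mean, 1 - alpha, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(summary = summary, replicates = reps, n_boot = n_boot,
         n_failed = failed),
    class = "amik_bootstrap"
  )
}

#' @export
print.amik_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<bootstrap: %d replicates, %d failed>\n", x$n_boot, x$n_failed
  ))
  print(x$summary)
  invisible(x)
}

#' Pearson chi-square association test for a 2x2 outcome table
#'
#' Pearson chi-square without continuity correction on one degree of
#' freedom, as used to relate peak-to-MIC target attainment to survival and
#' microbiological eradication.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative integer counts.
#'
#' @return A tibble with `statistic`, `df`, `p_value`, `n`.
#' @examples
#' association_test(matrix(c(5, 2, 1, 3), nrow = 2))
#' @export
association_test <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) abort("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  if (sum(tab) < 1) abort("table must contain at least one count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero marginal total: association is undefined",
          class = "amikelder_zero_marginal")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    n = sum(tab)
  )
}
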