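test_that("subject log-likelihood matches closed-form and brute-force sums", {
  subj <- make_subject(obs_times = c(1, 23.5))
  em <- assay_error_model()

  # zero residuals: logL is minus the sum of log(SD * sqrt(2*pi))
  pred <- concentration_profile(2.25, 18, dose_events(0, 800, 0.5),
                                c(1, 23.5))$conc_mg_L
  sds <- assay_sd(em, pred)
  expect_equal(subject_loglik(2.25, 18, subj),
               -sum(log(sds * sqrt(2 * pi))), tolerance = 1e-12)

  # arbitrary parameters: term-by-term hand sum
  pred2 <- concentration_profile(2.0 * 52.9 / 52.9, 20,
                                 dose_events(0, 800, 0.5),
                                 c(1, 23.5))$conc_mg_L
  hand <- sum(dnorm(subj$conc_mg_L[subj$event_type == "obs"],
                    mean = pred2, sd = assay_sd(em, pred2), log = TRUE))
  expect_equal(subject_loglik(2.0, 20, subj), hand, tolerance = 1e-12)

  # inflating any residual strictly decreases the log-likelihood
  bumped <- subj
  i <- which(bumped$event_type == "obs")[1]
  bumped$conc_mg_L[i] <- bumped$conc_mg_L[i] + 5
  expect_lt(subject_loglik(2.25, 18, bumped),
            subject_loglik(2.25, 18, subj))

  expect_equal(subject_loglik(-1, 18, subj), -Inf)
})

test_that("below-LOD policies change the likelihood as intended", {
  subj <- make_subject(obs_times = c(1, 23.5), conc = c(30, 0.4),
                       blq = c(FALSE, TRUE))
  em <- assay_error_model()
  ll_cens <- subject_loglik(2.25, 18, subj, blq = "censored")
  ll_excl <- subject_loglik(2.25, 18, subj, blq = "exclude")
  ll_imp <- subject_loglik(2.25, 18, subj, blq = "impute")
  # censored adds a (negative) log-probability term to the excluded version
  pred <- concentration_profile(2.25, 18, dose_events(0, 800, 0.5),
                                23.5)$conc_mg_L
  cens_term <- pnorm(0.8, pred, assay_sd(em, pred), log.p = TRUE)
  expect_equal(ll_cens, ll_excl + cens_term, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ll_imp, ll_excl)))
})

test_that("a single richly sampled subject collapses to its generating point", {
  subj <- make_subject(obs_times = c(1, 2, 4, 6, 8, 12, 18, 23.5))
  fit <- npag_fit(subj, fit_options(n_grid = 100, seed = 2))
  expect_equal(sum(fit$support$prob), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$logl_trace) > -1e-6))
  top <- fit$support[which.max(fit$support$prob), ]
  expect_equal(top$CLs, 2.25, tolerance = 0.01)
  expect_equal(top$V, 18, tolerance = 0.01)
  s <- fit_summary(fit)
  expect_equal(s$mean[s$parameter == "CLs"], 2.25, tolerance = 0.01)
  expect_equal(s$mean[s$parameter == "V"], 18, tolerance = 0.01)
})

test_that("mixture likelihood on a fixed grid equals brute-force evaluation", {
  cohort <- dplyr::bind_rows(
    make_subject("A", obs_times = c(1, 23.5), CL = 1.8, V = 15, ccr = 40),
    make_subject("B", obs_times = c(1, 23.5), CL = 2.6, V = 20, ccr = 70),
    make_subject("C", obs_times = c(1, 12), CL = 1.2, V = 25, ccr = 25)
  )
  grid <- expand.grid(CLs = seq(1, 3, length.out = 5),
                      V = seq(10, 30, length.out = 5))
  fit <- npag_fit(cohort, fit_options(initial_grid = grid, adapt = FALSE))
  expect_equal(nrow(fit$support), 25)

  em <- assay_error_model()
  cm <- covariate_model()
  brute <- 0
  for (sid in c("A", "B", "C")) {
    rows <- cohort[cohort$id == sid, ]
    obs <- rows[rows$event_type == "obs", ]
    doses <- dose_events(rows$time_h[rows$event_type == "dose"],
                         rows$amount_mg[rows$event_type == "dose"],
                         rows$infusion_h[rows$event_type == "dose"])
    lik_k <- numeric(25)
    for (k in 1:25) {
      CL <- grid$CLs[k] * rows$ccr[1] / cm$reference
      pred <- concentration_profile(CL, grid$V[k], doses,
                                    obs$time_h)$conc_mg_L
      lik_k[k] <- prod(dnorm(obs$conc_mg_L, pred, assay_sd(em, pred)))
    }
    brute <- brute + log(sum(fit$support$prob * lik_k))
  }
  expect_equal(fit$logLik, brute, tolerance = 1e-8)
  expect_equal(
    mixture_loglik(cohort, fit$support[c("CLs", "V")], fit$support$prob),
    brute, tolerance = 1e-8
  )
})

test_that("estimates are invariant to subject ordering", {
  co <- simulate_tdm_cohort(n_subjects = 10, design = recovery_design(),
                            seed = 31)
  rev_co <- dplyr::arrange(co, dplyr::desc(id), time_h)
  opts <- fit_options(n_grid = 80, seed = 3, max_cycles = 25)
  f1 <- npag_fit(co, opts)
  f2 <- npag_fit(rev_co, opts)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(fit_summary(f1)$mean, fit_summary(f2)$mean,
               tolerance = 1e-6)
})

test_that("covariate scan recovers a true renal effect and skips degenerate candidates", {
  co <- simulate_tdm_cohort(population_model(), n_subjects = 30,
                            design = recovery_design(), seed = 71)
  co$flat <- 1
  opts <- fit_options(n_grid = 100, seed = 5, em_max_iter = 600,
                      em_tol = 1e-8)
  base <- npag_fit(co, opts, covariate_model = NULL)
  scan <- covariate_scan(co, base, candidates = c("ccr", "flat"),
                         options = opts)
  ccr_row <- scan[scan$candidate == "ccr", ]
  expect_true(ccr_row$included)
  expect_gt(ccr_row$delta_neg2LL, 3.84)
  expect_gt(ccr_row$r2, 0.2)
  flat_row <- scan[scan$candidate == "flat", ]
  expect_false(flat_row$included)
  expect_match(flat_row$note, "constant")
  expect_s3_class(attr(scan, "best_fit"), "npag_fit")
})

test_that("weighted parameter summaries follow the discrete moments", {
  toy <- structure(
    list(support = tibble::tibble(CLs = c(1, 3), V = c(10, 30),
                                  prob = c(0.5, 0.5)),
         posterior_means = NULL),
    class = c("npag_fit", "discrete_pop", "pop_model")
  )
  s <- fit_summary(toy)
  expect_equal(s$mean, c(2, 20))
  expect_equal(s$median, c(2, 20))
  expect_equal(s$sd, c(1, 10))
  expect_equal(s$var, s$sd^2)

  # a two-point distribution with the published mean/SD reproduces the CV%
  pts <- c(2.25 - 0.78, 2.25 + 0.78)
  toy2 <- toy
  toy2$support <- tibble::tibble(CLs = pts, V = c(18, 18), prob = c(.5, .5))
  s2 <- fit_summary(toy2)
  expect_equal(s2$cv_pct[1], 34.67, tolerance = 1e-3)

  # brute-force weighted variance on uneven weights
  w <- c(0.2, 0.3, 0.5)
  x <- c(1.1, 2.7, 3.4)
  toy3 <- toy
  toy3$support <- tibble::tibble(CLs = x, V = c(10, 20, 30), prob = w)
  s3 <- fit_summary(toy3)
  m <- sum(w * x)
  expect_equal(s3$var[1], sum(w * (x - m)^2), tolerance = 1e-12)
})

test_that("posterior predictions satisfy the Bayes identity and zero-noise limit", {
  # noise-free data from a one-point model: everything is exact
  model1 <- discrete_population(data.frame(CLs = 2.25, V = 18), 1)
  cohort <- dplyr::bind_rows(
    make_subject("A", obs_times = c(1, 23.5)),
    make_subject("B", obs_times = c(1, 12), amount = 400)
  )
  p <- predictions(model1, cohort)
  expect_equal(p$wres_pop, rep(0, 4))
  expect_equal(p$wres_ind, rep(0, 4))
  expect_equal(attr(p, "bias_pop"), 0)
  expect_equal(attr(p, "imprecision_pop"), 0)

  # two-point model, one subject: posterior weights match the Bayes ratio
  model2 <- discrete_population(data.frame(CLs = c(1.8, 2.6),
                                           V = c(16, 20)),
                                c(0.3, 0.7))
  subj <- make_subject("A", obs_times = c(1, 23.5))
  p2 <- predictions(model2, subj)
  pw <- attr(p2, "posterior_weights")[["A"]]
  ll <- c(subject_loglik(1.8, 16, subj), subject_loglik(2.6, 20, subj))
  hand <- c(0.3, 0.7) * exp(ll - max(ll))
  hand <- hand / sum(hand)
  expect_equal(pw, hand, tolerance = 1e-12)
  expect_equal(sum(pw), 1, tolerance = 1e-12)
})

test_that("the one-compartment model wins on AIC when the data are one-compartment", {
  co <- simulate_tdm_cohort(n_subjects = 12, design = recovery_design(),
                            seed = 51)
  f1 <- npag_fit(co, fit_options(n_grid = 100, seed = 6, max_cycles = 30))
  f2 <- npag_fit(co, fit_options(n_grid = 300, seed = 6, max_cycles = 15),
                 model = "two_cpt")
  expect_lt(f1$AIC, f2$AIC)
  expect_equal(sum(f2$support$prob), 1, tolerance = 1e-9)
})

test_that("degenerate cohorts produce informative fitting errors", {
  expect_error(npag_fit(tibble::tibble()), "missing columns")
  subj <- make_subject(obs_times = c(1, 23.5), blq = c(TRUE, TRUE),
                       conc = c(0.4, 0.4))
  expect_error(npag_fit(subj, blq = "exclude"), "observations")
})

test_that("tidy and glance expose the fit in broom style", {
  co <- simulate_tdm_cohort(n_subjects = 6, design = recovery_design(),
                            seed = 61)
  fit <- npag_fit(co, fit_options(n_grid = 60, seed = 1, max_cycles = 10))
  td <- tidy(fit)
  expect_identical(td, fit_summary(fit))
  expect_true(all(c("parameter", "mean", "sd", "cv_pct", "shrink_pct")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$neg2LL, -2 * gl$logLik)
  expect_equal(gl$AIC, gl$neg2LL + 4)
  expect_equal(gl$n_subjects, 6L)
  # shrinkage is a percentage in [0, 100] here and 0-ish with rich data
  expect_true(all(td$shrink_pct >= 0 & td$shrink_pct <= 100))
})
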