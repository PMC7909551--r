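synthetic_grid <- function(rows) {
  g <- tibble::as_tibble(rows)
  g$efficacy_pct <- g$joint_pct
  g$safety_pct <- 100
  g$n <- 1000L
  g$cell_seed <- 1
  class(g) <- c("amik_pta_grid", class(g))
  g
}

test_that("nomogram selection takes the lowest qualifying dose, then the longest interval", {
  g <- synthetic_grid(tibble::tribble(
    ~ccr, ~dose, ~interval, ~mic, ~joint_pct,
    40, 1600, 72, 8, 85,
    40, 1800, 48, 8, 93,
    40, 1800, 72, 8, 92,
    40, 2000, 72, 8, 97,
    30, 1800, 72, 8, 70
  ))
  nom <- build_nomogram(g, mic = 8)
  r40 <- nom[nom$ccr == 40, ]
  expect_equal(r40$dose, 1800)
  expect_equal(r40$interval, 72) # tie among 1800s broken by longest interval
  expect_equal(r40$label, "1800 mg q72h")
  # no qualifying regimen: explicit NA recommendation
  r30 <- nom[nom$ccr == 30, ]
  expect_true(is.na(r30$dose))
  expect_true(is.na(r30$label))
  expect_equal(r30$renal_function, "Severe impairment")
})

test_that("nomograms are deterministic and never violate their thresholds", {
  grid <- pta_table(population_model(), mics = 8, n = 400, seed = 19)
  n1 <- build_nomogram(grid, mic = 8)
  n2 <- build_nomogram(grid, mic = 8)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 9)
  expect_equal(n1$ccr, seq(10, 90, by = 10))
  picked <- n1[!is.na(n1$dose), ]
  for (i in seq_len(nrow(picked))) {
    cell <- grid[grid$ccr == picked$ccr[i] & grid$dose == picked$dose[i] &
                   grid$interval == picked$interval[i] & grid$mic == 8, ]
    expect_gte(cell$joint_pct, 90)
  }
  expect_error(build_nomogram(grid[0, ], mic = 8), "non-empty")
  expect_error(build_nomogram(grid, mic = 2), "no rows")
})

test_that("an FTA bar can further restrict recommendations", {
  g <- synthetic_grid(tibble::tribble(
    ~ccr, ~dose, ~interval, ~mic, ~joint_pct,
    50, 1600, 72, 8, 95,
    50, 1800, 72, 8, 96
  ))
  ft <- tibble::tibble(ccr = c(50, 50), dose = c(1600, 1800),
                       interval = c(72, 72), fta_pct = c(80, 91))
  nom <- build_nomogram(g, mic = 8, fta = ft, fta_threshold = 85)
  expect_equal(nom$dose, 1800)
  expect_error(build_nomogram(g, mic = 8, fta_threshold = 85), "fta")
})

test_that("the markdown rendering mirrors the renal-function table", {
  g <- synthetic_grid(tibble::tibble(ccr = c(10, 90), dose = c(800, 1800),
                                     interval = c(24, 48), mic = 8,
                                     joint_pct = c(10, 95)))
  nom <- build_nomogram(g, mic = 8)
  md <- format(nom)
  expect_match(md[1], "Renal function")
  expect_match(md[3], "Kidney failure \\| 10 \\| NA")
  expect_match(md[4], "Normal \\| 90 \\| 1800 mg q48h")
})

test_that("cohort files validate structure and name offending rows", {
  co <- simulate_tdm_cohort(n_subjects = 3, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(as.data.frame(back)[names(back)],
                   as.data.frame(co)[names(back)])

  # an observation before any dose is an orphan
  bad <- co
  first_obs <- which(bad$event_type == "obs")[1]
  bad$time_h[first_obs] <- -0.5
  bad <- dplyr::arrange(bad, id, time_h)
  expect_error(validate_cohort(bad), "before any dose")

  expect_error(suppressWarnings(read_cohort(
    withr::local_tempfile(lines = "id,time_h\nS1,0", fileext = ".csv")
  )))
  expect_error(validate_cohort(co[, -3]), "missing columns")

  unsorted <- co[c(2, 1, 3:nrow(co)), ]
  expect_error(validate_cohort(unsorted), "sorted")
})

test_that("the bundled synthetic cohort parses to the study's bookkeeping", {
  path <- system.file("extdata", "tdm_cohort_synthetic.csv",
                      package = "amikelder")
  co <- read_cohort(path)
  expect_equal(dplyr::n_distinct(co$id), 15)
  expect_equal(sum(co$event_type == "obs"), 33)
  expect_true(all(co$ccr > 10 & co$ccr < 95))
  # and it is fittable end to end
  fit <- npag_fit(co, fit_options(n_grid = 60, seed = 1, max_cycles = 10))
  expect_s3_class(fit, "npag_fit")
  expect_true(all(fit$support$prob >= 0))
})

test_that("result plots build without evaluation errors", {
  pop <- population_model()
  co <- simulate_tdm_cohort(pop, n_subjects = 8, seed = 29, n_samples = 3)
  v <- vpc(pop, co, n_sim = 150, seed = 3)
  expect_s3_class(ggplot2::ggplot_build(autoplot(v)), "ggplot_built")

  grid <- pta_table(pop, doses = c(400, 800), intervals = c(24, 72),
                    ccr_values = c(30, 60), mics = 8, n = 100, seed = 5)
  expect_s3_class(ggplot2::ggplot_build(autoplot(grid)), "ggplot_built")

  fit <- npag_fit(co, fit_options(n_grid = 50, seed = 2, max_cycles = 8))
  expect_s3_class(ggplot2::ggplot_build(autoplot(fit, co)), "ggplot_built")
})
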