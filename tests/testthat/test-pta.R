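test_that("degenerate population reproduces the closed-form exposures", {
  point <- discrete_population(data.frame(CLs = 2.25, V = 18), 1)
  s <- simulate_exposures(point, regimen(800, 24), ccr = 52.9, n = 50,
                          seed = 1)
  expect_equal(s$cmax, rep(40.47, 50), tolerance = 1e-3)
  expect_equal(s$cmin, rep(2.43, 50), tolerance = 1e-2)
  expect_true(all(s$cmin < s$cmax))

  # all draws passing both targets
  res <- pta(s, mic = 4)
  expect_equal(res$efficacy_pct, 100)
  expect_equal(res$safety_pct, 100)
  expect_equal(res$joint_pct, 100)
})

test_that("exposures scale with dose and are seed-reproducible", {
  pop <- population_model()
  a <- simulate_exposures(pop, regimen(800, 48), 50, n = 200, seed = 5)
  b <- simulate_exposures(pop, regimen(1600, 48), 50, n = 200, seed = 5)
  expect_equal(b$cmax, 2 * a$cmax)
  expect_identical(
    a, simulate_exposures(pop, regimen(800, 48), 50, n = 200, seed = 5)
  )
  expect_error(simulate_exposures(pop, regimen(800, 48), -1, n = 10),
               "positive")
})

test_that("attainment percentages equal brute-force counting", {
  samples <- tibble::tibble(
    cmax = c(70, 60, 30, 90, 64, 63.9, 100, 20, 55, 80),
    cmin = c(1, 5, 2, 3.9, 4.0, 0.5, 6, 2, 4.1, 3)
  )
  res <- pta(samples, mic = 8)
  eff <- samples$cmax / 8 >= 8
  safe <- samples$cmin < 4
  expect_equal(res$efficacy_pct, 100 * sum(eff) / 10)
  expect_equal(res$safety_pct, 100 * sum(safe) / 10)
  expect_equal(res$joint_pct, 100 * sum(eff & safe) / 10)

  # non-strict safety comparison counts the boundary draw
  res2 <- pta(samples, mic = 8,
              targets = target_definition(safety_strict = FALSE))
  expect_equal(res2$safety_pct, 100 * mean(samples$cmin <= 4))

  # doubling the MIC never increases efficacy
  expect_lte(pta(samples, 16)$efficacy_pct, res$efficacy_pct)
  expect_error(pta(samples, mic = -4), "positive")
  expect_error(pta(samples[0, ], mic = 4), "non-empty")
})

test_that("fractional target attainment is the frequency-weighted mixture", {
  expect_equal(
    fta(tibble::tibble(mic = 8, joint_pct = 73.2),
        mic_distribution(8, 1)),
    73.2
  )
  expect_equal(
    fta(tibble::tibble(mic = c(4, 8), joint_pct = c(80, 100)),
        mic_distribution(c(4, 8), c(0.5, 0.5))),
    90
  )
  # convex-combination bounds over random inputs
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    mics <- sort(2^sample(-2:5, k))
    freq <- runif(k)
    freq <- freq / sum(freq)
    ptas <- tibble::tibble(mic = mics, joint_pct = runif(k, 0, 100))
    val <- fta(ptas, mic_distribution(mics, freq))
    expect_gte(val, min(ptas$joint_pct) - 1e-9)
    expect_lte(val, max(ptas$joint_pct) + 1e-9)
  }
  expect_error(
    fta(tibble::tibble(mic = 4, joint_pct = 90),
        mic_distribution(c(4, 8), c(0.5, 0.5))),
    "no PTA entry"
  )
})

test_that("MIC distributions are validated and file-round-trippable", {
  expect_error(mic_distribution(c(4, 2), c(0.5, 0.5)), "increasing")
  expect_error(mic_distribution(c(2, 4), c(0.6, 0.6)), "sum to 1")
  d <- mic_distribution(c(2, 4), c(3, 1), normalize = TRUE)
  expect_equal(d$frequency, c(0.75, 0.25))

  bundled <- read_mic_distribution(
    system.file("extdata", "mic_pa_synthetic.csv", package = "amikelder")
  )
  expect_s3_class(bundled, "mic_distribution")
  expect_equal(sum(bundled$frequency), 1, tolerance = 1e-9)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.data.frame(bundled), jpath, digits = NA)
  expect_equal(read_mic_distribution(jpath)$frequency, bundled$frequency)
})

test_that("the PTA grid has the full factorial shape and internal coherence", {
  grid <- pta_table(population_model(), mics = c(4, 8, 16), n = 300,
                    seed = 17)
  expect_equal(nrow(grid), 9 * 10 * 3 * 3)
  expect_equal(dplyr::n_distinct(grid$ccr), 9)
  expect_equal(dplyr::n_distinct(grid$dose), 10)
  expect_equal(dplyr::n_distinct(grid$interval), 3)
  expect_true(all(grid$joint_pct <= pmin(grid$efficacy_pct,
                                         grid$safety_pct) + 1e-9))
  expect_true(all(grid$joint_pct >= 0 & grid$joint_pct <= 100))

  # joint attainment never increases with MIC within a cell
  mono_mic <- grid |>
    dplyr::group_by(ccr, dose, interval) |>
    dplyr::arrange(mic, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(joint_pct) <= 1e-9), .groups = "drop")
  expect_true(all(mono_mic$ok))

  # wide layout mirrors the dose-by-renal-function table shape
  wide <- pta_wide(grid, mic = 8, interval = 72)
  expect_equal(dim(wide), c(9, 11))
  expect_identical(names(wide)[1], "ccr")
})

test_that("collapsed variability turns attainment into a 0/100 indicator", {
  point <- discrete_population(data.frame(CLs = 2.25, V = 18), 1)
  grid <- pta_table(point, doses = c(200, 800, 1800), intervals = c(24, 72),
                    ccr_values = c(30, 60, 90), mics = c(4, 16), n = 50,
                    seed = 2)
  expect_true(all(grid$joint_pct %in% c(0, 100)))
  # and the indicator matches the closed-form typical exposure
  one <- grid[grid$ccr == 60 & grid$dose == 800 &
                grid$interval == 24 & grid$mic == 4, ]
  CL <- individual_clearance(2.25, 60)
  conc <- concentration_profile(CL, 18, dose_events(0, 800, 0.5),
                                c(1, 23.5))$conc_mg_L
  expected <- (conc[1] / 4 >= 8) && (conc[2] < 4)
  expect_equal(one$joint_pct, 100 * expected)
})
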