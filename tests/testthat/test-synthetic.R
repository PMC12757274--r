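test_that("config validation rejects impossible study designs", {
  expect_error(simulation_config(n = 0), "positive")
  expect_error(simulation_config(age_sd = -1), "positive")
  expect_error(simulation_config(age_bounds = c(100, 20)), "increasing")
  expect_error(simulation_config(event_rate = 0), "between 0 and 1")
  expect_error(simulation_config(correlation = matrix(1, 3, 3)),
               "positive-definite")
  expect_error(simulation_config(true_weights = c(-1, 0, 0)), "non-negative")
})

test_that("generated cohorts respect marginals, bounds and the seed", {
  cfg <- simulation_config(n = 10000, seed = 51)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 10000L)
  # moments within ~2 standard errors (truncation shifts them slightly)
  expect_equal(mean(cohort$age), 75, tolerance = 0.02)
  expect_equal(stats::sd(cohort$heart_rate), 19, tolerance = 0.05)
  expect_true(all(cohort$age >= 18 & cohort$age <= 105))
  expect_true(all(cohort$heart_rate >= 40 & cohort$heart_rate <= 180))
  expect_true(all(cohort$pao2 >= 30 & cohort$pao2 <= 110))
  # single absorbing event per record, within the window
  expect_false(any(!is.na(cohort$day_of_death) & !is.na(cohort$day_of_discharge)))
  expect_true(all(is.na(cohort$day_of_death) |
                    (cohort$day_of_death >= 1 & cohort$day_of_death <= 30)))
  expect_true(all(cohort$died_30d == !is.na(cohort$day_of_death)))

  # identical seeds give byte-identical CSVs
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(simulation_config(n = 200, seed = 8)), p1)
  write_cohort(generate_cohort(simulation_config(n = 200, seed = 8)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the event rate is calibrated to the study's mortality", {
  cfg <- simulation_config(n = 559, event_rate = 43 / 559, seed = 53)
  b0 <- calibrate_intercept(cfg)
  cov <- generate_cohort(cfg)
  lp <- conperform:::sim_linear_predictor(cfg, cov$age, cov$heart_rate,
                                          cov$pao2)
  expect_equal(mean(stats::plogis(b0 + lp)), 43 / 559, tolerance = 1e-4)
  # event count within wide binomial bounds of the 43 expected deaths
  counts <- vapply(1:5, function(i) {
    sum(generate_cohort(simulation_config(n = 559, seed = 53 + i))$died_30d)
  }, numeric(1))
  bounds <- stats::qbinom(c(0.005, 0.995), 559, 43 / 559)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))

  # symmetric null: target 0.5 with zero weights calibrates to intercept 0
  null_cfg <- simulation_config(n = 1000, true_weights = c(0, 0, 0),
                                event_rate = 0.5, seed = 55)
  expect_equal(calibrate_intercept(null_cfg), 0, tolerance = 1e-8)
  expect_error(
    calibrate_intercept(simulation_config(event_rate = 1e-9)),
    "between 0 and 1|extreme"
  )
})

test_that("zero true weights produce labels independent of covariates", {
  cfg <- simulation_config(n = 1500, true_weights = c(0, 0, 0),
                           event_rate = 0.3, seed = 57)
  cohort <- generate_cohort(cfg)
  g <- con_perform_score(cohort$age, cohort$heart_rate, cohort$pao2,
                         c(0.5, 0.3, 0.2))
  expect_equal(auc(g, cohort$died_30d), 0.5, tolerance = 0.05)
})

test_that("stronger signal monotonically raises the true-direction AUC", {
  aucs <- vapply(c(0.02, 0.1, 0.4), function(s) {
    cfg <- simulation_config(n = 4000, effect_scale = s, event_rate = 0.2,
                             seed = 59)
    co <- generate_cohort(cfg)
    auc(con_perform_score(co$age, co$heart_rate, co$pao2, c(0.6, 0.25, 0.15)),
        co$died_30d)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("correlated covariates honor the requested correlation", {
  C <- matrix(c(1, 0.5, -0.3, 0.5, 1, -0.2, -0.3, -0.2, 1), 3, 3)
  cohort <- generate_cohort(simulation_config(n = 8000, correlation = C,
                                              seed = 61))
  emp <- stats::cor(cbind(cohort$age, cohort$heart_rate, cohort$pao2))
  # truncation attenuates the latent correlation slightly
  expect_lt(abs(emp[1, 2] - 0.5), 0.06)
  expect_lt(abs(emp[1, 3] + 0.3), 0.06)
  expect_true(all(cohort$age >= 18 & cohort$age <= 105))
})
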