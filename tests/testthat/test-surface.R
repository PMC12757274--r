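test_that("weight-pair sampling is uniform, seeded, and strictly interior", {
  p <- sample_weight_pairs(5000, seed = 2)
  expect_equal(nrow(p), 5000L)
  expect_true(all(p$x > 0 & p$x < 1 & p$y > 0 & p$y < 1))
  expect_identical(p, sample_weight_pairs(5000, seed = 2))

  big <- sample_weight_pairs(10000, seed = 3)
  expect_equal(mean(big$x), 0.5, tolerance = 0.02)
  expect_equal(mean(big$y), 0.5, tolerance = 0.02)
  expect_error(sample_weight_pairs(0), "positive")
})

test_that("surface evaluation equals the pair-counting oracle point by point", {
  cohort <- tiny_cohort(8, seed = 21)
  pairs <- tibble::tibble(x = c(0.2, 0.5, 0.8), y = c(0.3, 0.6, 0.9))
  samples <- evaluate_surface(cohort, pairs)
  expect_equal(nrow(samples), 3L)
  for (k in 1:3) {
    w <- expand_weights(pairs$x[k], pairs$y[k])
    g <- con_perform_score(cohort$age, cohort$heart_rate, cohort$pao2, w)
    expect_equal(samples$q[k], auc_pair_oracle(g, cohort$died_30d))
  }
  expect_true(all(samples$q >= 0 & samples$q <= 1))
  # determinism
  expect_identical(samples, evaluate_surface(cohort, pairs))
})

test_that("a single informative covariate shapes the surface as expected", {
  # only age differs between classes: q rises with the age weight x
  withr::with_seed(5, {
    n <- 120
    died <- rep(c(TRUE, FALSE), length.out = n)
    cohort <- tibble::tibble(
      age = ifelse(died, rnorm(n, 85, 5), rnorm(n, 65, 5)),
      heart_rate = rnorm(n, 85, 1e-3),
      pao2 = rnorm(n, 75, 1e-3),
      died_30d = died
    )
  })
  pairs <- tibble::tibble(x = c(0.05, 0.5, 0.95), y = rep(0.5, 3))
  q <- evaluate_surface(cohort, pairs)$q
  expect_true(all(diff(q) >= 0))
  expect_gt(q[3], 0.9)
})

test_that("polynomial fitting recovers an exact low-degree surface", {
  truth <- function(x, y) 0.3 + 0.5 * x - 0.4 * y + 0.2 * x * y - 0.1 * x^2
  withr::with_seed(9, {
    samples <- tibble::tibble(x = runif(200), y = runif(200))
    samples$q <- truth(samples$x, samples$y)
  })
  fit <- fit_polynomial_surface(samples, order = 2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  co <- fit$coefficients
  expect_equal(co$coefficient[co$i == 0 & co$j == 0], 0.3, tolerance = 1e-8)
  expect_equal(co$coefficient[co$i == 1 & co$j == 1], 0.2, tolerance = 1e-8)
  expect_equal(co$coefficient[co$i == 2 & co$j == 0], -0.1, tolerance = 1e-8)
  # prediction reproduces the truth away from the fitting points
  grid <- tibble::tibble(x = seq(0.1, 0.9, 0.2), y = seq(0.9, 0.1, -0.2))
  expect_equal(predict(fit, grid), truth(grid$x, grid$y), tolerance = 1e-8)

  # an under-parameterized fit is strictly worse
  fit1 <- fit_polynomial_surface(samples, order = 1)
  expect_lt(fit1$r_squared, fit$r_squared)
})

test_that("basis size matches the total-degree term count and bounds the data", {
  samples <- withr::with_seed(1, tibble::tibble(x = runif(40), y = runif(40), q = runif(40)))
  fit7 <- fit_polynomial_surface(samples, order = 7)
  expect_equal(nrow(fit7$coefficients), 36L)
  expect_error(fit_polynomial_surface(samples[1:35, ], order = 7),
               "at least 36")
})

test_that("surrogate maximization matches analytic and grid oracles", {
  # analytic concave quadratic with interior maximum
  quad <- structure(
    list(order = 2,
         coefficients = tibble::tibble(
           i = c(0, 1, 0, 2, 1, 0),
           j = c(0, 0, 1, 0, 1, 2),
           # 0.8 - (x-0.3)^2 - (y-0.7)^2
           coefficient = c(0.8 - 0.09 - 0.49, 0.6, 1.4, -1, 0, -1)
         ),
         r_squared = NA_real_, n = NA_integer_),
    class = "cp_polysurface"
  )
  opt <- maximize_surface(quad)
  expect_equal(opt$x, 0.3, tolerance = 1e-6)
  expect_equal(opt$y, 0.7, tolerance = 1e-6)
  expect_equal(opt$value, 0.8, tolerance = 1e-9)
  expect_equal(opt$location, "interior")

  # monotone surface: the corner wins and is reported as boundary
  mono <- structure(
    list(order = 1,
         coefficients = tibble::tibble(i = c(0, 1, 0), j = c(0, 0, 1),
                                       coefficient = c(0, 1, 1)),
         r_squared = NA_real_, n = NA_integer_),
    class = "cp_polysurface"
  )
  m <- maximize_surface(mono)
  expect_equal(c(m$x, m$y, m$value), c(1, 1, 2), tolerance = 1e-8)
  expect_equal(m$location, "boundary")

  # random quartics against a dense grid
  for (seed in 1:5) {
    s <- random_surface(4, seed = seed)
    got <- maximize_surface(s)
    ref <- grid_max_oracle(s, grid_n = 1001L)
    expect_gte(got$value, ref$value - 1e-6)
    expect_equal(got$value, ref$value, tolerance = 1e-4)
  }
})
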