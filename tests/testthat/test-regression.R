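
test_that("noiseless data regenerates every printed equation to 1e-6", {
  for (spec in table2_models) {
    x <- seq(x_range[[spec$index]][1], x_range[[spec$index]][2],
             length.out = 30)
    y <- eval_cf(spec$family, spec$cf, x)
    ft <- curve_table(x, y, index = spec$index)
    fit <- fit_univariate(ft, spec$index, spec$family)
    expect_equal(coef(fit), spec$cf, tolerance = 1e-6,
                 label = paste(spec$family, spec$index))
    expect_equal(fit$modeling_r2, 1, tolerance = 1e-9)
  }
})

test_that("predictions evaluate the closed forms, rasters included", {
  quad <- fit_univariate(
    curve_table(seq(-30, 5, length.out = 20),
                eval_cf("quadratic", c(b2 = 5.812, b1 = -19.178,
                                       b0 = 3018.857),
                        seq(-30, 5, length.out = 20))),
    "CIVE", "quadratic")
  expect_equal(predict(quad, 0), 3018.857, tolerance = 1e-6)

  lin <- fit_univariate(
    curve_table(1:10, -175.307 * (1:10) + 2248.548), "CIVE", "linear")
  expect_equal(predict(lin, 0), 2248.548, tolerance = 1e-9)

  # nodata propagates through raster prediction
  r <- agb_raster(matrix(c(0, NA, 1, 2), 2, 2), origin = c(0, 2), gsd = 1)
  pr <- predict(lin, r)
  expect_true(is.na(band(pr)[2, 1]))
  expect_equal(band(pr)[1, 1], 2248.548, tolerance = 1e-9)
  rna <- agb_raster(matrix(NA_real_, 2, 2), origin = c(0, 2), gsd = 1)
  expect_true(all(is.na(band(predict(lin, rna)))))
})

test_that("degenerate fits behave as documented", {
  # constant response: zero slope, mean intercept, R2 defined as 0
  ft <- curve_table(1:10, rep(500, 10))
  fit <- fit_univariate(ft, "CIVE", "linear")
  expect_equal(unname(coef(fit)["b1"]), 0)
  expect_equal(unname(coef(fit)["b0"]), 500)
  expect_equal(fit$modeling_r2, 0)

  # constant predictor is singular
  expect_error(fit_univariate(curve_table(rep(2, 10), rnorm(10)),
                              "CIVE", "linear"), "singular")
  # exponential needs positive responses
  expect_error(fit_univariate(curve_table(1:10, c(-1, 2:10)),
                              "CIVE", "exponential"), "> 0")
  expect_error(fit_univariate(curve_table(1:3, 1:3), "WI", "linear"),
               "not in the feature table")
})

test_that("least-squares structure holds: orthogonality and nesting", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(30); y <- 5000 + 300 * x + rnorm(30, 0, 150)
    ft <- curve_table(x, y)
    lin <- fit_univariate(ft, "CIVE", "linear")
    qua <- fit_univariate(ft, "CIVE", "quadratic")
    scale_ <- sqrt(sum(y^2))
    expect_lt(abs(sum(residuals(lin))), 1e-8 * scale_)
    expect_lt(abs(sum(residuals(lin) * x)), 1e-8 * scale_)
    expect_lt(abs(sum(residuals(qua) * x^2)), 1e-8 * scale_)
    # the quadratic family nests the linear one
    expect_gte(qua$modeling_r2, lin$modeling_r2 - 1e-12)
  }
})

test_that("exponential fits use the log-linear route with optional nls", {
  set.seed(8)
  x <- runif(25, 10, 22)
  y <- 413.174 * exp(0.136 * x) * exp(rnorm(25, 0, 0.05))
  fit <- fit_univariate(curve_table(x, y), "CIVE", "exponential")
  expect_match(fit$route, "log-linear")
  expect_equal(unname(coef(fit)["b"]), 0.136, tolerance = 0.05)
  fit2 <- fit_univariate(curve_table(x, y), "CIVE", "exponential",
                         refine = TRUE)
  expect_match(fit2$route, "refinement")
  expect_equal(unname(coef(fit2)["b"]), 0.136, tolerance = 0.05)
})

test_that("validation lines recover exact linear relations", {
  pred <- c(3000, 4000, 5000, 6000, 7000)
  vl <- fit_validation_line(pred, pred)
  expect_equal(vl$slope, 1, tolerance = 1e-12)
  expect_equal(vl$intercept, 0, tolerance = 1e-9)
  expect_equal(vl$r2_fit, 1, tolerance = 1e-12)

  vl2 <- fit_validation_line(pred, 2 * pred + 10)
  expect_equal(vl2$slope, 2, tolerance = 1e-12)
  expect_equal(vl2$intercept, 10, tolerance = 1e-9)

  # independent pairs give near-zero r2_fit on average
  set.seed(77)
  r2s <- replicate(200, {
    fit_validation_line(rnorm(8, 5000, 500), rnorm(8, 5000, 500))$r2_fit
  })
  expect_lt(median(r2s), 0.25)

  vl3 <- fit_validation_line(rep(5, 5), rnorm(5))
  expect_true(is.na(vl3$slope))
  expect_error(fit_validation_line(1:2, 1:2), "at least 3")
})

test_that("univariate models expose the standard S3 surface", {
  set.seed(12)
  x <- rnorm(20); y <- 4000 + 100 * x + rnorm(20, 0, 50)
  fit <- fit_univariate(curve_table(x, y), "CIVE", "linear")
  expect_s3_class(fit, "agb_model")
  expect_output(print(fit), "linear model")
  expect_equal(fitted(fit) + residuals(fit), y)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(20L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 1), sims)
})
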