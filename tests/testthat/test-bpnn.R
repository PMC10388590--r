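test_that("the forward pass matches a hand-unrolled oracle", {
  set.seed(2)
  p <- 4; m <- 3; n <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, letters[1:p]))
  # build a model by hand around known weights and identity-like scaling
  df <- as.data.frame(X)
  df$agb <- rnorm(n, 0.5, 0.2)
  mod <- train_bpnn(df, letters[1:p], hidden = m,
                    config = bpnn_config(max_iterations = 1, seed = 3))
  W <- mod$weights
  pred <- predict(mod, df)
  for (i in seq_len(n)) {
    xs <- (X[i, ] - mod$input_scaling$min) /
      ((mod$input_scaling$max - mod$input_scaling$min) / 2) - 1
    z <- oracle_forward(xs, W$W1, W$b1, W$w2, W$b2)
    want <- (z + 1) * (mod$target_scaling$max - mod$target_scaling$min) /
      2 + mod$target_scaling$min
    expect_equal(pred[i], unname(want), tolerance = 1e-12)
  }
})

test_that("min-max scaling round-trips exactly", {
  set.seed(5)
  df <- data.frame(a = runif(20, -3, 9), b = runif(20, 100, 300))
  df$agb <- runif(20, 3000, 7600)
  mod <- train_bpnn(df, c("a", "b"), hidden = 2,
                    config = bpnn_config(max_iterations = 1))
  sc <- mod$target_scaling
  y <- df$agb
  z <- (y - sc$min) / ((sc$max - sc$min) / 2) - 1
  back <- (z + 1) * (sc$max - sc$min) / 2 + sc$min
  expect_equal(back, y, tolerance = 1e-12)
  expect_true(all(z >= -1 - 1e-12 & z <= 1 + 1e-12))
})

test_that("a representable linear target trains to near-zero error", {
  set.seed(5)
  df <- data.frame(a = runif(30, -2, 2), b = runif(30, -1, 3))
  df$agb <- 3000 + 40 * df$a - 25 * df$b
  mod <- train_bpnn(df, c("a", "b"), hidden = 3,
                    config = bpnn_config(seed = 2))
  expect_lt(sqrt(mod$training_log$final_mse_scaled), 1e-3)
  expect_lte(mod$training_log$iterations, 1000L)
})

test_that("identical seeds give bitwise-identical models", {
  set.seed(10)
  ft <- generate_feature_table_direct(n = 38, seed = 4)
  ft <- split_samples(ft, 30, seed = 4)
  ins <- c("CIVE", "ExG", "G", "B")
  m1 <- train_bpnn(ft, ins, hidden = 3, config = bpnn_config(seed = 11))
  m2 <- train_bpnn(ft, ins, hidden = 3, config = bpnn_config(seed = 11))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training_log$loss_trace, m2$training_log$loss_trace)
  m3 <- train_bpnn(ft, ins, hidden = 3, config = bpnn_config(seed = 12))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("plain-LM training loss is nonincreasing across accepted steps", {
  set.seed(20)
  df <- data.frame(a = rnorm(25), b = rnorm(25))
  df$agb <- 5000 + 300 * tanh(df$a) - 200 * df$b + rnorm(25, 0, 50)
  mod <- train_bpnn(df, c("a", "b"), hidden = 3,
                    config = bpnn_config(seed = 6, regularization = "none",
                                         val_fraction = 0))
  expect_true(all(diff(mod$training_log$loss_trace) <= 1e-15))
})

test_that("the network beats a linear fit on a warped response", {
  set.seed(30)
  df <- data.frame(a = runif(30, -2, 2), b = runif(30, -2, 2))
  df$agb <- 5000 + 800 * sin(1.5 * df$a) * tanh(df$b)
  lin <- lm(agb ~ a + b, data = df)
  lin_rmse <- sqrt(mean(residuals(lin)^2))
  mod <- train_bpnn(df, c("a", "b"), hidden = 3,
                    config = bpnn_config(seed = 3))
  bp_rmse <- sqrt(mean(residuals(mod)^2))
  expect_lt(bp_rmse, lin_rmse)
})

test_that("zero weights predict the midpoint of the target range", {
  set.seed(40)
  df <- data.frame(a = runif(20), agb = runif(20, 3000, 7600))
  mod <- train_bpnn(df, "a", hidden = 3,
                    config = bpnn_config(max_iterations = 1))
  mod$weights$W1[] <- 0; mod$weights$b1[] <- 0
  mod$weights$w2[] <- 0; mod$weights$b2 <- 0
  expect_equal(unique(round(predict(mod, df), 9)),
               round(mean(range(df$agb)), 9))
})

test_that("prediction demands matching inputs and propagates missing", {
  set.seed(50)
  ft <- generate_feature_table_direct(n = 20, seed = 5)
  mod <- train_bpnn(ft, c("CIVE", "ExG"), hidden = 2,
                    config = bpnn_config(max_iterations = 5))
  expect_error(predict(mod, ft[, c("plot_id", "CIVE")]), "lacks input")
  nd <- ft[1:5, c("CIVE", "ExG")]
  nd$ExG[2] <- NA
  pr <- predict(mod, nd)
  expect_true(is.na(pr[2]) && all(is.finite(pr[-2])))

  # raster stacks: missing pixels in any band go missing in the output
  r1 <- agb_raster(matrix(c(-10, -12, NA, -8), 2, 2), origin = c(0, 2),
                   gsd = 1)
  r2 <- agb_raster(matrix(c(40, 42, 44, 46), 2, 2), origin = c(0, 2),
                   gsd = 1)
  out <- predict(mod, list(CIVE = r1, ExG = r2))
  expect_s3_class(out, "agb_raster")
  expect_true(is.na(band(out)[1, 2]))
  expect_true(all(is.finite(band(out)[-3])))
  expect_error(predict(mod, list(CIVE = r1)), "lacks input")
})

test_that("hidden-size candidates follow the rule and ties pick smaller", {
  set.seed(60)
  ft <- generate_feature_table_direct(n = 38, seed = 6)
  ft <- split_samples(ft, 30, seed = 6)
  ins <- c("R", "G", "B", "ExG", "ExGR", "CIVE", "COM", "COM2")
  # rule-based default range for 8 inputs: round(sqrt(9)) + 1..10 = 4..13
  sel <- select_hidden_neurons(ft, ins, k = 1,
                               config = bpnn_config(max_iterations = 20))
  expect_equal(sel$scores$m, 4:13)
  expect_true(sel$m %in% 4:13)

  solo <- select_hidden_neurons(ft, ins, candidates = 3, k = 1,
                                config = bpnn_config(max_iterations = 5))
  expect_equal(solo$m, 3L)

  # equal scores resolve to the smaller candidate
  dup <- select_hidden_neurons(ft, ins, candidates = c(3, 3), k = 1,
                               config = bpnn_config(max_iterations = 5))
  expect_equal(dup$m, 3L)
  expect_error(select_hidden_neurons(ft, ins, candidates = integer(0)),
               "empty")
})

test_that("training refuses inconsistent input specifications", {
  ft <- generate_feature_table_direct(n = 20, seed = 9)
  expect_error(train_bpnn(ft, c("CIVE", "nope")), "not in the feature")
  expect_error(train_bpnn(ft[1:3, ], c("CIVE", "ExG", "G")), "at least")
})
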