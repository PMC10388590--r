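make_plot_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

test_that("plot tables are validated on read", {
  df <- data.frame(plot_id = sprintf("P%02d", 1:38),
                   x = runif(38, 0, 10), y = runif(38, 0, 10),
                   edge = 0.6, height = runif(38, 1.2, 1.54),
                   agb = runif(38, 3000, 7600))
  got <- read_plots(make_plot_csv(df))
  expect_equal(nrow(got), 38L)
  expect_true(all(is.na(got$role)))

  bad <- df; bad$agb[5] <- -5
  expect_error(read_plots(make_plot_csv(bad)), "agb")
  dup <- df; dup$plot_id[2] <- dup$plot_id[1]
  expect_error(read_plots(make_plot_csv(dup)), "duplicate")
  expect_error(read_plots(make_plot_csv(df[0, ])), "no plots")
  expect_error(read_plots(make_plot_csv(df[, c("plot_id", "agb")])),
               "lacks column")
})

test_that("window means reproduce closed-form block averages", {
  # 7x7 raster holding 1..49 column-major; 5x5 block centred mid-raster
  v <- matrix(1:49, 7, 7)
  r <- agb_raster(v, origin = c(0, 7), gsd = 1)
  plot <- list(plot_id = "P1", x = 3.5, y = 3.5)  # centre pixel (4, 4)
  w <- extract_window_mean(r, plot, window = 5)
  expect_equal(w$value, mean(v[2:6, 2:6]))
  expect_false(w$truncated); expect_false(w$missing)

  # the documented 5x5 example: values 1..25 in the window average to 13
  v2 <- matrix(0, 9, 9); v2[3:7, 3:7] <- matrix(1:25, 5, 5)
  r2 <- agb_raster(v2, origin = c(0, 9), gsd = 1)
  expect_equal(extract_window_mean(r2, list(x = 4.5, y = 4.5), 5)$value, 13)

  # constant raster -> the constant, anywhere in bounds
  rc <- agb_raster(matrix(3.25, 6, 6), origin = c(0, 6), gsd = 1)
  expect_equal(extract_window_mean(rc, list(x = 1.1, y = 5.4), 5)$value,
               3.25)
})

test_that("edge windows truncate and heavy nodata flags missing", {
  v <- matrix(1:36, 6, 6)
  r <- agb_raster(v, origin = c(0, 6), gsd = 1)
  w <- extract_window_mean(r, list(x = 0.5, y = 5.5), 5)  # corner pixel
  expect_true(w$truncated)
  expect_equal(w$value, mean(v[1:3, 1:3]))

  vm <- v; vm[1:5, 1:4] <- NA            # 20 of 25 window px missing
  rm_ <- agb_raster(vm, origin = c(0, 6), gsd = 1)
  w2 <- extract_window_mean(rm_, list(x = 2.5, y = 3.5), 5)
  expect_true(w2$missing)
  expect_true(is.na(w2$value))

  expect_error(extract_window_mean(r, list(x = 99, y = 1), 5), "outside")
})

test_that("feature tables assemble agb plus one column per index", {
  set.seed(3)
  idx <- lapply(1:17, function(i)
    agb_raster(matrix(rnorm(100, i), 10, 10), origin = c(0, 10), gsd = 1))
  names(idx) <- index_registry()
  plots <- data.frame(plot_id = sprintf("P%02d", 1:38),
                      x = runif(38, 2.5, 7.5), y = runif(38, 2.5, 7.5),
                      agb = runif(38, 3000, 7600))
  ft <- build_feature_table(idx, plots, window = 5)
  expect_equal(nrow(ft), 38L)
  expect_setequal(setdiff(names(ft), c("plot_id", "role")),
                  c("agb", index_registry()))
  expect_equal(nrow(attr(ft, "excluded")), 0L)

  # row order follows input but the values are order-independent
  perm <- sample(38)
  ft2 <- build_feature_table(idx, plots[perm, ], window = 5)
  expect_equal(ft2$ExG, ft$ExG[perm])

  # a plot over a nodata strip is excluded with a reason; the rest survive
  idx$ExG$values[, 1:3, 1] <- NA         # x in [0, 3) is missing
  plots2 <- plots                        # all others sit at x >= 2.5+2px
  plots2$x <- pmax(plots2$x, 5.5)
  plots2$x[1] <- 1.5                     # window 75% inside the strip
  ft3 <- build_feature_table(idx, plots2, window = 5)
  expect_equal(nrow(ft3), 37L)
  expect_equal(attr(ft3, "excluded")$plot_id, "P01")
  expect_match(attr(ft3, "excluded")$reason, "nodata")

  # grid mismatch among rasters is refused
  idx_bad <- idx
  idx_bad$WI <- agb_raster(matrix(0, 5, 5), origin = c(0, 5), gsd = 1)
  expect_error(build_feature_table(idx_bad, plots), "shared grid")
})

test_that("feature tables round-trip through CSV with provenance", {
  idx <- list(ExG = agb_raster(matrix(1:16, 4, 4), origin = c(0, 4),
                               gsd = 1))
  plots <- data.frame(plot_id = c("A", "B"), x = c(1.5, 2.5),
                      y = c(1.5, 2.5), agb = c(10, 20))
  ft <- build_feature_table(idx, plots, window = 3)
  p <- tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  back <- read_feature_table(p)
  expect_equal(back$ExG, ft$ExG)
  expect_equal(attr(back, "provenance")$window, 3L)
})

test_that("the 30/8 split partitions reproducibly and honours roles", {
  plots <- data.frame(plot_id = sprintf("P%02d", 1:38),
                      x = runif(38), y = runif(38),
                      agb = runif(38, 3000, 7600))
  s1 <- split_samples(plots, 30, seed = 7)
  expect_equal(sum(s1$role == "modeling"), 30L)
  expect_equal(sum(s1$role == "validation"), 8L)
  expect_identical(split_samples(plots, 30, seed = 7), s1)
  expect_false(identical(split_samples(plots, 30, seed = 8)$role, s1$role))

  for (seed in 1:100) {
    s <- split_samples(plots, 30, seed = seed)
    expect_equal(sort(unique(s$role)), c("modeling", "validation"))
    expect_equal(sum(s$role == "modeling"), 30L)
  }

  # preassigned roles are kept; fully assigned input ignores the seed
  pre <- plots
  pre$role <- rep(c("modeling", "validation"), c(30, 8))
  expect_identical(split_samples(pre, 30, seed = 1)$role, pre$role)
  expect_identical(split_samples(pre, 30, seed = 99)$role, pre$role)
  half <- plots; half$role <- NA_character_
  half$role[1:5] <- "modeling"
  s <- split_samples(half, 30, seed = 3)
  expect_true(all(s$role[1:5] == "modeling"))
  expect_equal(sum(s$role == "modeling"), 30L)

  expect_error(split_samples(plots, 38, seed = 1), "must be <")
})
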