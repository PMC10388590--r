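small_cfg <- function(seed = 1, ...) {
  scene_config(seed = seed, shape = c(500L, 500L), ...)
}

test_that("scenes are bitwise reproducible per seed", {
  s1 <- generate_scene(small_cfg(3))
  s2 <- generate_scene(small_cfg(3))
  expect_identical(s1$rgb$values, s2$rgb$values)
  expect_identical(s1$truth$agb_field$values, s2$truth$agb_field$values)
  expect_identical(s1$truth$plots, s2$truth$plots)
  s3 <- generate_scene(small_cfg(4))
  expect_false(identical(s1$rgb$values, s3$rgb$values))
})

test_that("scene structure honours the configured study design", {
  cfg <- small_cfg(7, vegetation_fraction = 0.55, n_plots = 38)
  sc <- generate_scene(cfg)
  expect_equal(dim(sc$rgb), c(500L, 500L, 3L))
  expect_true(all(sc$rgb$values %in% 0:255))
  mv <- band(sc$truth$mask)
  expect_true(all(mv %in% c(0, 1)))
  expect_equal(mean(mv), 0.55, tolerance = 0.02)
  # the AGB field lives only inside the mask and spans the range
  af <- band(sc$truth$agb_field)
  expect_true(all(is.na(af[mv == 0])))
  expect_equal(range(af[mv == 1]), cfg$agb_range, tolerance = 0.01)

  pl <- sc$truth$plots
  expect_equal(nrow(pl), 38L)
  expect_true(all(pl$agb %% 10 == 0))        # 10 g scale accuracy
  # plots fall inside the mask, at least one edge apart
  rc <- cbind(floor((sc$truth$mask$origin[2] - pl$y) / cfg$gsd) + 1,
              floor((pl$x - sc$truth$mask$origin[1]) / cfg$gsd) + 1)
  expect_true(all(mv[rc] == 1))
  dmin <- min(dist(cbind(pl$x, pl$y)))
  expect_gte(dmin, cfg$plot_edge - 1e-9)
})

test_that("noiseless plots read the field exactly up to 10 g rounding", {
  sc <- generate_scene(small_cfg(5, noise_sigma = 0))
  pl <- sc$truth$plots
  expect_true(all(abs(pl$agb - pl$true_agb) <= 5 + 1e-9))
})

test_that("greenness rises and CIVE falls with biomass by construction", {
  ok <- 0L
  for (s in 1:6) {
    sc <- generate_scene(small_cfg(s))
    work <- resample_block_mean(sc$rgb, 0.6)
    idx <- compute_all(work, select = c("ExG", "CIVE", "COM2"))
    pl <- sc$truth$plots
    ft <- build_feature_table(idx, pl, window = 5)
    r <- setNames(pearson_matrix(ft, rows = "all")$stats$r,
                  pearson_matrix(ft, rows = "all")$stats$index)
    if (r[["ExG"]] > 0.6 && r[["CIVE"]] < -0.6 && r[["COM2"]] > 0.6)
      ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("a crowded mask refuses more plots than it can host", {
  expect_error(
    generate_scene(scene_config(seed = 1, shape = c(120L, 120L),
                                vegetation_fraction = 0.05,
                                n_plots = 200L)),
    "plots")
})

test_that("scene bundles round-trip through disk", {
  sc <- generate_scene(small_cfg(2, n_plots = 10))
  dir <- file.path(tempdir(), "scene_bundle")
  write_scene(sc, dir)
  rgb <- load_rgb(file.path(dir, "rgb.tif"))
  expect_equal(rgb$values, sc$rgb$values)
  mask <- read_raster(file.path(dir, "mask.asc"))
  expect_equal(band(mask), band(sc$truth$mask))
  pl <- read_plots(file.path(dir, "plots.csv"))
  expect_equal(pl$agb, sc$truth$plots$agb)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 2L)
})

test_that("directly drawn tables expose their generating model", {
  # noiseless quadratic coupling: the printed-scale coefficients return
  ft <- generate_feature_table_direct(n = 38, seed = 1, noise_sigma = 0)
  fit <- fit_univariate(ft, "CIVE", "quadratic")
  expect_equal(coef(fit),
               c(b2 = 5.812, b1 = -19.178, b0 = 3018.857),
               tolerance = 1e-6)

  # determinism and the documented boundary size
  expect_identical(generate_feature_table_direct(n = 38, seed = 2),
                   generate_feature_table_direct(n = 38, seed = 2))
  tiny <- generate_feature_table_direct(n = 5, seed = 3, noise_sigma = 0)
  expect_equal(nrow(tiny), 5L)
  fit5 <- fit_univariate(tiny, "CIVE", "quadratic")
  expect_equal(unname(coef(fit5)["b2"]), 5.812, tolerance = 1e-6)

  # heavy noise destroys the fit quality, as a degradation check
  noisy <- generate_feature_table_direct(n = 38, seed = 4,
                                         noise_sigma = 1.0)
  fitn <- fit_univariate(noisy, "CIVE", "quadratic")
  expect_lt(fitn$modeling_r2, 0.3)

  # correlation pattern follows the configured targets
  set.seed(1)
  big <- generate_feature_table_direct(n = 400, seed = 5,
                                       noise_sigma = 0.05)
  r <- setNames(pearson_matrix(big, rows = "all")$stats$r,
                pearson_matrix(big, rows = "all")$stats$index)
  expect_lt(r[["CIVE"]], -0.8)
  expect_gt(r[["ExG"]], 0.7)
  expect_gt(r[["COM2"]], 0.7)
  expect_lt(abs(r[["WI"]]), 0.3)
})
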