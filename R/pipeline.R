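#' Run the full AGB estimation workflow
#'
#' Chains the stages end to end: resample the orthomosaic to the plot
#' scale, compute the seventeen vegetation indices, align the species mask,
#' build the per-plot feature table, correlate and select indices, fit the
#' univariate families on the strongly correlated indices, train the
#' network on the significantly correlated ones, evaluate everything on the
#' validation plots, and invert the best model into an AGB map.
#'
#' @param rgb RGB orthomosaic: an `agb_raster` or a file path.
#' @param plots plot table: a data.frame or a CSV path (see
#'   [read_plots()]).
#' @param mask optional species mask (`agb_raster` or path); `NULL` maps
#'   the whole scene.
#' @param outdir optional output directory; when given, rasters, tables,
#'   model records and a run manifest are written there.
#' @param target_gsd working grid resolution, m (default 0.6, the plot
#'   edge).
#' @param window plot extraction window in pixels (default 5).
#' @param dialect index formula dialect (see [index_registry()]).
#' @param threshold_high,alpha selection thresholds (defaults 0.8, 0.05).
#' @param n_modeling modeling-set size for the random split (default 30).
#' @param seed integer seed driving the split and network initialisation.
#' @param families univariate families to fit.
#' @param hidden hidden-layer size for the network (default 3).
#' @param max_iterations LM iteration cap (default 1000).
#' @param r2_variant holdout R2 centring (see [evaluate()]).
#' @param clamp0 truncate negative map predictions to zero.
#' @return list with the stage products: `resampled`, `mask`, `indices`,
#'   `features`, `correlation`, `selection`, `models` (univariate list +
#'   `bpnn`), `evaluations`, `comparison`, `best_model_id`, `map`,
#'   `manifest`.
#' @export
run_pipeline <- function(rgb, plots, mask = NULL, outdir = NULL,
                         target_gsd = 0.6, window = 5L,
                         dialect = "as-printed", threshold_high = 0.8,
                         alpha = 0.05, n_modeling = 30L, seed = 1L,
                         families = c("linear", "quadratic", "exponential"),
                         hidden = 3L, max_iterations = 1000L,
                         r2_variant = "measured-mean", clamp0 = FALSE) {
  if (is.character(rgb)) rgb <- load_rgb(rgb)
  if (is.character(plots)) plots <- read_plots(plots)
  if (is.character(mask)) mask <- read_raster(mask)

  work <- resample_block_mean(rgb, target_gsd)
  if (!is.null(mask)) mask <- align_mask(mask, work)
  indices <- compute_all(work, dialect = dialect)

  plots <- split_samples(plots, n_modeling = n_modeling, seed = seed)
  features <- build_feature_table(indices, plots, window = window)
  corr <- pearson_matrix(features)
  sel <- select_indices(corr, threshold_high = threshold_high,
                        alpha = alpha)
  ord <- order(-abs(corr$stats$r))
  uni_set <- sel$univariate
  if (!length(uni_set)) {
    uni_set <- utils::head(corr$stats$index[ord], 3L)
    warning("falling back to the 3 highest-|r| indices for univariate fits")
  }
  bp_set <- sel$bpnn
  if (!length(bp_set)) {
    bp_set <- utils::head(corr$stats$index[ord], 8L)
    warning("falling back to the 8 highest-|r| indices as network inputs")
  }
  # cap the network at the eight strongest inputs: with ~30 modeling plots
  # more inputs push the weight count past the sample count
  bp_set <- utils::head(bp_set, 8L)

  val <- features[features$role %in% "validation", , drop = FALSE]
  models <- list()
  evals <- list()
  for (ix in uni_set) for (fam in families) {
    id <- paste(fam, ix, sep = "_")
    mod <- tryCatch(fit_univariate(features, ix, fam),
                    error = function(e) e)
    if (inherits(mod, "error")) {
      warning("skipping ", id, ": ", conditionMessage(mod))
      next
    }
    models[[id]] <- mod
    evals[[id]] <- evaluate(val$agb, predict(mod, val[[ix]]),
                            model_id = id, r2_variant = r2_variant)
  }
  bp <- train_bpnn(features, bp_set, hidden = hidden,
                   config = bpnn_config(max_iterations = max_iterations,
                                        seed = seed))
  models$bpnn <- bp
  evals$bpnn <- evaluate(val$agb, predict(bp, val), model_id = "bpnn",
                         r2_variant = r2_variant)

  rmses <- vapply(evals, `[[`, 1, "rmse")
  quad <- grep("^quadratic_", names(evals), value = TRUE)
  baseline <- if (length(quad)) quad[which.min(rmses[quad])]
              else names(evals)[which.min(rmses)]
  comparison <- compare_models(evals, baseline = baseline)
  best_id <- comparison$model_id[1]
  map <- invert_map(models[[best_id]], indices, mask = mask,
                    clamp0 = clamp0)

  manifest <- list(
    config = list(target_gsd = target_gsd, window = window,
                  dialect = dialect, threshold_high = threshold_high,
                  alpha = alpha, n_modeling = n_modeling, seed = seed,
                  families = families, hidden = hidden,
                  max_iterations = max_iterations,
                  r2_variant = r2_variant, clamp0 = clamp0),
    selection = list(univariate = uni_set, bpnn = bp_set),
    n_plots = nrow(plots), n_features = nrow(features),
    excluded = attr(features, "excluded")$plot_id,
    baseline = baseline, best_model = best_id,
    map_summary = attr(map, "summary"),
    version = as.character(utils::packageVersion("wetlandAGB")))
  manifest$config_hash <- object_hash(manifest$config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    idx_dir <- file.path(outdir, "indices")
    dir.create(idx_dir, showWarnings = FALSE)
    paths <- character(0)
    for (nm in names(indices)) {
      pth <- file.path(idx_dir, paste0(nm, ".asc"))
      write_raster(indices[[nm]], pth)
      paths <- c(paths, pth)
    }
    write_feature_table(features, file.path(outdir, "features.csv"))
    utils::write.csv(
      data.frame(corr$matrix, check.names = FALSE),
      file.path(outdir, "correlation_matrix.csv"))
    jsonlite::write_json(
      lapply(models, model_record),
      file.path(outdir, "models.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    write_raster(map, file.path(outdir, "agb_map.asc"))
    manifest$paths <- c(paths, file.path(outdir, c(
      "features.csv", "correlation_matrix.csv", "models.json",
      "comparison.csv", "agb_map.asc")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(resampled = work, mask = mask, indices = indices,
       features = features, correlation = corr,
       selection = list(univariate = uni_set, bpnn = bp_set),
       models = models, evaluations = evals, comparison = comparison,
       best_model_id = best_id, map = map, manifest = manifest)
}

# serialisable model record (JSON interface)
model_record <- function(m) {
  if (inherits(m, "agb_bpnn")) {
    list(kind = "bpnn", architecture = m$architecture, inputs = m$inputs,
         weights = list(W1 = as.vector(m$weights$W1), b1 = m$weights$b1,
                        w2 = m$weights$w2, b2 = m$weights$b2),
         input_scaling = m$input_scaling,
         target_scaling = m$target_scaling,
         training = m$training_log[c("iterations", "final_mse_scaled",
                                     "stop_reason", "seed")])
  } else {
    list(kind = "univariate", family = m$family, index = m$index_name,
         coefficients = as.list(m$coefficients),
         modeling_r2 = m$modeling_r2, n_fit = m$n_fit, route = m$route)
  }
}
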