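#' Apply a fitted model across index rasters to map AGB
#'
#' Evaluates the model per pixel inside the species mask. Pixels outside
#' the mask, or with any required index missing, are missing in the output.
#' Negative predictions (possible for regression models at extreme index
#' values) are reported as-is by default and counted; `clamp0 = TRUE`
#' truncates them to zero.
#'
#' @param model an `agb_univariate` or `agb_bpnn` model.
#' @param indices named list of single-band `agb_raster`s on one grid,
#'   containing every index the model requires.
#' @param mask optional binary species mask on the same grid; `NULL` maps
#'   the whole raster.
#' @param clamp0 truncate negative predictions to 0 (default `FALSE`).
#' @return object of class `c("agb_map", "agb_raster")`: the prediction
#'   raster with attributes `summary` (min/max/mean/n of valid pixels),
#'   `model_id`, `mask_applied`, `n_negative`.
#' @export
invert_map <- function(model, indices, mask = NULL, clamp0 = FALSE) {
  stopifnot(inherits(model, "agb_model"), is.list(indices),
            !is.null(names(indices)))
  need <- if (inherits(model, "agb_bpnn")) model$inputs else model$index_name
  miss <- setdiff(need, names(indices))
  if (length(miss)) stop("index stack lacks required layer(s): ",
                         paste(miss, collapse = ", "))
  ref <- indices[[need[1]]]
  for (nm in need)
    if (!same_grid(indices[[nm]], ref))
      stop("index raster '", nm, "' is not on the shared grid")
  if (!is.null(mask)) {
    if (!same_grid(mask, ref))
      stop("mask is not on the index grid; align_mask() it first")
    mv <- band(mask)
  } else mv <- NULL

  if (inherits(model, "agb_bpnn")) {
    pred_r <- predict(model, indices[need])
  } else {
    pred_r <- predict(model, indices[[need]])
  }
  v <- band(pred_r)
  if (!is.null(mv)) v[!(mv %in% 1) | !is.finite(mv)] <- NA_real_
  n_neg <- sum(v < 0, na.rm = TRUE)
  if (clamp0) v[is.finite(v) & v < 0] <- 0
  out <- agb_raster(v, origin = ref$origin, gsd = ref$gsd, crs = ref$crs,
                    nodata = ref$nodata)
  class(out) <- c("agb_map", class(out))
  valid <- v[is.finite(v)]
  attr(out, "summary") <- if (length(valid))
    list(min = min(valid), max = max(valid), mean = mean(valid),
         n = length(valid))
  else {
    warning("empty mask or no valid pixels; map summary undefined")
    list(min = NA_real_, max = NA_real_, mean = NA_real_, n = 0L)
  }
  attr(out, "model_id") <- paste0(
    class(model)[1], ":",
    if (inherits(model, "agb_bpnn")) paste(model$inputs, collapse = "+")
    else paste(model$family, model$index_name))
  attr(out, "mask_applied") <- !is.null(mask)
  attr(out, "n_negative") <- n_neg
  attr(out, "clamped") <- clamp0
  out
}

#' @export
print.agb_map <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<agb_map> %s%s\n", attr(x, "model_id"),
              if (attr(x, "mask_applied")) ", masked" else ""))
  cat(sprintf("  %d valid px: min %.1f, mean %.1f, max %.1f g/m2\n",
              s$n, s$min, s$mean, s$max))
  if (attr(x, "n_negative") > 0)
    cat(sprintf("  %d negative prediction(s)%s\n", attr(x, "n_negative"),
                if (attr(x, "clamped")) " clamped to 0" else ""))
  NextMethod()
}

#' Summary statistics of an AGB map, optionally by zone
#'
#' @param map an `agb_map` (or any single-band `agb_raster`).
#' @param zones optional integer-labelled zone raster on the same grid;
#'   `NULL` summarises the whole map as one zone.
#' @return data.frame with `zone, n, min, max, mean` over valid pixels;
#'   zones with no valid pixel report `n = 0` and `NA` statistics.
#' @export
summarize_map <- function(map, zones = NULL) {
  stopifnot(inherits(map, "agb_raster"))
  v <- band(map)
  if (is.null(zones)) {
    z <- rep(1L, length(v))
  } else {
    if (!same_grid(zones, map)) stop("zone raster is not on the map grid")
    z <- as.vector(band(zones))
  }
  vv <- as.vector(v)
  zl <- sort(unique(z[is.finite(z)]))
  out <- do.call(rbind, lapply(zl, function(zi) {
    vals <- vv[z == zi & is.finite(vv) & !is.na(z)]
    if (length(vals))
      data.frame(zone = zi, n = length(vals), min = min(vals),
                 max = max(vals), mean = mean(vals))
    else
      data.frame(zone = zi, n = 0L, min = NA_real_, max = NA_real_,
                 mean = NA_real_)
  }))
  rownames(out) <- NULL
  out
}
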