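#' Visible-band vegetation index registry
#'
#' The seventeen indices commonly computed from UAV RGB imagery for canopy
#' monitoring: the raw bands R, G, B; the ratio indices RGRI, BGRI, RGBRI;
#' the Woebbecke index WI; the normalised differences NGRDI, NGBDI, VDVI,
#' RGBVI; the vegetation index VEG; the colour index of vegetation CIVE; the
#' excess-green family ExG, ExGR; and the weighted combinations COM and
#' COM2.
#'
#' Two formula dialects exist for ExGR and CIVE:
#' * `"as-printed"` (default): `ExGR = ExG - 1.4 R - G` read literally, and
#'   `CIVE = 0.44 R - 0.88 G + 0.39 B + 18.79` on raw band values.
#' * `"canonical"`: the forms widespread in the crop-segmentation
#'   literature, `ExGR = ExG - (1.4 R - G)` and CIVE on chromatic
#'   coordinates `r = R/(R+G+B)` etc.,
#'   `CIVE = 0.441 r - 0.811 g + 0.385 b + 18.78745`.
#'
#' The composite indices COM and COM2 are always built from the same-dialect
#' ExG/ExGR/CIVE/VEG values.
#'
#' @return character vector of the seventeen index names, in registry order.
#' @export
index_registry <- function() {
  c("R", "G", "B", "RGRI", "BGRI", "WI", "NGRDI", "NGBDI", "RGBRI",
    "VEG", "CIVE", "ExG", "ExGR", "COM", "COM2", "VDVI", "RGBVI")
}

# guarded division: exact zero denominator -> NA
div0 <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Evaluate one vegetation index on band vectors
#'
#' Vectorised pure function of the band values; pixels where the formula is
#' singular (zero denominator; zero base under a fractional power in VEG)
#' evaluate to `NA`.
#'
#' @param name index name from [index_registry()].
#' @param R,G,B numeric vectors of band values (digital numbers).
#' @param dialect `"as-printed"` or `"canonical"`; see [index_registry()].
#' @return numeric vector of index values.
#' @export
index_value <- function(name, R, G, B, dialect = c("as-printed", "canonical")) {
  dialect <- match.arg(dialect)
  exg <- 2 * G - R - B
  switch(name,
    R = R + 0, G = G + 0, B = B + 0,
    RGRI  = div0(R, G),
    BGRI  = div0(B, G),
    WI    = div0(G - B, R - G),
    NGRDI = div0(G - R, G + R),
    NGBDI = div0(G - B, G + B),
    RGBRI = div0(R + B, 2 * G),
    VEG   = {
      den <- R^0.67 * B^0.33
      out <- div0(G, den)
      out[R <= 0 | B <= 0] <- NA_real_
      out
    },
    CIVE  = if (dialect == "as-printed") {
      0.44 * R - 0.88 * G + 0.39 * B + 18.79
    } else {
      tot <- R + G + B
      0.441 * div0(R, tot) - 0.811 * div0(G, tot) +
        0.385 * div0(B, tot) + 18.78745
    },
    ExG   = exg,
    ExGR  = if (dialect == "as-printed") exg - 1.4 * R - G
            else exg - (1.4 * R - G),
    COM   = 0.25 * index_value("ExG",  R, G, B, dialect) +
            0.30 * index_value("ExGR", R, G, B, dialect) +
            0.33 * index_value("CIVE", R, G, B, dialect) +
            0.12 * index_value("VEG",  R, G, B, dialect),
    COM2  = 0.36 * index_value("ExG",  R, G, B, dialect) +
            0.47 * index_value("CIVE", R, G, B, dialect) +
            0.17 * index_value("VEG",  R, G, B, dialect),
    VDVI  = div0(2 * G - R - B, 2 * G + R + B),
    RGBVI = div0(G^2 - R * B, G^2 + R * B),
    stop("unknown index name: '", name, "'")
  )
}

#' Compute one vegetation index as a raster
#'
#' Applies a registry formula per pixel. Output pixels are missing wherever
#' any source band is missing or the formula is singular there.
#'
#' @param raster a 3-band `agb_raster` (R, G, B).
#' @param name index name from [index_registry()].
#' @inheritParams index_value
#' @return single-band `agb_raster` on the source grid.
#' @export
compute_index <- function(raster, name,
                          dialect = c("as-printed", "canonical")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(raster, "agb_raster"))
  if (n_bands(raster) < 3L) stop("need a 3-band RGB raster")
  if (!name %in% index_registry()) stop("unknown index name: '", name, "'")
  R <- band(raster, 1); G <- band(raster, 2); B <- band(raster, 3)
  bad <- !is.finite(R) | !is.finite(G) | !is.finite(B)
  v <- index_value(name, as.vector(R), as.vector(G), as.vector(B), dialect)
  v <- matrix(v, nrow(R), ncol(R))
  v[bad] <- NA_real_
  out <- agb_raster(v, origin = raster$origin, gsd = raster$gsd,
                    crs = raster$crs, nodata = raster$nodata)
  attr(out, "index") <- name
  attr(out, "dialect") <- dialect
  out
}

#' Compute all seventeen registry indices
#'
#' @inheritParams compute_index
#' @param select optional character vector restricting the set of indices.
#' @return named list of single-band `agb_raster`s, one per index.
#' @export
compute_all <- function(raster, dialect = c("as-printed", "canonical"),
                        select = index_registry()) {
  dialect <- match.arg(dialect)
  unknown <- setdiff(select, index_registry())
  if (length(unknown)) stop("unknown index name(s): ",
                            paste(unknown, collapse = ", "))
  out <- lapply(select, function(nm) compute_index(raster, nm, dialect))
  names(out) <- select
  out
}
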