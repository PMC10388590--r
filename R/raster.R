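#' Lightweight georeferenced raster
#'
#' Container for single- or multi-band raster data on a north-up, square-pixel
#' grid. Band values are stored as stored digital numbers (no reflectance
#' calibration is attempted); missing pixels are `NA` internally and are
#' mapped to a sentinel `nodata` value only on write.
#'
#' The grid convention is pixel-area with map coordinates at pixel centres:
#' the centre of cell `(row, col)` is at
#' `x = origin[1] + (col - 0.5) * gsd`, `y = origin[2] - (row - 0.5) * gsd`,
#' where `origin` is the map coordinate of the top-left corner of the
#' top-left pixel and rows increase southwards.
#'
#' @param values numeric matrix (one band) or 3-d array (rows x cols x bands).
#' @param origin length-2 numeric, map x/y of the top-left raster corner (m).
#' @param gsd ground sampling distance, m per pixel (square pixels).
#' @param crs coordinate reference identifier (free-form string), or `NA`.
#' @param nodata sentinel used in files for missing pixels (default -9999).
#' @return an object of class `agb_raster`.
#' @export
agb_raster <- function(values, origin = c(0, 0), gsd = 1,
                       crs = NA_character_, nodata = -9999) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(origin) == 2L, is.finite(gsd), gsd > 0)
  storage.mode(values) <- "double"
  structure(list(values = values, origin = as.numeric(origin),
                 gsd = as.numeric(gsd), crs = crs, nodata = nodata),
            class = "agb_raster")
}

#' @export
dim.agb_raster <- function(x) dim(x$values)

n_bands <- function(r) dim(r$values)[3L]

#' Extract one band of a raster as a matrix
#' @param r an `agb_raster`.
#' @param band band number (1-based).
#' @return numeric matrix.
#' @export
band <- function(r, band = 1L) {
  d <- dim(r$values)
  matrix(r$values[, , band], d[1], d[2])
}

#' @export
print.agb_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<agb_raster> %d x %d px, %d band(s), gsd %g m\n",
              d[1], d[2], d[3], x$gsd))
  cat(sprintf("  origin (%.3f, %.3f)%s\n", x$origin[1], x$origin[2],
              if (is.na(x$crs)) "" else paste0(", crs ", x$crs)))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values [%g, %g], %d valid px\n", min(v), max(v),
                sum(rowSums(!is.finite(
                  matrix(x$values, prod(d[1:2]), d[3]))) == 0)))
  invisible(x)
}

# map coordinate -> (row, col) of the pixel whose area contains it
map_to_cell <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$gsd) + 1L
  row <- floor((r$origin[2] - y) / r$gsd) + 1L
  cbind(row = as.integer(row), col = as.integer(col))
}

cell_center <- function(r, row, col) {
  cbind(x = r$origin[1] + (col - 0.5) * r$gsd,
        y = r$origin[2] - (row - 0.5) * r$gsd)
}

extent_of <- function(r) {
  d <- dim(r$values)
  c(xmin = r$origin[1], xmax = r$origin[1] + d[2] * r$gsd,
    ymin = r$origin[2] - d[1] * r$gsd, ymax = r$origin[2])
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values)[1:2] == dim(b$values)[1:2]) &&
    abs(a$gsd - b$gsd) < tol * max(1, a$gsd) &&
    all(abs(a$origin - b$origin) < tol * max(1, a$gsd))
}

## ---------------------------------------------------------------------------
## File I/O: ESRI ASCII grid for float rasters, TIFF + world file for imagery
## ---------------------------------------------------------------------------

#' Write a raster to disk
#'
#' Two interchange formats are supported, chosen by file extension:
#' * `.asc` — ESRI ASCII grid (single band, full double precision,
#'   georeferencing in the header). A `.aux.json` sidecar stores the crs.
#' * `.tif`/`.tiff` — TIFF for 8-bit imagery (all values integers in
#'   0..255). Georeferencing goes to an ESRI world file (`.tfw`) and
#'   nodata/crs to a `.aux.json` sidecar.
#'
#' @param r an `agb_raster`.
#' @param path output path ending in `.asc`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "agb_raster"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") write_raster_asc(r, path)
  else if (ext %in% c("tif", "tiff")) write_raster_tif(r, path)
  else stop("unsupported raster extension: '.", ext, "' (use .asc or .tif)")
  invisible(path)
}

aux_path <- function(path) paste0(path, ".aux.json")

write_aux <- function(r, path) {
  jsonlite::write_json(
    list(crs = r$crs, nodata = r$nodata),
    aux_path(path), auto_unbox = TRUE, null = "null", digits = NA)
}

read_aux <- function(path) {
  if (file.exists(aux_path(path))) jsonlite::read_json(aux_path(path))
  else list(crs = NULL, nodata = NULL)
}

write_raster_asc <- function(r, path) {
  if (n_bands(r) != 1L)
    stop("ASCII grid holds a single band; got ", n_bands(r))
  d <- dim(r$values)
  v <- band(r)
  v[!is.finite(v)] <- r$nodata
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10f", r$origin[1]),
           sprintf("yllcorner %.10f", r$origin[2] - d[1] * r$gsd),
           sprintf("cellsize %.12g", r$gsd),
           sprintf("NODATA_value %.12g", r$nodata))
  rows <- apply(v, 1L, function(z)
    paste(formatC(z, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  write_aux(r, path)
}

read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = lines[i:(i + nr - 1L)], quiet = TRUE)
  v <- matrix(vals, nr, nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  v[v == nodata] <- NA_real_
  aux <- read_aux(path)
  agb_raster(v,
             origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
             gsd = hdr$cellsize,
             crs = if (is.null(aux$crs)) NA_character_ else aux$crs,
             nodata = nodata)
}

tfw_path <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)

write_raster_tif <- function(r, path) {
  v <- r$values
  fin <- is.finite(v)
  if (any(v[fin] < 0 | v[fin] > 255 | v[fin] != round(v[fin])))
    stop("TIFF output supports 8-bit integer values 0..255; ",
         "write float rasters as .asc")
  nodata <- if (any(!fin)) 255 else r$nodata
  v[!fin] <- nodata
  img <- aperm(v, c(1, 2, 3)) / 255
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  writeLines(sprintf("%.12f", c(r$gsd, 0, 0, -r$gsd,
                                r$origin[1] + r$gsd / 2,
                                r$origin[2] - r$gsd / 2)),
             tfw_path(path))
  r2 <- r; r2$nodata <- if (any(!fin)) nodata else r$nodata
  write_aux(r2, path)
}

read_raster_tif <- function(path) {
  img <- tiff::readTIFF(path)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  v <- round(img * 255)
  gsd <- 1; origin <- c(0, 0)
  if (file.exists(tfw_path(path))) {
    w <- as.numeric(readLines(tfw_path(path)))
    gsd <- w[1]
    origin <- c(w[5] - gsd / 2, w[6] + gsd / 2)
  } else {
    warning("no world file for ", path, "; assuming unit grid at origin")
  }
  aux <- read_aux(path)
  nodata <- if (is.null(aux$nodata)) -9999 else aux$nodata
  if (nodata >= 0 && nodata <= 255) v[v == nodata] <- NA_real_
  agb_raster(v, origin = origin, gsd = gsd,
             crs = if (is.null(aux$crs)) NA_character_ else aux$crs,
             nodata = nodata)
}

#' Read a raster from disk
#'
#' Counterpart of [write_raster()]; dispatches on extension.
#'
#' @param path path to a `.asc` or `.tif`/`.tiff` raster.
#' @return an `agb_raster`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") read_raster_asc(path)
  else if (ext %in% c("tif", "tiff")) read_raster_tif(path)
  else stop("unsupported raster extension: '.", ext, "'")
}

#' Load an RGB orthomosaic
#'
#' Reads a raster file and returns its first three bands as R, G, B. Extra
#' bands (e.g. an alpha channel) are dropped.
#'
#' @param path raster file with at least three bands.
#' @return a 3-band `agb_raster`.
#' @export
load_rgb <- function(path) {
  r <- read_raster(path)
  nb <- n_bands(r)
  if (nb < 3L)
    stop("expected ≥3 bands for an RGB orthomosaic, found ", nb)
  if (nb > 3L) r$values <- r$values[, , 1:3, drop = FALSE]
  r
}

## ---------------------------------------------------------------------------
## Resampling and mask alignment
## ---------------------------------------------------------------------------

# Overlap-length weight matrix between output intervals and input intervals
# along one axis. Input pixel j spans [lo + (j-1)*g_in, lo + j*g_in]; output
# pixel J spans [LO + (J-1)*g_out, LO + J*g_out]. W[J, j] = overlap length.
overlap_weights <- function(n_out, lo_out, g_out, n_in, lo_in, g_in) {
  J <- seq_len(n_out); j <- seq_len(n_in)
  a0 <- lo_out + (J - 1) * g_out; a1 <- lo_out + J * g_out
  b0 <- lo_in + (j - 1) * g_in;   b1 <- lo_in + j * g_in
  lo <- outer(a0, b0, pmax); hi <- outer(a1, b1, pmin)
  w <- hi - lo
  w[w < 0] <- 0
  w
}

# Area-weighted mean of `v` (matrix, NA = missing) onto a target grid given
# per-axis weight matrices. Returns list(mean, cover) where cover is the
# covered valid area per output pixel.
weighted_block_mean <- function(v, w_row, w_col) {
  valid <- is.finite(v)
  v0 <- v; v0[!valid] <- 0
  num <- w_row %*% v0 %*% t(w_col)
  den <- w_row %*% (valid + 0) %*% t(w_col)
  m <- num / den
  m[den <= 0] <- NA_real_
  list(mean = m, cover = den)
}

#' Resample a raster to a coarser grid by area-weighted (block) mean
#'
#' Each output pixel is the mean of the source pixels it covers, weighted by
#' overlap area; missing source pixels are excluded and an output pixel is
#' missing only when all of its contributors are. When the target grid step
#' is an integer multiple of the source step this is an exact block mean and
#' the global mean of valid pixels is conserved. Used to bring centimetre
#' imagery to the field-plot scale (0.6 m).
#'
#' @param r an `agb_raster`.
#' @param target_gsd output ground sampling distance, m; must be >= `r$gsd`.
#' @return an `agb_raster` on the coarser grid, same origin and crs.
#' @export
resample_block_mean <- function(r, target_gsd) {
  stopifnot(inherits(r, "agb_raster"))
  if (target_gsd < r$gsd * (1 - 1e-9))
    stop("target_gsd (", target_gsd, ") must be >= source gsd (", r$gsd,
         "); upsampling is out of contract")
  if (abs(target_gsd - r$gsd) < 1e-12 * max(1, r$gsd)) return(r)
  d <- dim(r$values)
  n_out_r <- max(1L, ceiling(d[1] * r$gsd / target_gsd - 1e-9))
  n_out_c <- max(1L, ceiling(d[2] * r$gsd / target_gsd - 1e-9))
  # work in a local frame measured from the top-left corner
  w_row <- overlap_weights(n_out_r, 0, target_gsd, d[1], 0, r$gsd)
  w_col <- overlap_weights(n_out_c, 0, target_gsd, d[2], 0, r$gsd)
  out <- array(NA_real_, c(n_out_r, n_out_c, d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- weighted_block_mean(r$values[, , b], w_row, w_col)$mean
  agb_raster(out, origin = r$origin, gsd = target_gsd, crs = r$crs,
             nodata = r$nodata)
}

#' Align a binary species mask to a reference grid
#'
#' Resamples a 0/1 mask onto the grid of `reference` by area-weighted
#' majority rule; exact ties resolve to 0 (conservative: outside the target
#' species). A mask already on the reference grid is returned unchanged.
#'
#' @param mask single-band `agb_raster` with values in `{0, 1, NA}`.
#' @param reference `agb_raster` defining the target grid.
#' @return the mask on the reference grid.
#' @export
align_mask <- function(mask, reference) {
  stopifnot(inherits(mask, "agb_raster"), inherits(reference, "agb_raster"))
  if (n_bands(mask) != 1L) stop("mask must be single-band")
  mv <- band(mask)
  if (!all(mv[is.finite(mv)] %in% c(0, 1)))
    stop("mask values must be 0, 1 or missing")
  if (!is.na(mask$crs) && !is.na(reference$crs) &&
      !identical(mask$crs, reference$crs))
    stop("crs mismatch between mask (", mask$crs, ") and reference (",
         reference$crs, ")")
  if (same_grid(mask, reference)) return(mask)
  em <- extent_of(mask); er <- extent_of(reference)
  if (em["xmin"] >= er["xmax"] || em["xmax"] <= er["xmin"] ||
      em["ymin"] >= er["ymax"] || em["ymax"] <= er["ymin"])
    stop("mask and reference extents are disjoint")
  dr <- dim(reference$values); dm <- dim(mask$values)
  w_row <- overlap_weights(dr[1], -er["ymax"], reference$gsd,
                           dm[1], -em["ymax"], mask$gsd)
  w_col <- overlap_weights(dr[2], er["xmin"], reference$gsd,
                           dm[2], em["xmin"], mask$gsd)
  wb <- weighted_block_mean(mv, w_row, w_col)
  out <- ifelse(is.na(wb$mean), NA_real_, as.numeric(wb$mean > 0.5))
  agb_raster(matrix(out, dr[1], dr[2]),
             origin = reference$origin, gsd = reference$gsd,
             crs = reference$crs, nodata = mask$nodata)
}
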