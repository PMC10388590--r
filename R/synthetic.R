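#' Configuration for synthetic wetland scenes
#'
#' Describes the study conditions the generator emulates: a
#' centimetre-resolution RGB orthomosaic over an emergent-vegetation stand,
#' a binary species mask, a smooth true-AGB field in the fresh-weight range
#' observed for *Zizania latifolia* stands at peak season, and 0.6 m field
#' plots whose weighed AGB is the field value plus measurement noise,
#' rounded to the 10 g accuracy of a field scale.
#'
#' @param seed integer seed; every random element derives from it.
#' @param shape raster size in pixels, `c(rows, cols)` (default 1000 x
#'   1000, i.e. 24 m x 24 m at the default gsd).
#' @param gsd ground sampling distance, m/pixel (default 0.024).
#' @param agb_range true AGB span inside the stand, g/m2 (default
#'   3000-7600).
#' @param noise_sigma plot measurement noise, as a fraction of the AGB
#'   range (default 0.15).
#' @param vegetation_fraction fraction of the scene inside the species
#'   mask (default 0.6).
#' @param n_plots number of field plots (default 38).
#' @param plot_edge plot edge length, m (default 0.6; also the minimum
#'   separation between plot centres).
#' @param color_noise per-pixel Gaussian colour noise, digital numbers
#'   (default 4).
#' @param smoothness correlation scale of the AGB and mask fields, in
#'   0.6 m cells of the coarse generator grid (default 8, ~5 m features —
#'   larger than the 3 m extraction footprint, so stands are locally
#'   homogeneous at the plot scale as the windowed protocol presumes).
#' @param crs coordinate reference label (default `"local"`).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(seed = 1L, shape = c(1000L, 1000L), gsd = 0.024,
                         agb_range = c(3000, 7600), noise_sigma = 0.15,
                         vegetation_fraction = 0.6, n_plots = 38L,
                         plot_edge = 0.6, color_noise = 4,
                         smoothness = 8, crs = "local") {
  stopifnot(agb_range[1] < agb_range[2], vegetation_fraction > 0,
            vegetation_fraction <= 1, noise_sigma >= 0, n_plots >= 1,
            plot_edge > 0, gsd > 0, all(shape >= 4))
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 gsd = gsd, agb_range = agb_range,
                 noise_sigma = noise_sigma,
                 vegetation_fraction = vegetation_fraction,
                 n_plots = as.integer(n_plots), plot_edge = plot_edge,
                 color_noise = color_noise, smoothness = smoothness,
                 crs = crs),
            class = "scene_config")
}

# colour endpoints of the ramp: open water / sparse background vs dense
# canopy. G rises and R, B fall with AGB, so ExG rises and CIVE falls by
# construction (a test-harness colour model, not radiometry).
scene_palette <- function() {
  list(water = c(R = 110, G = 115, B = 120),
       canopy = c(R = 42, G = 168, B = 48))
}

## separable Gaussian smoothing with edge renormalisation
gauss_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  smooth1 <- function(x) {
    # convolve columns of x with k, renormalising at the borders
    n <- nrow(x)
    out <- matrix(0, n, ncol(x)); wsum <- matrix(0, n, ncol(x))
    for (o in -half:half) {
      w <- k[o + half + 1]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + w * x[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out / wsum
  }
  t(smooth1(t(smooth1(m))))
}

## bilinear upsampling of a coarse matrix to a fine grid covering the same
## extent (both grids share the top-left corner; cell centres interpolated)
bilinear_up <- function(mc, n_out_r, n_out_c, factor) {
  # position of fine-cell centre i in coarse-cell units
  pos <- function(n_out) ((seq_len(n_out) - 0.5) / factor) + 0.5 - 0.5
  interp_axis <- function(p, n_in) {
    p <- pmin(pmax(p, 1), n_in)
    i0 <- pmin(floor(p), n_in - 1L)
    list(i0 = as.integer(i0), w = p - i0)
  }
  pr <- interp_axis(pos(n_out_r) + 0.5, nrow(mc))
  pc <- interp_axis(pos(n_out_c) + 0.5, ncol(mc))
  a <- mc[pr$i0, pc$i0, drop = FALSE]
  b <- mc[pr$i0 + 1L, pc$i0, drop = FALSE]
  d <- mc[pr$i0, pc$i0 + 1L, drop = FALSE]
  e <- mc[pr$i0 + 1L, pc$i0 + 1L, drop = FALSE]
  wr <- matrix(pr$w, n_out_r, n_out_c)
  wc <- matrix(pc$w, n_out_r, n_out_c, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) +
    d * (1 - wr) * wc + e * wr * wc
}

#' Generate a synthetic RGB scene with known AGB ground truth
#'
#' Builds, reproducibly from the seed: a smooth true-AGB field spanning
#' `agb_range` over a smoothly shaped species mask; RGB pixels whose colour
#' ramps from a water/background endpoint to a dense-canopy endpoint with
#' local AGB (so greenness indices such as ExG rise, and CIVE falls, with
#' biomass by construction) plus per-pixel colour noise; and `n_plots`
#' field plots placed at least one plot edge apart inside the mask, with
#' 10 g-rounded noisy AGB readings.
#'
#' @param config a [scene_config()].
#' @return list with elements `rgb` (3-band `agb_raster`, 8-bit values),
#'   `truth` (list: `agb_field` raster with `NA` outside the mask, `mask`
#'   raster, `plots` data.frame, `config`).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    nr <- config$shape[1]; nc <- config$shape[2]
    # coarse generator grid at ~0.6 m
    cg <- 0.6
    factor <- cg / config$gsd
    nrc <- max(4L, ceiling(nr / factor)); ncc <- max(4L, ceiling(nc / factor))
    u_c <- gauss_smooth(matrix(stats::rnorm(nrc * ncc), nrc, ncc),
                        config$smoothness)
    m_c <- gauss_smooth(matrix(stats::rnorm(nrc * ncc), nrc, ncc),
                        config$smoothness * 2)
    u <- bilinear_up(u_c, nr, nc, factor)
    mfield <- bilinear_up(m_c, nr, nc, factor)
    thresh <- stats::quantile(mfield, 1 - config$vegetation_fraction)
    mask <- (mfield >= thresh) + 0
    # normalised greenness/AGB driver in [0, 1] within the mask
    inm <- mask == 1
    u01 <- u
    rng <- range(u[inm])
    u01 <- (u - rng[1]) / diff(rng)
    u01 <- pmin(pmax(u01, 0), 1)
    agb <- config$agb_range[1] + u01 * diff(config$agb_range)
    agb[!inm] <- NA_real_

    pal <- scene_palette()
    rgbv <- array(NA_real_, c(nr, nc, 3))
    for (b in 1:3) {
      lo <- pal$water[b]; hi <- pal$canopy[b]
      base <- matrix(lo, nr, nc)
      base[inm] <- lo + (hi - lo) * u01[inm]
      base <- base + matrix(stats::rnorm(nr * nc, 0, config$color_noise),
                            nr, nc)
      rgbv[, , b] <- pmin(pmax(round(base), 0), 255)
    }

    origin <- c(0, nr * config$gsd)   # local frame, top-left at (0, H)
    rgb <- agb_raster(rgbv, origin = origin, gsd = config$gsd,
                      crs = config$crs, nodata = -9999)
    mask_r <- agb_raster(mask, origin = origin, gsd = config$gsd,
                         crs = config$crs)
    agb_r <- agb_raster(agb, origin = origin, gsd = config$gsd,
                        crs = config$crs)

    plots <- place_plots(mask_r, agb, config)
    list(rgb = rgb,
         truth = list(agb_field = agb_r, mask = mask_r, plots = plots,
                      config = config))
  })
}

# rejection-sample plot centres inside the mask with minimum separation of
# one plot edge; reads the true field at the centre pixel and adds seeded
# measurement noise rounded to 10 g
place_plots <- function(mask_r, agb, config) {
  inm <- which(band(mask_r) == 1, arr.ind = TRUE)
  # keep centres at least half an edge from the scene border
  margin <- ceiling(config$plot_edge / 2 / config$gsd)
  d <- dim(mask_r$values)
  inm <- inm[inm[, 1] > margin & inm[, 1] <= d[1] - margin &
               inm[, 2] > margin & inm[, 2] <= d[2] - margin, ,
             drop = FALSE]
  if (nrow(inm) < config$n_plots)
    stop("vegetation fraction too small to host ", config$n_plots, " plots")
  sep2 <- config$plot_edge^2
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < config$n_plots) {
    tries <- tries + 1L
    if (tries > 10000L * config$n_plots)
      stop("could not place ", config$n_plots,
           " non-overlapping plots inside the mask")
    i <- inm[sample.int(nrow(inm), 1L), ]
    ctr <- cell_center(mask_r, i[1], i[2])
    if (length(xs) &&
        any((xs - ctr[1])^2 + (ys - ctr[2])^2 < sep2)) next
    xs <- c(xs, ctr[1]); ys <- c(ys, ctr[2])
  }
  rc <- map_to_cell(mask_r, xs, ys)
  true_agb <- agb[cbind(rc[, 1], rc[, 2])]
  noise <- stats::rnorm(config$n_plots, 0,
                        config$noise_sigma * diff(config$agb_range))
  meas <- pmax(round((true_agb + noise) / 10) * 10, 0)
  data.frame(plot_id = sprintf("P%02d", seq_len(config$n_plots)),
             x = xs, y = ys, edge = config$plot_edge,
             height = round(stats::runif(config$n_plots, 1.20, 1.54), 2),
             agb = meas, role = NA_character_,
             true_agb = true_agb)
}

#' Write a synthetic scene bundle to disk
#'
#' Writes `rgb.tif` (+ world file), `mask.asc`, `truth_agb.asc`,
#' `plots.csv` and `config.json` under `dir`.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(scene$rgb, file.path(dir, "rgb.tif"))
  write_raster(scene$truth$mask, file.path(dir, "mask.asc"))
  write_raster(scene$truth$agb_field, file.path(dir, "truth_agb.asc"))
  utils::write.csv(scene$truth$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(scene$truth$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default AGB-index correlation targets
#'
#' The sign-and-magnitude pattern of AGB correlations the generator aims
#' for: strong with CIVE (negative), ExG and COM2 (positive), moderate
#' with the raw bands, ExGR and COM, and weak (non-significant at n = 30)
#' for the ratio and normalised-difference indices and WI.
#'
#' @return named numeric vector over the registry indices.
#' @export
correlation_targets <- function() {
  c(R = 0.584, G = 0.736, B = 0.662, RGRI = -0.25, BGRI = -0.28,
    WI = 0.05, NGRDI = 0.22, NGBDI = 0.25, RGBRI = -0.27, VEG = 0.30,
    CIVE = -0.870, ExG = 0.866, ExGR = -0.534, COM = -0.476,
    COM2 = 0.837, VDVI = 0.22, RGBVI = 0.26)
}

# location/scale per index along the noise-free colour ramp, for plausible
# index units in directly drawn tables
ramp_index_stats <- function(dialect = "as-printed") {
  pal <- scene_palette()
  u <- seq(0, 1, length.out = 201)
  ch <- sapply(1:3, function(b)
    pal$water[b] + (pal$canopy[b] - pal$water[b]) * u)
  stats <- lapply(index_registry(), function(nm) {
    v <- index_value(nm, ch[, 1], ch[, 2], ch[, 3], dialect)
    c(mu = mean(v), sd = stats::sd(v))
  })
  names(stats) <- index_registry()
  stats
}

#' Generate a feature table directly, with a known generating model
#'
#' Fast path for testing the model layer without rasters. A latent canopy
#' density `g ~ N(0,1)` drives everything: CIVE is an exact (decreasing)
#' linear function of `g`, placed on the scale implied by the backbone
#' coefficients so that the quadratic response spans the field AGB range;
#' every other index is drawn with a target correlation to AGB following
#' the observed wetland pattern (see [correlation_targets()]), with
#' idiosyncratic Gaussian components otherwise. AGB is the stated coupling
#' of the index values plus noise; the generating model is returned in the
#' `"generator"` attribute for recovery tests.
#'
#' Couplings:
#' * `"quadratic_cive"` (default): `agb = b2 CIVE^2 + b1 CIVE + b0 +
#'   noise` — a single-index model a univariate fit can fully capture.
#' * `"multi_index"`: the quadratic CIVE backbone plus a bounded nonlinear
#'   term `multi_amp * range * tanh((e_ExGR + e_COM)/sqrt(2))` driven by
#'   the idiosyncratic components of ExGR and COM. These two indices are
#'   only moderately correlated with AGB (never univariate candidates),
#'   so the term is structurally invisible to any single-index model while
#'   a multi-input network seeing ExGR, COM and the strong indices can
#'   recover it.
#'
#' @param n number of plots (default 38).
#' @param seed integer seed.
#' @param coupling `"quadratic_cive"` or `"multi_index"`.
#' @param coefficients quadratic backbone coefficients `(b2, b1, b0)` with
#'   `b2 > 0` (default `c(5.812, -19.178, 3018.857)`, a published-scale
#'   CIVE response).
#' @param agb_range AGB span the backbone covers, g/m2 (default
#'   3000-7600).
#' @param noise_sigma i.i.d. Gaussian noise, as a fraction of the backbone
#'   AGB range (default 0.15).
#' @param multi_amp amplitude of the multi-index term, same units
#'   (default 0.25).
#' @param target_r named correlation targets (default
#'   [correlation_targets()]).
#' @param dialect index dialect (see [index_registry()]).
#' @return data.frame `plot_id, role, agb` + 17 index columns, with
#'   attribute `"generator"` describing the generating model.
#' @export
generate_feature_table_direct <- function(
    n = 38L, seed = 1L,
    coupling = c("quadratic_cive", "multi_index"),
    coefficients = c(5.812, -19.178, 3018.857),
    agb_range = c(3000, 7600),
    noise_sigma = 0.15, multi_amp = 0.25,
    target_r = correlation_targets(),
    dialect = "as-printed") {
  coupling <- match.arg(coupling)
  stopifnot(n >= 5, length(coefficients) == 3, coefficients[1] > 0)
  q <- function(x) coefficients[1] * x^2 + coefficients[2] * x +
    coefficients[3]
  # decreasing branch of the parabola covering agb_range:
  # from the vertex up to the x where q reaches the range top
  xv <- -coefficients[2] / (2 * coefficients[1])
  top <- max(agb_range[2], q(xv) + 1)
  x_lo <- xv - sqrt((top - q(xv)) / coefficients[1])
  cive_mu <- (x_lo + xv) / 2
  cive_sd <- (xv - x_lo) / 4          # +-2 sd spans the branch
  rstats <- ramp_index_stats(dialect)
  rho <- target_r / max(abs(target_r))
  rho <- pmin(pmax(rho, -1), 1)
  with_seed(seed, {
    g <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * length(index_registry())), n)
    colnames(eps) <- index_registry()
    tab <- as.data.frame(sapply(index_registry(), function(nm) {
      if (nm == "CIVE") return(cive_mu - cive_sd * g)
      s <- rstats[[nm]]
      s[["mu"]] + s[["sd"]] *
        (rho[[nm]] * g + sqrt(1 - rho[[nm]]^2) * eps[, nm])
    }))
    backbone <- q(tab$CIVE)
    rng <- diff(range(backbone))
    if (rng == 0) rng <- max(1, abs(mean(backbone)))
    extra <- 0
    if (coupling == "multi_index")
      extra <- multi_amp * rng *
        tanh((eps[, "ExGR"] + eps[, "COM"]) / sqrt(2))
    agb <- backbone + extra + stats::rnorm(n, 0, noise_sigma * rng)
    out <- cbind(data.frame(plot_id = sprintf("P%02d", seq_len(n)),
                            role = NA_character_, agb = agb), tab)
    attr(out, "generator") <- list(coupling = coupling,
                                   coefficients = coefficients,
                                   cive_mu = cive_mu, cive_sd = cive_sd,
                                   noise_sigma = noise_sigma,
                                   multi_amp = multi_amp,
                                   backbone_range = rng, seed = seed)
    out
  })
}
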