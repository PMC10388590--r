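#' Read a field-plot table
#'
#' Field plots are 0.6 m x 0.6 m quadrats whose fresh-weight aboveground
#' biomass (AGB, g/m2) was measured by harvest. The CSV must carry columns
#' `plot_id, x, y, agb`; `edge` (m), `height` (m) and `role`
#' (`"modeling"`/`"validation"`) are optional.
#'
#' @param path CSV file path.
#' @return data.frame of validated plot records.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop("plot file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plots(df)
}

#' Validate a plot table
#'
#' @param df data.frame of plot records (see [read_plots()]).
#' @return the validated data.frame, with defaults filled in.
#' @export
validate_plots <- function(df) {
  if (nrow(df) == 0L) stop("no plots in table")
  need <- c("plot_id", "x", "y", "agb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"edge" %in% names(df)) df$edge <- 0.6
  if (!"height" %in% names(df)) df$height <- NA_real_
  if (!"role" %in% names(df)) df$role <- NA_character_
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$agb) |
                 df$agb < 0 | df$edge <= 0 |
                 (!is.na(df$height) & df$height < 0))
  if (length(bad))
    stop("invalid plot row(s) (need finite x/y, agb >= 0, edge > 0, ",
         "height >= 0): lines ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$plot_id))
    stop("duplicate plot_id(s): ",
         paste(unique(df$plot_id[duplicated(df$plot_id)]), collapse = ", "))
  okrole <- is.na(df$role) | df$role %in% c("modeling", "validation")
  if (!all(okrole))
    stop("role must be 'modeling', 'validation' or empty: lines ",
         paste(which(!okrole), collapse = ", "))
  df
}

#' Windowed mean of an index raster around a plot
#'
#' Mean of the `window` x `window` pixel block centred on the pixel whose
#' area contains the plot coordinate, excluding missing pixels. Blocks that
#' overhang the raster edge are truncated to the in-bounds part and flagged;
#' a block whose in-bounds part is more than `max_missing` nodata is flagged
#' missing.
#'
#' @param index single-band `agb_raster`.
#' @param plot one-row data.frame (or list) with `x`, `y` map coordinates.
#' @param window odd window size in pixels (default 5).
#' @param max_missing maximum tolerated nodata fraction in the in-bounds
#'   window (default 0.5).
#' @return list with `value`, `truncated`, `missing`, `n_valid`, `n_window`.
#' @export
extract_window_mean <- function(index, plot, window = 5L, max_missing = 0.5) {
  stopifnot(inherits(index, "agb_raster"), window %% 2 == 1, window >= 1)
  d <- dim(index$values)
  rc <- map_to_cell(index, plot$x, plot$y)
  if (rc[1] < 1 || rc[1] > d[1] || rc[2] < 1 || rc[2] > d[2])
    stop("plot ", if (!is.null(plot$plot_id)) plot$plot_id else "",
         " at (", plot$x, ", ", plot$y, ") falls outside the raster extent")
  h <- (window - 1L) %/% 2L
  rows <- (rc[1] - h):(rc[1] + h)
  cols <- (rc[2] - h):(rc[2] + h)
  truncated <- any(rows < 1 | rows > d[1] | cols < 1 | cols > d[2])
  rows <- rows[rows >= 1 & rows <= d[1]]
  cols <- cols[cols >= 1 & cols <= d[2]]
  blk <- band(index)[rows, cols, drop = FALSE]
  n_in <- length(blk)
  n_valid <- sum(is.finite(blk))
  missing <- (n_in - n_valid) / n_in > max_missing
  value <- if (n_valid > 0 && !missing) mean(blk[is.finite(blk)]) else NA_real_
  list(value = value, truncated = truncated, missing = missing || n_valid == 0,
       n_valid = n_valid, n_window = window^2)
}

#' Build the per-plot feature table
#'
#' One row per plot: measured AGB plus the windowed mean of every index
#' raster at the plot location. Plots whose window is missing-flagged for
#' any index (or which fall outside the raster) are excluded and reported
#' in the `"excluded"` attribute.
#'
#' @param indices named list of single-band `agb_raster`s on one shared grid.
#' @param plots validated plot data.frame (see [read_plots()]).
#' @param window odd window size in pixels (default 5).
#' @param max_missing per-window nodata tolerance (see
#'   [extract_window_mean()]).
#' @param drop_truncated exclude edge-truncated windows instead of flagging
#'   (default `FALSE`).
#' @return data.frame with columns `plot_id`, `role`, `agb`, then one column
#'   per index; attributes `"excluded"` (data.frame of plot_id + reason),
#'   `"truncated"` (plot_ids with any truncated window) and `"provenance"`.
#' @export
build_feature_table <- function(indices, plots, window = 5L,
                                max_missing = 0.5, drop_truncated = FALSE) {
  stopifnot(is.list(indices), length(indices) >= 1,
            !is.null(names(indices)))
  ref <- indices[[1]]
  for (nm in names(indices))
    if (!same_grid(indices[[nm]], ref))
      stop("index raster '", nm, "' is not on the shared grid")
  plots <- validate_plots(plots)
  if (nrow(plots) == 0L) {
    warning("no plots; returning empty feature table")
    return(plots)
  }
  vals <- matrix(NA_real_, nrow(plots), length(indices),
                 dimnames = list(NULL, names(indices)))
  reason <- rep(NA_character_, nrow(plots))
  trunc <- logical(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    for (j in seq_along(indices)) {
      w <- tryCatch(
        extract_window_mean(indices[[j]], plots[i, ], window, max_missing),
        error = function(e) conditionMessage(e))
      if (is.character(w)) { reason[i] <- "outside raster extent"; break }
      if (w$missing) {
        reason[i] <- paste0("window >", round(max_missing * 100),
                            "% nodata for ", names(indices)[j])
        break
      }
      if (w$truncated) trunc[i] <- TRUE
      vals[i, j] <- w$value
    }
  }
  if (drop_truncated)
    reason[trunc & is.na(reason)] <- "window truncated at raster edge"
  keep <- is.na(reason)
  out <- cbind(plots[keep, c("plot_id", "role", "agb"), drop = FALSE],
               as.data.frame(vals[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(plot_id = plots$plot_id[!keep],
                                      reason = reason[!keep])
  attr(out, "truncated") <- plots$plot_id[keep & trunc]
  attr(out, "provenance") <- list(window = window, max_missing = max_missing,
                                  gsd = ref$gsd, indices = names(indices))
  out
}

#' Split plots into modeling and validation sets
#'
#' Reproducibly partitions the plots, honouring any preassigned `role`
#' values and drawing only the unassigned ones at random so that
#' `n_modeling` plots end up in the modeling set.
#'
#' @param plots validated plot data.frame.
#' @param n_modeling number of modeling plots (default 30 of 38).
#' @param seed integer seed for the draw.
#' @return the data.frame with `role` filled for every row.
#' @export
split_samples <- function(plots, n_modeling = 30L, seed = 1L) {
  # works for full plot records and for bare feature tables alike
  if (!"role" %in% names(plots)) plots$role <- NA_character_
  if (all(c("x", "y", "agb") %in% names(plots)))
    plots <- validate_plots(plots)
  n <- nrow(plots)
  if (n_modeling >= n)
    stop("n_modeling (", n_modeling, ") must be < number of plots (", n, ")")
  pre_m <- sum(plots$role %in% "modeling")
  if (pre_m > n_modeling)
    stop("more plots preassigned to modeling (", pre_m,
         ") than n_modeling (", n_modeling, ")")
  open <- which(is.na(plots$role))
  need <- n_modeling - pre_m
  if (need > length(open))
    stop("not enough unassigned plots to reach n_modeling")
  pick <- with_seed(seed, sample(open, need))
  plots$role[pick] <- "modeling"
  plots$role[is.na(plots$role)] <- "validation"
  plots
}

#' Write / read a feature table with its provenance sidecar
#'
#' @param table feature table from [build_feature_table()].
#' @param path CSV path; a `.json` sidecar stores window/provenance.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  side <- list(provenance = attr(table, "provenance"),
               excluded = attr(table, "excluded"),
               truncated = attr(table, "truncated"))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    attr(out, "provenance") <- side$provenance
    attr(out, "excluded") <- side$excluded
    attr(out, "truncated") <- side$truncated
  }
  out
}
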