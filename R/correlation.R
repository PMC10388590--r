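#' Pearson correlation between AGB and every vegetation index
#'
#' Computes the product-moment correlation of measured AGB with each index
#' column of the feature table, with two-sided p-values from the
#' t-distribution on `n - 2` degrees of freedom, plus the full symmetric
#' correlation matrix over `{agb}` and the indices (for heat-map style
#' inspection of inter-index structure).
#'
#' @param table feature table (data.frame with `agb` and index columns).
#' @param rows which plots feed the correlation: `"modeling"` (default;
#'   keeps the validation set untouched) or `"all"`. Ignored when the table
#'   has no `role` column or no assigned roles.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, i.e. unadjusted significance).
#' @return object of class `agb_correlation`: list with `stats` (data.frame
#'   `index, r, p, n`), `matrix`, `rows_used`, `n_rows`.
#' @export
pearson_matrix <- function(table, rows = c("modeling", "all"),
                           adjust = "none") {
  rows <- match.arg(rows)
  idx_cols <- setdiff(names(table),
                      c("plot_id", "role", "agb", "x", "y", "edge", "height"))
  if (!"agb" %in% names(table)) stop("feature table lacks an 'agb' column")
  if (!length(idx_cols)) stop("feature table has no index columns")
  use <- table
  if (rows == "modeling" && "role" %in% names(table) &&
      any(table$role %in% "modeling"))
    use <- table[table$role %in% "modeling", , drop = FALSE]
  mat <- as.matrix(use[, c("agb", idx_cols), drop = FALSE])
  cc <- stats::complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 complete rows, have ", n)
  sds <- apply(mat, 2, stats::sd)
  cmat <- suppressWarnings(stats::cor(mat))
  diag(cmat) <- 1
  r <- cmat["agb", idx_cols]
  r[sds[idx_cols] == 0 | sds["agb"] == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  p <- stats::p.adjust(p, method = adjust)
  structure(list(
    stats = data.frame(index = idx_cols, r = unname(r), p = unname(p),
                       n = n, row.names = NULL),
    matrix = cmat, rows_used = rows, n_rows = n, adjust = adjust),
    class = "agb_correlation")
}

#' @export
print.agb_correlation <- function(x, ...) {
  cat(sprintf("<agb_correlation> AGB vs %d indices on %d %s plots\n",
              nrow(x$stats), x$n_rows, x$rows_used))
  s <- x$stats[order(-abs(x$stats$r)), ]
  s$r <- round(s$r, 3); s$p <- signif(s$p, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Apply the two index-selection rules
#'
#' Univariate models use indices whose absolute correlation with AGB is
#' strictly greater than `threshold_high`; the network uses all indices
#' significantly correlated with AGB (`p < alpha`). Both sets are ordered by
#' decreasing `|r|`.
#'
#' @param result an `agb_correlation`.
#' @param threshold_high absolute-correlation cut for univariate modeling
#'   (default 0.8; strict inequality).
#' @param alpha significance level for the network input set (default 0.05).
#' @return list with `univariate` and `bpnn` character vectors.
#' @export
select_indices <- function(result, threshold_high = 0.8, alpha = 0.05) {
  stopifnot(inherits(result, "agb_correlation"))
  s <- result$stats[!is.na(result$stats$r), ]
  s <- s[order(-abs(s$r)), ]
  uni <- s$index[abs(s$r) > threshold_high]
  bp <- s$index[s$p < alpha]
  if (!length(uni))
    warning("no index exceeds |r| > ", threshold_high,
            "; univariate selection is empty")
  if (!length(bp))
    warning("no index is significant at alpha = ", alpha,
            "; network selection is empty")
  list(univariate = uni, bpnn = bp)
}
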