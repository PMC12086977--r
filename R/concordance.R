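# Rank-agreement statistics: Kendall's coefficient of concordance across
# blocks (e.g. the 12 treatment combinations ranked over removal dates or
# mesh sizes) and Spearman rank correlation.

#' Kendall's coefficient of concordance (W)
#'
#' Ranks items within each block (rows = blocks, columns = items; mid-ranks
#' for ties) and measures agreement of the orderings: W = 1 is complete
#' agreement among blocks, W = 0 no agreement. With tie correction,
#' `W = 12 S / (m^2 (n^3 - n) - m * sum(T))` where S is the sum of squared
#' deviations of item rank-sums from their mean, m the number of blocks, n the
#' number of items, and `T = sum(t^3 - t)` over tie groups of each block. The
#' chi-square approximation `m (n - 1) W` on `n - 1` df is reported.
#'
#' @param x Numeric matrix (or data frame) of measurements, blocks in rows and
#'   items in columns; at least 2 of each.
#' @param tie_correction Apply the tie term (default `TRUE`).
#' @param direction `"ascending"` ranks the smallest value 1 (so the fastest
#'   decay, i.e. most negative k or lowest mass remaining, ranks first);
#'   `"descending"` reverses this. W itself is direction-invariant; the choice
#'   is recorded with the returned rank matrix.
#' @return A `kendall_w` list: `w`, `chi_squared`, `df`, `p_value`,
#'   `n_blocks`, `n_items`, `ranks`, `direction`.
#' @export
#' @examples
#' kendalls_w(rbind(c(1, 2, 3), c(10, 20, 30)))$w  # 1: perfect agreement
kendalls_w <- function(x, tie_correction = TRUE,
                       direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain("x must be a finite numeric matrix")
  }
  m <- nrow(x)
  n <- ncol(x)
  if (n < 2L) stop_domain("need at least 2 items to rank")
  if (m < 2L) stop_domain("need at least 2 blocks")
  if (direction == "descending") x <- -x
  ranks <- t(apply(x, 1L, rank))
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - mean(rank_sums))^2)
  tie_term <- 0
  if (tie_correction) {
    tie_term <- sum(apply(ranks, 1L, function(r) {
      t <- table(r)
      sum(t^3 - t)
    }))
  }
  denom <- m^2 * (n^3 - n) - m * tie_term
  w <- if (denom <= 0) {
    # every block is entirely tied; no ordering information
    0
  } else {
    12 * s / denom
  }
  chi2 <- m * (n - 1) * w
  df <- n - 1
  structure(list(
    w = w, chi_squared = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    n_blocks = m, n_items = n, ranks = ranks, direction = direction,
    tie_correction = tie_correction
  ), class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf(
    "Kendall's W = %.3f (%d blocks x %d items); chi-sq = %.2f, df = %d, p = %.3g\n",
    x$w, x$n_blocks, x$n_items, x$chi_squared, x$df, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranked values, in [-1, 1].
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return Correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 3L) stop_domain("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_domain("x and y must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("rank correlation is undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Block table of cell means for concordance analysis
#'
#' Builds the blocks-by-items matrix of mean values per treatment cell
#' (blocks, canonical order) by an item factor such as removal day or mesh
#' size.
#'
#' @param bags Bag table.
#' @param values Numeric vector aligned with `bags` (e.g. instantaneous k or
#'   percent remaining).
#' @param item Name of the bag column defining the items (`"removal_day"` or
#'   `"mesh"`).
#' @return Numeric matrix, one row per treatment cell present, labelled
#'   columns.
#' @export
rank_block_table <- function(bags, values, item = "removal_day") {
  if (!item %in% names(bags)) stop_domain("unknown item column: ", item)
  cellv <- cell_label(bags$proliferation, bags$exclusion, bags$species)
  cells <- treatment_cells()$cell
  cells <- cells[cells %in% cellv]
  items <- sort(unique(bags[[item]]))
  m <- matrix(NA_real_, nrow = length(cells), ncol = length(items),
              dimnames = list(cells, as.character(items)))
  for (i in seq_along(cells)) {
    for (j in seq_along(items)) {
      sel <- cellv == cells[i] & bags[[item]] == items[j]
      if (any(sel)) m[i, j] <- mean(values[sel])
    }
  }
  if (any(is.na(m))) stop_domain("block table is not rectangular: empty cells")
  m
}
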