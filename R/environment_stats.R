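# Plot-level environmental summaries and group-difference tests: moisture-grid
# statistics, basal-area-weighted shade tolerance, compositional (clr)
# transforms, a one-way Euclidean PERMANOVA, and simple covariate arithmetic.

#' Mean, SD and CV% of a set of grid readings
#'
#' Sample SD (n - 1 denominator); `CV% = 100 * sd / mean`. CV% is
#' scale-invariant.
#'
#' @param node_values At least 2 strictly positive readings.
#' @return List `mean`, `sd`, `cv_percent`.
#' @export
#' @examples
#' grid_summary(c(8, 12))  # mean 10, CV ~28.3%
grid_summary <- function(node_values) {
  if (length(node_values) < 2L) stop_domain("need at least 2 readings")
  if (any(!is.finite(node_values)) || any(node_values <= 0)) {
    stop_domain("readings must be > 0")
  }
  m <- mean(node_values)
  s <- stats::sd(node_values)
  list(mean = m, sd = s, cv_percent = 100 * s / m)
}

#' Basal-area-weighted shade-tolerance index
#'
#' Averages ordinal shade-tolerance ratings (1 = most tolerant) of the canopy
#' species of a plot, each weighted by that species' basal area. Bounded by
#' the minimum and maximum ratings present.
#'
#' @param basal_area Basal areas (m^2 ha^-1), >= 0, total > 0.
#' @param rating Shade-tolerance ratings aligned with `basal_area`.
#' @return Weighted mean rating.
#' @export
weighted_shade_tolerance <- function(basal_area, rating) {
  if (length(basal_area) != length(rating)) {
    stop_domain("basal_area and rating must be aligned")
  }
  if (any(!is.finite(basal_area)) || any(basal_area < 0)) {
    stop_domain("basal areas must be >= 0")
  }
  if (sum(basal_area) <= 0) stop_domain("total basal area must be > 0")
  if (any(basal_area > 0 & !is.finite(rating))) {
    stop_domain("every species with positive basal area needs a rating")
  }
  sum(basal_area * rating) / sum(basal_area)
}

#' Centered log-ratio transform of a composition
#'
#' Maps strictly positive parts of a whole (e.g. sand/silt/clay percentages)
#' into Euclidean space: component i is `ln(x_i / geometric mean)`. Outputs
#' sum to zero and are invariant to rescaling of the whole. No
#' zero-replacement is performed.
#'
#' @param x Strictly positive parts.
#' @return Numeric vector summing to 0.
#' @export
#' @examples
#' clr_transform(c(58.4, 38.6, 3.0))
clr_transform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("all parts must be > 0 (no zero-replacement is performed)")
  }
  log(x) - mean(log(x))
}

#' One-way permutation group test (PERMANOVA) on Euclidean distances
#'
#' Partitions squared Euclidean distances into among- and within-group
#' components and forms the pseudo-F
#' `(SS_A / (a - 1)) / (SS_W / (N - a))`. The p-value uses the add-one
#' permutation convention `(#{F* >= F} + 1) / (n_permutations + 1)`. In the
#' univariate case the pseudo-F equals the classical one-way ANOVA F.
#'
#' @param x Numeric matrix or data frame of rows (observations), or a vector
#'   for the univariate case.
#' @param groups Group labels; at least 2 groups with at least 2 rows each.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Optional seed making the p-value reproducible.
#' @return A `permutation_test` list: `pseudo_f`, `p_value`, df, sums of
#'   squares, `n_permutations`.
#' @export
permutation_group_test <- function(x, groups, n_permutations = 9999,
                                   seed = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain("x must be finite numeric")
  }
  groups <- as.factor(groups)
  if (length(groups) != nrow(x)) stop_domain("groups must match rows of x")
  if (nlevels(droplevels(groups)) < 2L) stop_domain("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop_domain("every group needs at least 2 rows")
  }
  n <- nrow(x)
  a <- nlevels(groups)
  d2 <- as.matrix(stats::dist(x))^2
  ss_total <- sum(d2) / (2 * n)
  ss_within_of <- function(g) {
    sw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) f_of(sample(groups)), numeric(1))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  structure(list(
    pseudo_f = f_obs, p_value = p, df_among = a - 1, df_within = n - a,
    ss_among = ss_total - ss_within_of(groups),
    ss_within = ss_within_of(groups), ss_total = ss_total,
    n_permutations = n_permutations
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation group test: pseudo-F(%d, %d) = %.3f, p = %.4f (%d permutations)\n",
    x$df_among, x$df_within, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-group means and sample SDs
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`; every group non-empty.
#' @return Data frame `group`, `n`, `mean`, `sd` (SD is `NA`, with a warning,
#'   for single-element groups).
#' @export
group_means <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop_domain("values and groups must be aligned")
  }
  if (any(!is.finite(values))) stop_domain("values must be finite")
  groups <- as.factor(groups)
  if (any(tabulate(groups, nlevels(groups)) == 0L)) {
    stop_domain("empty group")
  }
  out <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    stringsAsFactors = FALSE
  )
  if (any(out$n == 1L)) {
    warning("SD undefined for single-element group(s): ",
            paste(out$group[out$n == 1L], collapse = ", "), call. = FALSE)
  }
  out
}

#' Monthly soil-moisture gain or loss
#'
#' Change in volumetric soil water content scaled to a 30-day month:
#' `((end - start) / days) * 30`.
#'
#' @param start_swc,end_swc SWC at the start and end of the period (% v/v or
#'   cm^3 cm^-3; units are preserved).
#' @param days Length of the period in days (> 0).
#' @return Gain (+) or loss (-) per 30 days.
#' @export
moisture_delta <- function(start_swc, end_swc, days) {
  if (any(!is.finite(days)) || any(days <= 0)) stop_domain("days must be > 0")
  ((end_swc - start_swc) / days) * 30
}
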