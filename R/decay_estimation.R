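# Decay-rate estimation: per-bag instantaneous k and the multi-group
# linearized negative-exponential (Olson) regression
#   ln M_t = ln M_0 - k t
# extended to one slope per treatment cell with a single shared intercept.

#' Instantaneous per-bag decay rate
#'
#' `(ln(percent remaining) - ln(100)) / year_fraction`, in year^-1; zero for an
#' intact bag and negative for any mass loss.
#'
#' @param percent_remaining Percent of initial mass remaining, in (0, 100].
#' @param yf Elapsed time as a year fraction (> 0).
#' @return Decay rate(s), year^-1 (<= 0).
#' @export
#' @examples
#' instantaneous_k(75.6, 0.2466)  # about -1.134
instantaneous_k <- function(percent_remaining, yf) {
  if (any(!is.finite(percent_remaining)) || any(percent_remaining <= 0)) {
    stop_domain("percent_remaining must be in (0, 100]")
  }
  if (any(percent_remaining > 100 + 1e-9)) {
    stop_domain("percent_remaining must be in (0, 100]")
  }
  if (any(!is.finite(yf)) || any(yf <= 0)) {
    stop_domain("year fraction must be > 0")
  }
  (log(percent_remaining) - log(100)) / yf
}

#' Per-bag instantaneous decay rates for a bag table
#'
#' Adds percent remaining, year fraction, the whole-bag instantaneous k, and
#' (for mixed bags) the per-species rates computed from the 1.5 g component
#' initial masses.
#'
#' @param bags Validated bag table.
#' @return `bags` with columns `percent_remaining`, `year_fraction`, `k`,
#'   `maple_k`, `beech_k` appended (the last two `NA` for monospecific bags).
#' @export
bag_instantaneous_k <- function(bags) {
  validate_bag_table(bags, expected_initial = NULL)
  bags$percent_remaining <- percent_remaining(bags)
  bags$year_fraction <- year_fraction(bags$removal_day)
  bags$k <- instantaneous_k(bags$percent_remaining, bags$year_fraction)
  bags$maple_k <- NA_real_
  bags$beech_k <- NA_real_
  mx <- bags$species == "mixed"
  if (any(mx)) {
    ks <- per_species_mixed_k(bags$maple_final_mass_g[mx],
                              bags$beech_final_mass_g[mx],
                              bags$year_fraction[mx])
    bags$maple_k[mx] <- ks$maple_k
    bags$beech_k[mx] <- ks$beech_k
  }
  bags
}

resolve_time <- function(bags, time_basis, gdd = NULL) {
  if (time_basis == "years") return(year_fraction(bags$removal_day))
  if (is.null(gdd)) stop_domain("time_basis = 'gdd' requires a gdd table")
  if (!all(c("day", "cum_gdd") %in% names(gdd))) {
    stop_domain("gdd table must have columns 'day' and 'cum_gdd'")
  }
  if ("plot" %in% names(gdd)) {
    key <- paste(bags$plot, bags$removal_day)
    idx <- match(key, paste(gdd$plot, gdd$day))
  } else {
    idx <- match(bags$removal_day, gdd$day)
  }
  if (any(is.na(idx))) {
    stop_domain("gdd table does not cover every removal day",
                if ("plot" %in% names(gdd)) " and plot" else "")
  }
  gdd$cum_gdd[idx]
}

#' Design matrix of the multi-group decay regression
#'
#' Response is `ln(percent remaining)`. The design has one shared intercept
#' column of ones and one predictor column per treatment cell present in the
#' data, where column `i` equals the elapsed time for bags in cell `i` and 0
#' elsewhere. Columns follow the canonical [treatment_cells()] ordering, so on
#' the full design the matrix has 13 columns of full rank.
#'
#' @param bags Validated bag table.
#' @param time_basis `"years"` (year fractions) or `"gdd"` (cumulative growing
#'   degree-days at each removal day).
#' @param gdd Optional degree-day table (`day`, `cum_gdd`, optionally `plot`)
#'   required when `time_basis = "gdd"`.
#' @return List with the model matrix `X`, response `y`, time vector `time`,
#'   and the `cells` table (canonical order) of the columns.
#' @export
build_design_matrix <- function(bags, time_basis = c("years", "gdd"),
                                gdd = NULL) {
  time_basis <- match.arg(time_basis)
  validate_bag_table(bags, expected_initial = NULL)
  tvec <- resolve_time(bags, time_basis, gdd)
  cells <- treatment_cells()
  bag_cell <- cell_label(bags$proliferation, bags$exclusion, bags$species)
  present <- cells[cells$cell %in% bag_cell, , drop = FALSE]
  X <- matrix(0, nrow = nrow(bags), ncol = 1L + nrow(present),
              dimnames = list(NULL, c("intercept", present$cell)))
  X[, "intercept"] <- 1
  for (j in seq_len(nrow(present))) {
    in_cell <- bag_cell == present$cell[j]
    X[in_cell, j + 1L] <- tvec[in_cell]
  }
  list(X = X, y = log(percent_remaining(bags)), time = tvec, cells = present)
}

#' Fit the multi-group linearized decay model
#'
#' Ordinary least squares on the design of [build_design_matrix()]: a single
#' shared intercept (near `ln(100)`) and one slope (k, year^-1, negative for
#' mass loss) per treatment cell, with t-based 95% confidence intervals.
#' Optional plot-level covariates enter jointly as additional columns and are
#' reported with their own intervals.
#'
#' @inheritParams build_design_matrix
#' @param covariates Optional data frame of plot-level covariates: a `plot`
#'   column plus numeric columns, joined to bags by plot.
#' @param conf_level Confidence level for all intervals (default 0.95).
#' @param se_type `"hc3"` (default) uses heteroscedasticity-robust HC3
#'   standard errors: litterbag residual variance on the ln scale grows with
#'   elapsed time and differs between moisture regimes, so the pooled
#'   homoscedastic variance misstates per-cell uncertainty. `"classical"`
#'   gives the ordinary pooled OLS errors.
#' @return A `decay_fit` object: `intercept` (estimate/SE/bounds), `slopes`
#'   (one row per cell: estimate, SE, lower, upper), `covariates` (or `NULL`),
#'   `r_squared`, `adj_r_squared`, `n`, `time_basis`, and the underlying `lm`
#'   fit.
#' @export
#' @examples
#' bags <- generate_bags(synthetic_config(ln_noise_sd = 0, seed = 1))
#' fit <- fit_multigroup(bags)
#' fit$slopes$estimate  # the configured true slopes, exactly
fit_multigroup <- function(bags, time_basis = c("years", "gdd"), gdd = NULL,
                           covariates = NULL, conf_level = 0.95,
                           se_type = c("hc3", "classical")) {
  time_basis <- match.arg(time_basis)
  se_type <- match.arg(se_type)
  d <- build_design_matrix(bags, time_basis, gdd)
  bag_cell <- cell_label(bags$proliferation, bags$exclusion, bags$species)
  for (cl in d$cells$cell) {
    if (length(unique(d$time[bag_cell == cl])) < 2L) {
      stop_domain("cell ", cl,
                  " is observed at fewer than 2 distinct time points; ",
                  "its slope is not estimable with a shared intercept")
    }
  }
  X <- d$X
  if (!is.null(covariates)) {
    if (!"plot" %in% names(covariates)) {
      stop_domain("covariate table must have a 'plot' column")
    }
    idx <- match(bags$plot, covariates$plot)
    if (any(is.na(idx))) stop_domain("covariate table does not cover every plot")
    cov_cols <- setdiff(names(covariates), "plot")
    C <- as.matrix(covariates[idx, cov_cols, drop = FALSE])
    if (!is.numeric(C)) stop_domain("covariate columns must be numeric")
    colnames(C) <- cov_cols
    X <- cbind(X, C)
  }
  df_fit <- data.frame(.y = d$y, X, check.names = FALSE)
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- stats::lm(form, data = df_fit)
  est <- stats::coef(fit)
  if (se_type == "hc3") {
    Xm <- stats::model.matrix(fit)
    e <- stats::residuals(fit)
    h <- pmin(stats::hatvalues(fit), 1 - 1e-8)
    xtxi <- chol2inv(qr.R(qr(Xm)))
    meat <- crossprod(Xm, Xm * (e^2 / (1 - h)^2))
    vc <- xtxi %*% meat %*% xtxi
    se <- stats::setNames(sqrt(pmax(diag(vc), 0)), colnames(Xm))
  } else {
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  }
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  ci <- cbind(est - tcrit * se, est + tcrit * se)
  strip <- function(x) gsub("`", "", x, fixed = TRUE)
  names(est) <- strip(names(est))
  names(se) <- strip(names(se))
  rownames(ci) <- strip(names(est))
  nm <- function(x) x

  slopes <- d$cells
  sl_nm <- nm(slopes$cell)
  slopes$estimate <- unname(est[sl_nm])
  slopes$se <- unname(se[sl_nm])
  slopes$lower <- unname(ci[sl_nm, 1])
  slopes$upper <- unname(ci[sl_nm, 2])

  covs <- NULL
  cov_nm <- setdiff(colnames(X), c("intercept", d$cells$cell))
  if (length(cov_nm)) {
    covs <- data.frame(
      covariate = cov_nm,
      estimate = unname(est[nm(cov_nm)]), se = unname(se[nm(cov_nm)]),
      lower = unname(ci[nm(cov_nm), 1]), upper = unname(ci[nm(cov_nm), 2]),
      stringsAsFactors = FALSE
    )
  }

  # centered R^2 (summary.lm would report the uncentered version for a
  # no-implicit-intercept fit even though the design carries an explicit one)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((d$y - mean(d$y))^2)
  n <- length(d$y)
  p <- length(est)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)

  structure(list(
    intercept = list(estimate = unname(est["intercept"]),
                     se = unname(se["intercept"]),
                     lower = unname(ci["intercept", 1]),
                     upper = unname(ci["intercept", 2])),
    slopes = slopes, covariates = covs,
    r_squared = r2, adj_r_squared = adj,
    n = n, time_basis = time_basis, conf_level = conf_level, lm_fit = fit
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Multi-group linearized decay fit (", x$time_basis, " basis)\n", sep = "")
  cat(sprintf("  n = %d bags; shared intercept = %.3f (ln%%; %.1f%% remaining)\n",
              x$n, x$intercept$estimate, exp(x$intercept$estimate)))
  cat(sprintf("  R-squared = %.3f (adjusted %.3f)\n",
              x$r_squared, x$adj_r_squared))
  cat("  Slopes (k, per time unit):\n")
  sl <- x$slopes
  for (i in seq_len(nrow(sl))) {
    cat(sprintf("    %-14s %8.3f  [%8.3f, %8.3f]\n",
                sl$cell[i], sl$estimate[i], sl$lower[i], sl$upper[i]))
  }
  if (!is.null(x$covariates)) {
    cat("  Covariates:\n")
    cv <- x$covariates
    for (i in seq_len(nrow(cv))) {
      cat(sprintf("    %-20s %8.4f  [%8.4f, %8.4f]\n",
                  cv$covariate[i], cv$estimate[i], cv$lower[i], cv$upper[i]))
    }
  }
  invisible(x)
}

#' Slope magnitudes of a decay fit
#'
#' Slopes are stored with the negative mass-loss sign; ratio arithmetic uses
#' magnitudes.
#' @param fit A `decay_fit`.
#' @return Named numeric vector of |k| per cell.
#' @export
slope_magnitudes <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  stats::setNames(abs(fit$slopes$estimate), fit$slopes$cell)
}

#' Accumulate growing degree-days from a temperature log
#'
#' Daily contribution is `max(0, daily mean - base)` computed from the
#' sub-daily readings; the cumulative sum is non-decreasing and days with mean
#' at or below the base contribute nothing. Days with logging gaps (fewer
#' readings than the modal daily count) are excluded with a warning.
#'
#' @param log_df Temperature log with columns `day` and `temp_c` (as produced
#'   by [generate_temperature_log()]).
#' @param base Base temperature in deg C (default 5).
#' @return Data frame `day`, `daily_gdd`, `cum_gdd`.
#' @export
#' @examples
#' tl <- generate_temperature_log(1, 10, profile = 15)
#' tail(accumulate_gdd(tl)$cum_gdd, 1)  # 100 degree-days
accumulate_gdd <- function(log_df, base = 5) {
  if (!all(c("day", "temp_c") %in% names(log_df))) {
    stop_domain("temperature log must have columns 'day' and 'temp_c'")
  }
  if (nrow(log_df) == 0L) stop_domain("temperature log is empty")
  counts <- table(log_df$day)
  expected <- as.integer(stats::median(as.integer(counts)))
  gap_days <- names(counts)[as.integer(counts) < expected]
  if (length(gap_days)) {
    warning("excluding day(s) with logging gaps: ",
            paste(gap_days, collapse = ", "), call. = FALSE)
    log_df <- log_df[!(as.character(log_df$day) %in% gap_days), , drop = FALSE]
  }
  means <- tapply(log_df$temp_c, log_df$day, mean)
  days <- as.integer(names(means))
  ord <- order(days)
  daily <- pmax(0, as.numeric(means)[ord] - base)
  data.frame(day = days[ord], daily_gdd = daily, cum_gdd = cumsum(daily))
}
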