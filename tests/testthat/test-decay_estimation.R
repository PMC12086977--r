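test_that("instantaneous_k matches the closed form", {
  expect_equal(instantaneous_k(100, 0.2466), 0)
  expect_equal(round(instantaneous_k(75.6, 0.2466), 3), -1.134)
  expect_equal(instantaneous_k(92.9, 0.0822), log(0.929) / 0.0822)
  expect_true(all(instantaneous_k(c(10, 50, 99.9), 0.1644) < 0))
  expect_error(instantaneous_k(0, 0.2466), "\\(0, 100\\]")
  expect_error(instantaneous_k(-5, 0.2466), "\\(0, 100\\]")
  expect_error(instantaneous_k(101, 0.2466), "\\(0, 100\\]")
  expect_error(instantaneous_k(50, 0), "> 0")
})

test_that("design matrix has a shared intercept and one time column per cell", {
  bags <- generate_bags(synthetic_config(seed = 1))
  d <- build_design_matrix(bags)
  expect_equal(ncol(d$X), 13L)
  expect_equal(qr(d$X)$rank, 13L)
  expect_identical(colnames(d$X), c("intercept", treatment_cells()$cell))
  expect_true(all(d$X[, "intercept"] == 1))
  # each row has exactly one non-zero cell entry, equal to its year fraction
  cell_part <- d$X[, -1]
  expect_true(all(rowSums(cell_part != 0) == 1))
  expect_equal(rowSums(cell_part), year_fraction(bags$removal_day))

  one <- make_bag_row(proliferation = "Yes", exclusion = "Yes",
                      species = "maple", removal_day = 90L, final = 2.5)
  d1 <- build_design_matrix(one)
  expect_equal(unname(d1$X[1, ]), c(1, 90 / 365))

  expect_error(build_design_matrix(small_bag_table()[0, ]), "0 rows")
})

test_that("noiseless fit returns the true slopes and ln(100) intercept", {
  cfg <- synthetic_config(ln_noise_sd = 0, seed = 4)
  fit <- suppressWarnings(fit_multigroup(generate_bags(cfg)))
  truth <- default_k_table()
  expect_equal(fit$slopes$estimate,
               truth$k[match(fit$slopes$cell, truth$cell)],
               tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, log(100), tolerance = 1e-10)
  expect_true(all(fit$slopes$estimate < 0))
  expect_true(all(fit$slopes$lower <= fit$slopes$estimate &
                    fit$slopes$estimate <= fit$slopes$upper))
})

test_that("single cell at a single time equals instantaneous k of the mean", {
  # equivalence oracle: ln(mean percent) fitted through ln(100) at one time
  pcts <- c(80, 82, 78, 81)
  bags <- do.call(rbind, lapply(seq_along(pcts), function(i)
    make_bag_row(replicate = i, removal_day = 90L, final = 3 * pcts[i] / 100)))
  # a one-cell one-time design is rejected (slope and intercept confounded)
  expect_error(fit_multigroup(bags), "fewer than 2 distinct time")
  # anchoring the same cell at a second time point, the noiseless slope
  # equals instantaneous k exactly
  pct2 <- 100 * exp(log(pcts[1] / 100) / 0.2466 * 0.0822)
  bags2 <- rbind(
    make_bag_row(removal_day = 90L, final = 3 * pcts[1] / 100),
    make_bag_row(removal_day = 30L, final = 3 * pct2 / 100)
  )
  fit <- suppressWarnings(fit_multigroup(bags2))
  expect_equal(fit$slopes$estimate,
               instantaneous_k(pcts[1], year_fraction(90)), tolerance = 1e-9)
})

test_that("r-squared is the centered fraction of variance explained", {
  bags <- generate_bags(synthetic_config(seed = 6))
  fit <- fit_multigroup(bags)
  y <- log(percent_remaining(bags))
  rss <- sum(residuals(fit$lm_fit)^2)
  expect_equal(fit$r_squared, 1 - rss / sum((y - mean(y))^2))
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_lt(fit$adj_r_squared, fit$r_squared)
})

test_that("plot-level covariates are estimated jointly with intervals", {
  bags <- generate_bags(synthetic_config(seed = 8))
  plots <- unique(bags[, "plot", drop = FALSE])
  set.seed(42)
  plots$swc <- rnorm(nrow(plots), 12, 4)
  fit <- fit_multigroup(bags, covariates = plots)
  expect_equal(nrow(fit$covariates), 1L)
  expect_identical(fit$covariates$covariate, "swc")
  expect_true(fit$covariates$lower < fit$covariates$estimate &
                fit$covariates$estimate < fit$covariates$upper)
  expect_error(fit_multigroup(bags, covariates = data.frame(swc = 1)),
               "plot")
})

test_that("GDD accumulates daily mean excess above the base", {
  tl <- generate_temperature_log(1, 10, profile = 15)
  g <- accumulate_gdd(tl, base = 5)
  expect_equal(g$daily_gdd, rep(10, 10))
  expect_equal(tail(g$cum_gdd, 1), 100)
  expect_true(all(diff(g$cum_gdd) >= 0))

  cold <- generate_temperature_log(1, 10, profile = 4)
  expect_equal(tail(accumulate_gdd(cold)$cum_gdd, 1), 0)

  alt <- generate_temperature_log(1, 10, profile = rep(c(10, 0), 5))
  expect_equal(tail(accumulate_gdd(alt)$cum_gdd, 1), 25)

  # a day with a logging gap is excluded with a warning
  gap <- tl[-(1:10), ]
  expect_warning(gg <- accumulate_gdd(gap), "gap")
  expect_equal(nrow(gg), 9L)
})

test_that("constant temperature makes the GDD fit a rescaled years fit", {
  bags <- generate_bags(synthetic_config(seed = 9))
  temp <- 15
  gdd_per_day <- temp - 5
  tl <- generate_temperature_log(1, 90, profile = temp)
  gdd <- accumulate_gdd(tl)
  fit_y <- fit_multigroup(bags, time_basis = "years")
  fit_g <- fit_multigroup(bags, time_basis = "gdd", gdd = gdd)
  # GDD(d) = gdd_per_day * d = gdd_per_day * 365 * yearfrac, so slopes rescale
  # by exactly 1 / (gdd_per_day * 365)
  expect_equal(fit_g$slopes$estimate * gdd_per_day * 365,
               fit_y$slopes$estimate, tolerance = 1e-9)
  expect_equal(fit_g$r_squared, fit_y$r_squared, tolerance = 1e-12)
  expect_error(fit_multigroup(bags, time_basis = "gdd"), "gdd table")
})

test_that("bag_instantaneous_k adds whole-bag and per-species rates", {
  bags <- generate_bags(synthetic_config(ln_noise_sd = 0, seed = 10))
  inst <- bag_instantaneous_k(bags)
  expect_true(all(inst$k <= 0))
  mx <- inst$species == "mixed"
  expect_true(all(is.finite(inst$maple_k[mx])))
  expect_true(all(is.na(inst$maple_k[!mx])))
  # noiseless components decay at the mixed-cell rate
  truth <- default_k_table()
  cellk <- truth$k[match(cell_label(inst$proliferation, inst$exclusion,
                                    inst$species), truth$cell)]
  expect_equal(inst$maple_k[mx], cellk[mx], tolerance = 1e-9)
})
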