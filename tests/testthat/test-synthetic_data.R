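test_that("noiseless generation follows the closed form exactly", {
  tk <- treatment_cells()
  tk$k <- -1
  cfg <- synthetic_config(true_k = tk, ln_noise_sd = 0, seed = 1)
  bags <- generate_bags(cfg)
  at90 <- bags[bags$removal_day == 90, ]
  expect_equal(percent_remaining(at90),
               rep(100 * exp(-0.2466), nrow(at90)), tolerance = 1e-4)
  # exact closed form at the unrounded year fraction
  expect_equal(percent_remaining(at90),
               rep(100 * exp(-90 / 365), nrow(at90)), tolerance = 1e-12)
})

test_that("the full factorial design yields 648 bags, dropout removes a site", {
  bags <- generate_bags(synthetic_config(seed = 2))
  expect_equal(nrow(bags), 648L)
  expect_equal(length(unique(bags$site)), 6L)
  expect_equal(length(unique(bags$plot)), 12L)
  counts <- table(cell_label(bags$proliferation, bags$exclusion, bags$species))
  expect_equal(length(counts), 12L)
  expect_true(all(counts == 54L))

  dropped <- generate_bags(synthetic_config(seed = 2, site_dropout = "site3"))
  expect_equal(nrow(dropped), 540L)
  expect_equal(length(unique(dropped$site)), 5L)
  expect_false("site3" %in% dropped$site)
  expect_error(generate_bags(synthetic_config(site_dropout = "nowhere")),
               "unknown site")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_bags(synthetic_config(seed = 99))
  b <- generate_bags(synthetic_config(seed = 99))
  expect_identical(a, b)
  c <- generate_bags(synthetic_config(seed = 100))
  expect_false(identical(a$final_mass_g, c$final_mass_g))
})

test_that("percent remaining stays in (0, 100] and components sum exactly", {
  cfg <- synthetic_config(ln_noise_sd = 0.5, seed = 11)
  bags <- generate_bags(cfg)
  pct <- percent_remaining(bags)
  expect_true(all(pct > 0))
  expect_true(all(pct <= 100))
  mx <- bags$species == "mixed"
  expect_equal(bags$maple_final_mass_g[mx] + bags$beech_final_mass_g[mx],
               bags$final_mass_g[mx], tolerance = 1e-12)
})

test_that("config validation rejects degenerate parameters", {
  tk <- treatment_cells()
  tk$k <- 0.5  # positive sign violates the mass-loss convention
  expect_error(synthetic_config(true_k = tk), "negative")
  tk$k <- 0
  expect_error(synthetic_config(true_k = tk), "non-zero")
  expect_error(synthetic_config(ln_noise_sd = -0.1), ">= 0")
  expect_error(synthetic_config(removal_days = c(0, 30)), "> 0")
  expect_error(synthetic_config(mesh_effects = c(L = 1, M = 0, S = 1)), "> 0")
})

test_that("mesh effects scale the effective decay rate", {
  tk <- treatment_cells()
  tk$k <- -1
  cfg <- synthetic_config(true_k = tk, ln_noise_sd = 0,
                          mesh_effects = c(L = 2, M = 1, S = 0.5), seed = 3)
  bags <- generate_bags(cfg)
  k <- bag_instantaneous_k(bags)
  kL <- mean(k$k[k$mesh == "L"])
  kM <- mean(k$k[k$mesh == "M"])
  kS <- mean(k$k[k$mesh == "S"])
  expect_equal(kL / kM, 2, tolerance = 1e-9)
  expect_equal(kS / kM, 0.5, tolerance = 1e-9)
})

test_that("moisture grids hit the configured mean and CV", {
  cfg <- synthetic_environment_config()
  # degenerate CV: all 42 nodes equal the configured mean
  cfg0 <- synthetic_environment_config(
    swc_cv_by_exclusion = c(Yes = 0, No = 0))
  g0 <- generate_moisture_grid(cfg0, "No", seed = 1)
  expect_equal(dim(g0$values), c(6L, 7L))
  expect_equal(as.numeric(g0$values), rep(15.57, 42))
  expect_equal(g0$cv_percent, 0)

  # determinism
  g1 <- generate_moisture_grid(cfg, "Yes", seed = 5)
  g2 <- generate_moisture_grid(cfg, "Yes", seed = 5)
  expect_identical(g1$values, g2$values)

  # law of large numbers: node-level mean and CV approach the target
  nodes <- unlist(lapply(1:250, function(i)
    as.numeric(generate_moisture_grid(cfg, "No", seed = i)$values)))
  expect_lt(abs(mean(nodes) - 15.57), 0.01 * 15.57)
  expect_lt(abs(100 * sd(nodes) / mean(nodes) - 24.40), 1.5)
})

test_that("temperature logs have exact daily means and reading counts", {
  tl <- generate_temperature_log(1, 10, profile = 15)
  expect_equal(nrow(tl), 960L)  # 96 readings/day * 10 days
  expect_equal(as.numeric(tapply(tl$temp_c, tl$day, mean)), rep(15, 10))

  # sinusoidal diurnal cycle integrates to zero over each day
  tls <- generate_temperature_log(1, 5, profile = 15, diurnal_amplitude = 8)
  expect_equal(as.numeric(tapply(tls$temp_c, tls$day, mean)), rep(15, 5),
               tolerance = 1e-12)
  expect_gt(max(tls$temp_c), 20)

  # degenerate interval: one reading per day
  tl1 <- generate_temperature_log(1, 7, profile = 1:7,
                                  interval_minutes = 1440)
  expect_equal(nrow(tl1), 7L)
  expect_equal(tl1$temp_c, 1:7)

  expect_error(generate_temperature_log(1, 5, profile = numeric(0)),
               "non-empty")
})

test_that("fitting the generator output recovers the generator parameters", {
  # noiseless: exact to numerical precision (checked tightly in acceptance);
  # here, with noise, estimates stay within their own intervals most of the
  # time over a handful of seeds
  truth <- default_k_table()
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    bags <- generate_bags(synthetic_config(ln_noise_sd = 0.1, seed = s))
    fit <- fit_multigroup(bags)
    tk <- truth$k[match(fit$slopes$cell, truth$cell)]
    hits <- hits + sum(fit$slopes$lower <= tk & tk <= fit$slopes$upper)
    total <- total + nrow(fit$slopes)
  }
  expect_gt(hits / total, 0.8)
})
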