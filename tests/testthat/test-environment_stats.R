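test_that("grid_summary returns sample SD and scale-invariant CV", {
  s <- grid_summary(c(8, 12))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, sd(c(8, 12)))
  expect_equal(s$cv_percent, 100 * sd(c(8, 12)) / 10, tolerance = 1e-12)

  const <- grid_summary(rep(7.3, 42))
  expect_equal(const$cv_percent, 0)

  set.seed(2)
  v <- runif(42, 5, 25)
  expect_equal(grid_summary(3.7 * v)$cv_percent, grid_summary(v)$cv_percent)

  expect_error(grid_summary(5), "at least 2")
  expect_error(grid_summary(c(5, -1)), "> 0")
})

test_that("published moisture summaries are reproduced from the plot table", {
  m <- study_table("moisture_summary")
  rain <- m[m$exclusion == "No", ]
  excl <- m[m$exclusion == "Yes", ]
  expect_equal(round(mean(rain$mean_swc_pct), 2), 15.57)
  expect_equal(round(mean(excl$swc_cv_pct), 2), 54.10)
})

test_that("weighted shade tolerance is the BA-weighted mean rating", {
  expect_equal(weighted_shade_tolerance(5, 3), 3)
  expect_equal(weighted_shade_tolerance(c(10, 10), c(1, 3)), 2)
  expect_equal(weighted_shade_tolerance(c(1, 7, 2), rep(2.5, 3)), 2.5)
  ba <- c(20, 5, 3)
  r <- c(1, 3, 4)
  w <- weighted_shade_tolerance(ba, r)
  expect_true(w >= min(r) && w <= max(r))
  expect_equal(w, sum(ba * r) / sum(ba))
  expect_error(weighted_shade_tolerance(c(0, 0), c(1, 2)), "> 0")
  expect_error(weighted_shade_tolerance(c(1, 2), c(1, NA)), "rating")
})

test_that("clr transform is zero-sum, scale-invariant and zero-intolerant", {
  expect_equal(clr_transform(c(1, 1, 1) / 3), c(0, 0, 0))
  v <- clr_transform(c(58.4, 38.6, 3.0))
  expect_equal(sum(v), 0, tolerance = 1e-12)
  expect_equal(clr_transform(c(58.4, 38.6, 3.0) / 100), v, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    x <- runif(sample(3:6, 1), 0.01, 10)
    expect_equal(sum(clr_transform(x)), 0, tolerance = 1e-10)
  }
  expect_error(clr_transform(c(0.5, 0, 0.5)), "> 0")
})

test_that("univariate pseudo-F equals the classical one-way F", {
  set.seed(11)
  values <- rnorm(24, rep(c(0, 1, 3), each = 8))
  groups <- rep(letters[1:3], each = 8)
  res <- permutation_group_test(values, groups, n_permutations = 99, seed = 1)
  expect_equal(res$pseudo_f, oracle_oneway_f(values, groups),
               tolerance = 1e-10)
  expect_equal(res$pseudo_f,
               summary(aov(values ~ factor(groups)))[[1]]$`F value`[1],
               tolerance = 1e-10)
})

test_that("multivariate pseudo-F matches vegan's Euclidean PERMANOVA", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rnorm(40), nrow = 10)
  x[6:10, ] <- x[6:10, ] + 1
  g <- rep(c("a", "b"), each = 5)
  ours <- permutation_group_test(x, g, n_permutations = 999, seed = 2)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 999)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$ss_among, ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("extreme separation attains the minimal add-one p-value", {
  # groups internally identical and far apart: no permuted labelling (with 20
  # rows, the chance of redrawing the exact partition is negligible) reaches
  # the observed pseudo-F
  x <- rbind(matrix(0, 10, 2), matrix(100, 10, 2))
  g <- rep(c("a", "b"), each = 10)
  res <- permutation_group_test(x, g, n_permutations = 99, seed = 3)
  expect_equal(res$p_value, 1 / 100)
  expect_error(permutation_group_test(x, c("a", rep("b", 19))),
               "at least 2 rows")
  expect_error(permutation_group_test(x, rep("a", 20)), "at least 2 groups")
})

test_that("permutation p-values are reproducible and near-uniform under null", {
  x <- rnorm(12)
  g <- rep(c("a", "b"), 6)
  p1 <- permutation_group_test(x, g, n_permutations = 199, seed = 9)$p_value
  p2 <- permutation_group_test(x, g, n_permutations = 199, seed = 9)$p_value
  expect_identical(p1, p2)

  set.seed(77)
  ps <- vapply(1:200, function(i) {
    permutation_group_test(rnorm(12), g, n_permutations = 99,
                           seed = i)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.04)
  expect_gt(mean(ps), 0.35)  # roughly uniform, not piled near 0
})

test_that("group means reproduce the published plot-level summaries", {
  soil <- study_table("soil_properties")
  gm <- group_means(soil$mineral_ph, soil$proliferation)
  expect_equal(round(gm$mean[gm$group == "No"], 2), 4.91)
  expect_equal(round(gm$mean[gm$group == "Yes"], 2), 4.16)
  expect_equal(round(gm$sd[gm$group == "No"], 2), 0.38)

  inv <- study_table("stand_inventory")
  gm_ba <- group_means(inv$total_canopy_ba_m2_ha, rep("all", nrow(inv)))
  expect_equal(round(gm_ba$mean, 2), 33.62)

  expect_warning(group_means(c(1, 2, 3), c("a", "a", "b")), "SD undefined")
  expect_error(group_means(1:3, factor(c("a", "a", "a"),
                                       levels = c("a", "b"))), "empty group")
})

test_that("moisture delta scales the SWC change to 30 days", {
  expect_equal(moisture_delta(10, 10, 45), 0)
  expect_equal(moisture_delta(10, 16, 30), 6)
  expect_equal(moisture_delta(16, 10, 60), -3)
  expect_error(moisture_delta(10, 12, 0), "> 0")
})
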