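# shared fixtures: small hand-built bag tables and brute-force oracles

make_bag_row <- function(site = "site1", plot = "site1-2",
                         proliferation = "Yes", exclusion = "No",
                         species = "maple", mesh = "L", replicate = 1L,
                         removal_day = 90L, initial = 3,
                         final = 2.5, maple_final = NA_real_,
                         beech_final = NA_real_) {
  data.frame(site = site, plot = plot, proliferation = proliferation,
             exclusion = exclusion, species = species, mesh = mesh,
             replicate = replicate, removal_day = removal_day,
             initial_mass_g = initial, final_mass_g = final,
             maple_final_mass_g = maple_final, beech_final_mass_g = beech_final,
             stringsAsFactors = FALSE)
}

small_bag_table <- function() {
  rbind(
    make_bag_row(final = 2.5),
    make_bag_row(species = "beech", final = 2.7),
    make_bag_row(species = "mixed", final = 2.3,
                 maple_final = 1.2, beech_final = 1.1),
    make_bag_row(removal_day = 30L, final = 2.9)
  )
}

# brute-force Kendall W: rank within blocks and apply the textbook formula
# directly, independent of the package implementation
oracle_kendalls_w <- function(x, tie_correction = TRUE) {
  x <- as.matrix(x)
  m <- nrow(x)
  n <- ncol(x)
  ranks <- t(apply(x, 1, rank))
  rs <- colSums(ranks)
  s <- sum((rs - mean(rs))^2)
  tt <- if (tie_correction) {
    sum(apply(ranks, 1, function(r) {
      tb <- table(r)
      sum(tb^3 - tb)
    }))
  } else 0
  denom <- m^2 * (n^3 - n) - m * tt
  if (denom <= 0) return(0)  # every block fully tied: no ordering information
  12 * s / denom
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# classical one-way ANOVA F, computed from group means directly
oracle_oneway_f <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  a <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  ssa <- sum(ng * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  (ssa / (a - 1)) / (ssw / (n - a))
}
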