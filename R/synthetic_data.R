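# Synthetic litterbag experiments and environmental records.
#
# The generator is the exact inverse of the estimator: percent remaining is
# drawn as exp(ln(100) - |k| * t + eps) with eps additive on the ln scale
# (multiplicative on mass), so fitting the multigroup decay regression on
# noiseless output returns the configured slopes to numerical precision.

#' Default true decay-rate table for the synthetic design
#'
#' One slope (year^-1, negative for mass loss) per treatment cell. The six
#' rainfall-accessible cells use the rates estimated by the field study the
#' package is modelled on (maple decaying fastest, beech slowest, the mixture
#' intermediate but maple-like); the six excluder cells use the much slower
#' leaching-phase rates, with the mixed-cell value chosen so the excluder cells
#' average -0.296 year^-1.
#'
#' @return Data frame: `proliferation`, `exclusion`, `species`, `cell`, `k`.
#' @export
default_k_table <- function() {
  cells <- treatment_cells()
  k <- c(
    Yes.Yes.maple = -0.248, Yes.Yes.beech = -0.307, Yes.Yes.mixed = -0.333,
    Yes.No.maple  = -1.026, Yes.No.beech  = -0.787, Yes.No.mixed  = -0.969,
    No.Yes.maple  = -0.248, No.Yes.beech  = -0.307, No.Yes.mixed  = -0.333,
    No.No.maple   = -0.812, No.No.beech   = -0.698, No.No.mixed   = -0.829
  )
  cells$k <- unname(k[cells$cell])
  cells
}

#' Configuration for the synthetic litterbag generator
#'
#' Defaults reproduce the study design: 2 proliferation levels x 2 exclusion
#' plots x 3 species x 3 mesh sizes x 2 replicates x 3 sites per proliferation
#' level x 3 removals (30/60/90 d) = 648 bags, with ln-scale noise SD 0.1.
#'
#' @param true_k Data frame mapping each treatment cell to a true slope
#'   (year^-1, negative); see [default_k_table()].
#' @param ln_noise_sd SD of additive Normal noise on `ln(percent remaining)`.
#' @param n_sites_per_proliferation Sites per proliferation level.
#' @param n_replicates Replicate bags per plot x species x mesh x removal.
#' @param mesh_effects Named multiplicative modifiers of |k| for meshes L/M/S.
#'   Default all 1 (no mesh effect, as observed in the field).
#' @param site_dropout Character vector of site labels to omit (emulating the
#'   loss of one proliferation site in the field study), or `NULL`.
#' @param removal_days Integer removal days.
#' @param mixture_components Either `"cell"` (both components of a mixed bag
#'   decay at the mixed-cell slope, so the bag total follows it exactly) or
#'   `"species"` (each component decays at its own monospecific cell slope,
#'   the additive null used by the additivity simulations).
#' @param mixture_synergy Fractional inflation of component |k| inside mixed
#'   bags when `mixture_components = "species"` (0.3 = 30% faster than the
#'   monospecific rate); 0 is the additive null.
#' @param seed Integer seed fixing the full output stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_k = default_k_table(),
                             ln_noise_sd = 0.1,
                             n_sites_per_proliferation = 3,
                             n_replicates = 2,
                             mesh_effects = c(L = 1, M = 1, S = 1),
                             site_dropout = NULL,
                             removal_days = c(30L, 60L, 90L),
                             mixture_components = c("cell", "species"),
                             mixture_synergy = 0,
                             seed = 1L) {
  mixture_components <- match.arg(mixture_components)
  stopifnot(is.data.frame(true_k),
            all(c("cell", "k") %in% names(true_k)))
  if (!setequal(true_k$cell, treatment_cells()$cell)) {
    stop_domain("true_k must cover exactly the 12 treatment cells")
  }
  if (any(!is.finite(true_k$k)) || any(true_k$k == 0)) {
    stop_domain("all true k values must be finite and non-zero")
  }
  if (any(true_k$k > 0)) {
    stop_domain("true k values carry the negative (mass-loss) sign convention")
  }
  assert_scalar_number(ln_noise_sd, "ln_noise_sd")
  if (ln_noise_sd < 0) stop_domain("ln_noise_sd must be >= 0")
  assert_scalar_number(n_sites_per_proliferation, "n_sites_per_proliferation",
                       positive = TRUE)
  assert_scalar_number(n_replicates, "n_replicates", positive = TRUE)
  if (!all(mesh_levels() %in% names(mesh_effects))) {
    stop_domain("mesh_effects must name all of L, M, S")
  }
  if (any(mesh_effects <= 0)) stop_domain("mesh_effects must be > 0")
  if (any(removal_days <= 0)) stop_domain("removal_days must be > 0")
  assert_scalar_number(mixture_synergy, "mixture_synergy")
  structure(list(
    true_k = true_k, ln_noise_sd = ln_noise_sd,
    n_sites_per_proliferation = as.integer(n_sites_per_proliferation),
    n_replicates = as.integer(n_replicates),
    mesh_effects = mesh_effects, site_dropout = site_dropout,
    removal_days = as.integer(removal_days),
    mixture_components = mixture_components,
    mixture_synergy = mixture_synergy,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Site labels of a synthetic design
#'
#' Proliferation sites come first (`site1..siteN`), beech-free sites after.
#' @param config A [synthetic_config()].
#' @return Data frame `site`, `proliferation`.
#' @export
synthetic_sites <- function(config) {
  n <- config$n_sites_per_proliferation
  data.frame(
    site = paste0("site", seq_len(2L * n)),
    proliferation = rep(yes_no(), each = n),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic litterbag experiment
#'
#' Draws, for every site x exclusion plot x species x mesh x replicate x
#' removal day, a percent-remaining value
#' `exp(ln(100) - |k_cell| * mesh_modifier * t + eps)`,
#' `eps ~ Normal(0, ln_noise_sd)`, truncated above at 100%. Mixed bags are
#' built from two 1.5 g components generated with half the noise variance each
#' and summed, so component masses add up to the bag total exactly.
#'
#' @param config A [synthetic_config()].
#' @return A validated bag table (see [bag_columns()]); the full factorial has
#'   `3 * 3 * 2 * n_replicates * 2 * n_sites_per_proliferation * 3` rows minus
#'   any dropped sites.
#' @export
#' @examples
#' bags <- generate_bags(synthetic_config(seed = 42))
#' nrow(bags)  # 648
generate_bags <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sites <- synthetic_sites(config)
  if (!is.null(config$site_dropout)) {
    unknown <- setdiff(config$site_dropout, sites$site)
    if (length(unknown)) {
      stop_domain("site_dropout names unknown site(s): ",
                  paste(unknown, collapse = ", "))
    }
    sites <- sites[!(sites$site %in% config$site_dropout), , drop = FALSE]
  }
  g <- expand.grid(
    removal_day = config$removal_days,
    replicate = seq_len(config$n_replicates),
    mesh = mesh_levels(),
    species = species_levels(),
    exclusion = yes_no(),
    site = sites$site,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$proliferation <- sites$proliferation[match(g$site, sites$site)]
  g$plot <- paste0(g$site, "-", ifelse(g$exclusion == "Yes", "1", "2"))
  g$cell <- cell_label(g$proliferation, g$exclusion, g$species)

  k_of <- function(cells) {
    k <- config$true_k$k[match(cells, config$true_k$cell)]
    if (any(is.na(k))) stop_domain("unknown treatment cell in design")
    k
  }
  tvec <- year_fraction(g$removal_day)
  modifier <- config$mesh_effects[g$mesh]
  n <- nrow(g)

  # Noise is Normal(0, sd) symmetrically truncated to |eps| <= |k| t, the
  # distance to the no-loss boundary: mean ln(percent) stays exactly at
  # ln(100) - |k| t (so the fit recovers the configured slopes without bias)
  # while percent remaining stays inside (0, 100]. Near the boundary the
  # effective noise shrinks, mirroring the small between-bag spread of barely
  # decayed litter.
  draw_percent <- function(k_mag, t, sd) {
    mu <- k_mag * t
    eps <- if (sd > 0) {
      lo <- stats::pnorm(-mu, 0, sd)
      hi <- stats::pnorm(mu, 0, sd)
      stats::qnorm(lo + stats::runif(length(t)) * (hi - lo), 0, sd)
    } else 0
    pmin(exp(log(100) - mu + eps), 100)
  }

  with_seed(substream_seed(config$seed, 1L), {
    mono <- g$species != "mixed"
    pct <- numeric(n)
    k_mag <- abs(k_of(g$cell)) * modifier
    pct[mono] <- draw_percent(k_mag[mono], tvec[mono], config$ln_noise_sd)

    mx <- !mono
    if (any(mx)) {
      comp_sd <- config$ln_noise_sd / sqrt(2)
      comp_k <- function(sp) {
        if (config$mixture_components == "cell") {
          abs(k_of(g$cell[mx]))
        } else {
          mono_cell <- cell_label(g$proliferation[mx], g$exclusion[mx], sp)
          abs(k_of(mono_cell)) * (1 + config$mixture_synergy)
        }
      }
      pct_m <- draw_percent(comp_k("maple") * modifier[mx], tvec[mx], comp_sd)
      pct_b <- draw_percent(comp_k("beech") * modifier[mx], tvec[mx], comp_sd)
      g$maple_final_mass_g <- NA_real_
      g$beech_final_mass_g <- NA_real_
      g$maple_final_mass_g[mx] <- 1.5 * pct_m / 100
      g$beech_final_mass_g[mx] <- 1.5 * pct_b / 100
      pct[mx] <- (pct_m + pct_b) / 2
    } else {
      g$maple_final_mass_g <- NA_real_
      g$beech_final_mass_g <- NA_real_
    }
    g$initial_mass_g <- 3
    g$final_mass_g <- 3 * pct / 100
  })

  bags <- g[, bag_columns()]
  rownames(bags) <- NULL
  validate_bag_table(bags)
  bags
}

#' Configuration for synthetic environmental records
#'
#' Defaults match the field summaries: rainfall-accessible plots with mean
#' volumetric soil water content (SWC) 15.57% and spatial CV 24.40%; excluder
#' plots drier (8.82%) but twice as variable (CV 54.10%); 6 x 7 measurement
#' grids with 3 averaged readings per node.
#'
#' @param swc_mean_by_exclusion Named (`Yes`, `No`) mean SWC (% v/v).
#' @param swc_cv_by_exclusion Named (`Yes`, `No`) spatial CV (%).
#' @param grid_shape Integer `c(rows, cols)` of the measurement grid.
#' @param readings_per_node Averaged TDR readings per grid node.
#' @param temperature_profile Daily mean soil temperatures (deg C) used by the
#'   temperature-log generator.
#' @return An object of class `synthetic_environment_config`.
#' @export
synthetic_environment_config <- function(
    swc_mean_by_exclusion = c(Yes = 8.82, No = 15.57),
    swc_cv_by_exclusion = c(Yes = 54.10, No = 24.40),
    grid_shape = c(6L, 7L),
    readings_per_node = 3L,
    temperature_profile = rep(15, 90)) {
  if (!all(yes_no() %in% names(swc_mean_by_exclusion)) ||
      !all(yes_no() %in% names(swc_cv_by_exclusion))) {
    stop_domain("SWC means and CVs must be named with 'Yes' and 'No'")
  }
  if (any(swc_mean_by_exclusion <= 0)) stop_domain("SWC means must be > 0")
  if (any(swc_cv_by_exclusion < 0)) stop_domain("SWC CVs must be >= 0")
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stop_domain("grid_shape must be c(rows, cols)")
  }
  assert_scalar_number(readings_per_node, "readings_per_node", positive = TRUE)
  structure(list(
    swc_mean_by_exclusion = swc_mean_by_exclusion,
    swc_cv_by_exclusion = swc_cv_by_exclusion,
    grid_shape = as.integer(grid_shape),
    readings_per_node = as.integer(readings_per_node),
    temperature_profile = temperature_profile
  ), class = "synthetic_environment_config")
}

#' Generate a plot soil-moisture grid
#'
#' Node values are means of `readings_per_node` lognormal draws parameterized
#' so that the node-level mean and CV match the configured exclusion level
#' (the lognormal is a pragmatic positive-support choice; only mean and CV are
#' specified by the design). With CV 0 every node equals the configured mean.
#'
#' @param config A [synthetic_environment_config()].
#' @param exclusion "Yes" or "No"; selects the configured mean/CV.
#' @param seed Integer seed; a fixed seed returns an identical grid.
#' @return A `moisture_grid`: list with the node-value matrix (`values`) and
#'   `mean`, `sd`, `cv_percent` summaries over all nodes.
#' @export
generate_moisture_grid <- function(config, exclusion, seed) {
  stopifnot(inherits(config, "synthetic_environment_config"))
  if (!exclusion %in% yes_no()) stop_domain("exclusion must be 'Yes' or 'No'")
  m <- config$swc_mean_by_exclusion[[exclusion]]
  cv <- config$swc_cv_by_exclusion[[exclusion]]
  n_nodes <- prod(config$grid_shape)
  r <- config$readings_per_node
  vals <- with_seed(seed, {
    if (cv == 0) {
      rep(m, n_nodes)
    } else {
      # reading-level CV inflated by sqrt(r) so the r-reading node mean has
      # the target CV
      cv_read <- (cv / 100) * sqrt(r)
      sdlog <- sqrt(log(1 + cv_read^2))
      meanlog <- log(m) - sdlog^2 / 2
      reads <- matrix(stats::rlnorm(n_nodes * r, meanlog, sdlog), nrow = n_nodes)
      rowMeans(reads)
    }
  })
  values <- matrix(vals, nrow = config$grid_shape[1], ncol = config$grid_shape[2])
  s <- grid_summary(as.numeric(values))
  structure(list(values = values, mean = s$mean, sd = s$sd,
                 cv_percent = s$cv_percent, exclusion = exclusion),
            class = "moisture_grid")
}

#' Generate a sub-daily soil-temperature log
#'
#' Readings are deterministic: the daily mean profile plus an optional
#' sinusoidal diurnal cycle whose mean over a whole day of equally spaced
#' readings is exactly zero, so daily means equal the profile.
#'
#' @param start_day First day index (integer).
#' @param n_days Number of days (>= 1).
#' @param profile Daily mean temperatures (deg C); recycled to `n_days`.
#' @param interval_minutes Logging interval; must divide 1440.
#' @param diurnal_amplitude Amplitude (deg C) of the sinusoidal diurnal cycle.
#' @return Data frame `day`, `minute_of_day`, `timestamp_min`, `temp_c`.
#' @export
generate_temperature_log <- function(start_day = 1L, n_days, profile,
                                     interval_minutes = 15L,
                                     diurnal_amplitude = 0) {
  if (length(profile) == 0L) stop_domain("temperature profile must be non-empty")
  assert_scalar_number(n_days, "n_days", positive = TRUE)
  if (1440L %% as.integer(interval_minutes) != 0L) {
    stop_domain("interval_minutes must divide 1440")
  }
  per_day <- 1440L %/% as.integer(interval_minutes)
  days <- seq.int(start_day, length.out = n_days)
  daily_mean <- rep_len(profile, n_days)
  minute <- seq(0L, 1439L, by = as.integer(interval_minutes))
  out <- data.frame(
    day = rep(days, each = per_day),
    minute_of_day = rep(minute, times = n_days)
  )
  out$timestamp_min <- (out$day - 1) * 1440 + out$minute_of_day
  cycle <- diurnal_amplitude * sin(2 * pi * minute / 1440)
  out$temp_c <- rep(daily_mean, each = per_day) + rep(cycle, times = n_days)
  out
}
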