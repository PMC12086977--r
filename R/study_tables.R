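# Bundled plot-level summary tables from the rainfall-exclusion litterbag
# field study the package is designed around. These are the published
# summaries (stand inventories, soil properties, end-of-season moisture grids
# summarized per plot, 90-day mass remaining, and fitted decay rates), shipped
# so that examples and validation arithmetic run without any download.

#' Summary tables from the rainfall-exclusion field study
#'
#' Plot-level summaries of the drought x beech-proliferation litterbag
#' experiment used throughout the examples:
#' \describe{
#'   \item{`stand_inventory`}{Per-plot canopy and sapling basal areas
#'     (m^2 ha^-1) and the basal-area-weighted canopy shade-tolerance rating.}
#'   \item{`soil_properties`}{F-H layer and mineral-soil pH plus sand/silt/clay
#'     percentages per plot.}
#'   \item{`moisture_summary`}{Mean and CV% of the 42-node end-of-season
#'     soil-water-content grid per plot, with the plot-mean 90-day
#'     instantaneous decay rate (one excluder plot lacks a rate because its
#'     mass-loss records were incomplete).}
#'   \item{`mass_remaining_90d`}{Mean fraction of initial mass remaining at 90
#'     days per treatment cell, with interval bounds, mass-loss percentages
#'     (whole-bag and mixed-bag components) and mesh-wise instantaneous
#'     k-values.}
#'   \item{`decay_rates`}{Fitted decay slopes (year^-1): the six
#'     rainfall-accessible multigroup regression slopes plus monospecific and
#'     within-mixture instantaneous rates used for mixture comparisons.}
#' }
#'
#' @param name One of the table names above.
#' @return A data frame.
#' @export
#' @examples
#' mean(study_table("stand_inventory")$total_canopy_ba_m2_ha)  # 33.62
study_table <- function(name = c("stand_inventory", "soil_properties",
                                 "moisture_summary", "mass_remaining_90d",
                                 "decay_rates")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "litterdecay", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fitted multigroup slopes of the rainfall-accessible cells
#'
#' Convenience accessor for the six rainfall-accessible (exclusion = No)
#' regression slopes of [study_table("decay_rates")][study_table], named by
#' treatment cell.
#'
#' @return Named numeric vector of six slopes (year^-1).
#' @export
published_rainfall_slopes <- function() {
  dr <- study_table("decay_rates")
  dr <- dr[dr$basis == "glm_slope" & dr$exclusion == "No", ]
  stats::setNames(dr$k_per_year,
                  cell_label(dr$proliferation, dr$exclusion, dr$species))
}
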