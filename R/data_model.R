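# Domain types and CSV interchange for litterbag records.
#
# One row of a bag table is one litterbag at one removal date. Treatment flags
# are serialized verbatim as "Yes"/"No"; per-species masses are present only
# for mixed (50:50 maple-beech) bags. Missing observations (e.g. a dropped
# site) are absent rows, never sentinels.

#' Factor levels used throughout the package
#'
#' Litter "species" levels (two monospecific litters and their 50:50 mixture),
#' mesh aperture codes (Large, Medium, Small), and the Yes/No coding of the
#' proliferation and exclusion treatment flags.
#' @name design-levels
#' @keywords internal
NULL

species_levels <- function() c("maple", "beech", "mixed")
mesh_levels <- function() c("L", "M", "S")
yes_no <- function() c("Yes", "No")

#' Canonical table of the 12 treatment cells
#'
#' The factorial design crosses beech-sapling proliferation (Yes/No), rainfall
#' exclusion (Yes/No) and litter species (maple, beech, mixed) into 12 cells.
#' The ordering returned here (proliferation slowest, species fastest, Yes
#' before No, maple < beech < mixed) is the canonical ordering used by the
#' design matrix, the fit report, and the synthetic generator.
#'
#' @return A 12-row data frame with columns `proliferation`, `exclusion`,
#'   `species` and a unique `cell` label.
#' @export
#' @examples
#' treatment_cells()
treatment_cells <- function() {
  g <- expand.grid(
    species = species_levels(),
    exclusion = yes_no(),
    proliferation = yes_no(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, c("proliferation", "exclusion", "species")]
  g$cell <- cell_label(g$proliferation, g$exclusion, g$species)
  rownames(g) <- NULL
  g
}

#' Label a treatment cell
#'
#' @param proliferation,exclusion "Yes"/"No" flags.
#' @param species One of "maple", "beech", "mixed".
#' @return Character label, e.g. `"Yes.No.maple"`.
#' @export
cell_label <- function(proliferation, exclusion, species) {
  paste(proliferation, exclusion, species, sep = ".")
}

#' Column names of the bag-table interchange format
#' @return Character vector of required column names.
#' @export
bag_columns <- function() {
  c("site", "plot", "proliferation", "exclusion", "species", "mesh",
    "replicate", "removal_day", "initial_mass_g", "final_mass_g",
    "maple_final_mass_g", "beech_final_mass_g")
}

#' Validate a bag table against the litterbag invariants
#'
#' Checks, row by row: treatment flags and factor levels are known; masses are
#' positive and final mass does not exceed initial mass; per-species masses are
#' present if and only if the bag is mixed; mixed component masses sum to the
#' bag total within `mixed_tol` grams; and, unless `expected_initial` is
#' `NULL`, every bag starts at the design initial mass (3 g, mixed bags being
#' 1.5 g + 1.5 g).
#'
#' @param bags Data frame with the columns of [bag_columns()].
#' @param expected_initial Design initial dry mass in grams, or `NULL` to skip
#'   the check. Default 3.
#' @param mixed_tol Tolerance (g) for mixed-bag component masses summing to the
#'   bag total. The default 0.005 g reflects per-component weighing on an
#'   analytical balance.
#' @return The validated table, invisibly.
#' @export
validate_bag_table <- function(bags, expected_initial = 3, mixed_tol = 0.005) {
  if (!is.data.frame(bags)) stop_domain("bag table must be a data frame")
  missing_cols <- setdiff(bag_columns(), names(bags))
  if (length(missing_cols)) {
    stop_domain("bag table schema error: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(bags) == 0L) stop_domain("bag table schema error: table has 0 rows")

  fail <- function(rows, rule) {
    stop_domain(sprintf("bag table validation error (row %s): %s",
                        paste(utils::head(rows, 5L), collapse = ", "), rule))
  }
  bad <- which(!(bags$proliferation %in% yes_no()))
  if (length(bad)) fail(bad, "proliferation must be 'Yes' or 'No'")
  bad <- which(!(bags$exclusion %in% yes_no()))
  if (length(bad)) fail(bad, "exclusion must be 'Yes' or 'No'")
  bad <- which(!(bags$species %in% species_levels()))
  if (length(bad)) fail(bad, "species must be one of maple, beech, mixed")
  bad <- which(!(bags$mesh %in% mesh_levels()))
  if (length(bad)) fail(bad, "mesh must be one of L, M, S")
  bad <- which(!is.finite(bags$removal_day) | bags$removal_day <= 0)
  if (length(bad)) fail(bad, "removal_day must be a positive number of days")
  bad <- which(!is.finite(bags$initial_mass_g) | bags$initial_mass_g <= 0)
  if (length(bad)) fail(bad, "initial_mass_g must be > 0")
  bad <- which(!is.finite(bags$final_mass_g) | bags$final_mass_g <= 0)
  if (length(bad)) fail(bad, "final_mass_g must be > 0")
  bad <- which(bags$final_mass_g > bags$initial_mass_g + 1e-9)
  if (length(bad)) fail(bad, "final_mass_g must not exceed initial_mass_g")
  if (!is.null(expected_initial)) {
    bad <- which(abs(bags$initial_mass_g - expected_initial) > 1e-9)
    if (length(bad)) {
      fail(bad, sprintf("initial_mass_g must equal the design mass %g g",
                        expected_initial))
    }
  }

  mixed <- bags$species == "mixed"
  has_m <- is.finite(bags$maple_final_mass_g)
  has_b <- is.finite(bags$beech_final_mass_g)
  bad <- which(mixed & !(has_m & has_b))
  if (length(bad)) fail(bad, "mixed bags must carry both component masses")
  bad <- which(!mixed & (has_m | has_b))
  if (length(bad)) fail(bad, "per-species masses are only allowed for mixed bags")
  if (any(mixed)) {
    dev <- abs(bags$maple_final_mass_g[mixed] + bags$beech_final_mass_g[mixed] -
                 bags$final_mass_g[mixed])
    bad <- which(mixed)[dev > mixed_tol]
    if (length(bad)) {
      fail(bad, sprintf(
        "mixed component masses must sum to final_mass_g within %g g", mixed_tol))
    }
  }
  invisible(bags)
}

#' Read a litterbag table from CSV
#'
#' Reads and validates a bag table in the package interchange format (one row
#' per bag per removal; see [bag_columns()]). Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_bag_table
#' @return A validated data frame.
#' @export
read_bag_table <- function(path, expected_initial = 3, mixed_tol = 0.005) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  bags <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(bag_columns(), names(bags))
  if (length(missing_cols)) {
    stop_domain("bag table schema error: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  for (col in c("maple_final_mass_g", "beech_final_mass_g")) {
    bags[[col]] <- suppressWarnings(as.numeric(bags[[col]]))
  }
  validate_bag_table(bags, expected_initial = expected_initial,
                     mixed_tol = mixed_tol)
  bags
}

#' Write a litterbag table to CSV
#'
#' Inverse of [read_bag_table()]; the read-write-read round trip is lossless.
#'
#' @param bags Validated bag table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bag_table <- function(bags, path) {
  validate_bag_table(bags, expected_initial = NULL)
  utils::write.csv(bags[, bag_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Percentage mass loss of a litterbag
#'
#' `100 * (1 - final/initial)`. Values are carried on the 0-100 scale (not as
#' proportions) throughout the package, so that the decay regression operates
#' on `ln(percent)` with intercept near `ln(100)`.
#'
#' @param final_mass,initial_mass Dry masses in grams; vectorized.
#' @return Percentage of initial mass lost, in `[0, 100)`.
#' @export
#' @examples
#' mass_loss_percent(2.268, 3)   # 24.4% lost
mass_loss_percent <- function(final_mass, initial_mass) {
  if (any(!is.finite(final_mass)) || any(!is.finite(initial_mass))) {
    stop_domain("masses must be finite")
  }
  if (any(final_mass <= 0) || any(initial_mass <= 0)) {
    stop_domain("masses must be > 0")
  }
  if (any(final_mass > initial_mass + 1e-12)) {
    stop_domain("final_mass must not exceed initial_mass")
  }
  100 * (1 - final_mass / initial_mass)
}

#' Percent of initial mass remaining for each bag
#'
#' @param bags Validated bag table.
#' @return Numeric vector on the (0, 100] scale.
#' @export
percent_remaining <- function(bags) {
  100 * bags$final_mass_g / bags$initial_mass_g
}

#' Convert removal day to year fraction
#'
#' Incubation time expressed in years (fraction of 365 days); the 30/60/90-day
#' removals map to 0.0822, 0.1644 and 0.2466.
#' @param removal_day Days since deployment.
#' @return Years, as `removal_day / 365`.
#' @export
year_fraction <- function(removal_day) {
  if (any(!is.finite(removal_day)) || any(removal_day <= 0)) {
    stop_domain("removal_day must be > 0")
  }
  removal_day / 365
}
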