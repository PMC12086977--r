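# Litter-mixture additivity: is the decay rate of a 50:50 two-species mixture
# the average of the two monospecific rates? Deviations are synergistic
# (faster-than-expected loss) or antagonistic (slower).

#' Expected decay rate of a 50:50 mixture under additivity
#'
#' The arithmetic mean of the two monospecific rates.
#' @param k_maple,k_beech Monospecific slopes (year^-1, negative for loss).
#' @return `(k_maple + k_beech) / 2`.
#' @export
#' @examples
#' expected_mixture_k(-1.026, -0.787)  # -0.9065
expected_mixture_k <- function(k_maple, k_beech) {
  if (any(!is.finite(k_maple)) || any(!is.finite(k_beech))) {
    stop_domain("monospecific rates must be finite")
  }
  (k_maple + k_beech) / 2
}

#' Standardized difference between observed and expected rates
#'
#' `(observed - expected) / expected`, a signed fraction. For negative-rate
#' inputs the result is positive when the observed magnitude exceeds the
#' expected one (faster-than-expected loss).
#'
#' @param observed,expected Decay rates (year^-1); `expected` must be non-zero.
#' @return Signed fraction (0.26 = 26%).
#' @export
#' @examples
#' standardized_difference(-1.026, -0.812)  # ~0.26
standardized_difference <- function(observed, expected) {
  if (any(!is.finite(observed)) || any(!is.finite(expected))) {
    stop_domain("rates must be finite")
  }
  if (any(expected == 0)) stop_domain("expected rate must be non-zero")
  (observed - expected) / expected
}

#' Z-test of mixture additivity
#'
#' Compares the observed mixture slope with the additivity expectation using a
#' standard two-quantity z with independent variances:
#' `z = (observed - expected) / sqrt(var_observed + var_expected)`, where the
#' variance of the expectation (a mean of two slopes) is
#' `(var_maple + var_beech) / 4`. The sign of z is preserved so synergism and
#' antagonism are distinguishable; the squared variant is returned as
#' `z_squared` for users who prefer the chi-square-scale statistic.
#'
#' @param observed Observed mixture slope (year^-1, negative for loss).
#' @param var_observed Sampling variance of the observed slope (> 0).
#' @param expected Expected slope under additivity (see
#'   [expected_mixture_k()]).
#' @param var_expected Sampling variance of the expected slope (> 0); pass
#'   `(var_maple + var_beech)/4` when the expectation is a mean of two
#'   independently estimated slopes.
#' @param critical Two-sided critical value for the additive verdict
#'   (default 1.96, i.e. 5%).
#' @return An `additivity_result`: observed/expected rates, the standardized
#'   difference, `z`, `z_squared`, and a verdict among `additive`,
#'   `synergistic`, `antagonistic`.
#' @export
additivity_z <- function(observed, var_observed, expected, var_expected,
                         critical = 1.96) {
  assert_scalar_number(observed, "observed")
  assert_scalar_number(expected, "expected")
  assert_scalar_number(var_observed, "var_observed", positive = TRUE)
  assert_scalar_number(var_expected, "var_expected", positive = TRUE)
  assert_scalar_number(critical, "critical", positive = TRUE)
  if (expected == 0) stop_domain("expected rate must be non-zero")
  z <- (observed - expected) / sqrt(var_observed + var_expected)
  verdict <- if (abs(z) < critical) {
    "additive"
  } else if (abs(observed) > abs(expected)) {
    "synergistic"
  } else {
    "antagonistic"
  }
  structure(list(
    observed_k = observed, expected_k = expected,
    standardized_difference = standardized_difference(observed, expected),
    z_score = z, z_squared = z^2, critical = critical, verdict = verdict
  ), class = "additivity_result")
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf(
    "Mixture additivity: observed %.3f vs expected %.3f (std diff %.1f%%)\n",
    x$observed_k, x$expected_k, 100 * x$standardized_difference))
  cat(sprintf("  Z = %.2f (critical %.2f) -> %s\n",
              x$z_score, x$critical, x$verdict))
  invisible(x)
}

#' Per-species instantaneous rates inside mixed bags
#'
#' Applies the instantaneous-k formula to each 1.5 g component of a 50:50
#' mixed bag.
#'
#' @param maple_final_mass,beech_final_mass Component dry masses (g);
#'   vectorized.
#' @param yf Elapsed year fraction(s).
#' @param component_initial Initial component mass (g); 1.5 by design.
#' @return Data frame `maple_k`, `beech_k` (year^-1).
#' @export
per_species_mixed_k <- function(maple_final_mass, beech_final_mass, yf,
                                component_initial = 1.5) {
  if (any(!is.finite(maple_final_mass)) || any(!is.finite(beech_final_mass))) {
    stop_domain("mixed bag is missing a component mass")
  }
  data.frame(
    maple_k = instantaneous_k(
      100 * maple_final_mass / component_initial, yf),
    beech_k = instantaneous_k(
      100 * beech_final_mass / component_initial, yf)
  )
}

#' Relative rate of a species in mixture versus alone
#'
#' `|k_in_mixture| / |k_monospecific| - 1`, a signed fraction: +0.27 means the
#' species decayed 27% faster inside the mixture than in monospecific bags.
#'
#' @param k_in_mixture,k_monospecific Decay rates (year^-1); the monospecific
#'   rate must be non-zero.
#' @return Signed fraction.
#' @export
#' @examples
#' mixture_vs_mono_ratio(-1.031, -0.812)  # ~+0.27
mixture_vs_mono_ratio <- function(k_in_mixture, k_monospecific) {
  if (any(!is.finite(k_in_mixture)) || any(!is.finite(k_monospecific))) {
    stop_domain("rates must be finite")
  }
  if (any(k_monospecific == 0)) stop_domain("monospecific rate must be non-zero")
  abs(k_in_mixture) / abs(k_monospecific) - 1
}

#' Closed-interval containment check
#'
#' Flags whether a mixed-bag species rate lies inside the interval estimated
#' for the monospecific slope; rates outside are non-additivity candidates.
#' Bounds are inclusive.
#'
#' @param value Rate to test.
#' @param lower,upper Interval bounds, `lower <= upper`.
#' @return Logical.
#' @export
interval_containment <- function(value, lower, upper) {
  if (any(lower > upper)) stop_domain("interval bounds are inverted")
  value >= lower & value <= upper
}

#' Additivity tests for every proliferation x exclusion combination of a fit
#'
#' For each combination where all three species cells were fitted, tests the
#' mixed-cell slope against the mean of the two monospecific slopes with
#' [additivity_z()], using the squared standard errors of the fitted slopes as
#' variances.
#'
#' @param fit A `decay_fit` from [fit_multigroup()].
#' @param critical Critical value passed to [additivity_z()].
#' @return Data frame: `proliferation`, `exclusion`, `observed_k`,
#'   `expected_k`, `std_diff`, `z`, `verdict`.
#' @export
test_additivity <- function(fit, critical = 1.96) {
  stopifnot(inherits(fit, "decay_fit"))
  sl <- fit$slopes
  combos <- unique(sl[, c("proliferation", "exclusion")])
  out <- NULL
  for (i in seq_len(nrow(combos))) {
    sub <- sl[sl$proliferation == combos$proliferation[i] &
                sl$exclusion == combos$exclusion[i], ]
    if (!setequal(sub$species, species_levels())) next
    km <- sub[sub$species == "maple", ]
    kb <- sub[sub$species == "beech", ]
    kx <- sub[sub$species == "mixed", ]
    res <- additivity_z(
      observed = kx$estimate, var_observed = kx$se^2,
      expected = expected_mixture_k(km$estimate, kb$estimate),
      var_expected = (km$se^2 + kb$se^2) / 4,
      critical = critical
    )
    out <- rbind(out, data.frame(
      proliferation = combos$proliferation[i],
      exclusion = combos$exclusion[i],
      observed_k = res$observed_k, expected_k = res$expected_k,
      std_diff = res$standardized_difference, z = res$z_score,
      verdict = res$verdict, stringsAsFactors = FALSE
    ))
  }
  out
}
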