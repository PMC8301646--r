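#' Generate a synthetic genotype panel
#'
#' Draws a panel of synthetic safflower-like genotypes whose attributes drive
#' every downstream simulator: growth rate scales biomass accumulation,
#' drought sensitivity is the proportional growth reduction under water
#' stress, senescence propensity is the share of tissue that turns non-green
#' under stress, branch factor the mean branch count, and yield per biomass
#' the seed yield returned per gram of shoot biomass.
#'
#' Attributes are drawn independently: `growth_rate` and `yield_per_biomass`
#' log-normal (median 1 and 0.30 respectively, sdlog 0.25/0.15),
#' `drought_sensitivity` and `senescence_propensity` uniform on \[0.05, 0.95\]
#' and \[0.1, 0.8\], `branch_factor` 3 + Poisson(4). With `tiers`, drought
#' sensitivity is instead drawn around `tiers` equally spaced tier centres
#' (sd `tier_sd`), which plants a known tolerance grouping for cluster
#' recovery studies.
#'
#' @param n Number of genotypes (>= 1).
#' @param seed Integer seed; the panel is reproducible under a fixed seed.
#' @param tiers Optional number of planted tolerance tiers (e.g. 4).
#' @param tier_sd Within-tier standard deviation of drought sensitivity.
#' @return A tibble with one row per genotype: `genotype`, `growth_rate`,
#'   `drought_sensitivity`, `senescence_propensity`, `branch_factor`,
#'   `yield_per_biomass`, and `tier` (NA unless `tiers` given).
#' @examples
#' generate_genotypes(4, seed = 3)
#' @export
generate_genotypes <- function(n, seed, tiers = NULL, tier_sd = 0.02) {
  check_scalar_number(n, "n", min = 1)
  if (n != round(n)) stop_invalid("`n` must be a whole number")
  n <- as.integer(n)
  with_seed(seed, {
    sens <- if (is.null(tiers)) {
      tier <- rep(NA_integer_, n)
      runif(n, 0.05, 0.95)
    } else {
      check_scalar_number(tiers, "tiers", min = 1)
      centers <- seq(0.1, 0.9, length.out = tiers)
      tier <- sort(rep_len(seq_len(tiers), n))
      pmin(pmax(rnorm(n, centers[tier], tier_sd), 0), 1)
    }
    tibble(
      genotype = sprintf("G%03d", seq_len(n)),
      growth_rate = rlnorm(n, meanlog = 0, sdlog = 0.25),
      drought_sensitivity = sens,
      senescence_propensity = runif(n, 0.1, 0.8),
      branch_factor = 3L + rpois(n, 4),
      yield_per_biomass = rlnorm(n, meanlog = log(0.30), sdlog = 0.15),
      tier = tier
    )
  })
}
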