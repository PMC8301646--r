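# Simulated glasshouse experiments: replicated trait tables and dynamic
# growth series with planted genotype x treatment effects.

# Deterministic trait expectations for one genotype under one treatment.
trait_expectations <- function(g, treatment, ib_day = 66, fl_day = 100,
                               harvest_day = 146) {
  sev <- max(0, 1 - development_fraction(harvest_day, treatment,
                                         g$drought_sensitivity,
                                         ib_day, fl_day) /
               development_fraction(harvest_day, "C", 0, ib_day, fl_day))
  red <- 1 - sev  # realised growth relative to control
  db <- 60 * g$growth_rate * red
  yield_frac <- g$yield_per_biomass * (1 - 0.6 * sev)
  list(
    db = db,
    sy = db * yield_frac,
    brn = g$branch_factor * (0.4 + 0.6 * red),
    bdn = 2.5 * g$branch_factor * (0.3 + 0.7 * red),
    ph = 120 * sqrt(g$growth_rate) * (0.5 + 0.5 * red),
    sn = db * yield_frac * 28,
    esb = 6 * db
  )
}

#' Simulate a replicated drought experiment
#'
#' Generates a trait table following one of the study designs:
#' `"rcbd6"`, a randomized complete block design with six replications
#' over all four treatments, or `"splitplot"`, a split-plot design with
#' control and combined-stage stress (`C` vs `IB50FL50`) as main plots and
#' genotypes as sub-plots.
#'
#' Each observation is a deterministic genotype x treatment expectation
#' times a multiplicative block effect and multiplicative log-normal noise
#' (continuous traits) or a Poisson draw (counts). The digitally estimated
#' shoot biomass `esb` (kilopixels) is generated proportional to dry
#' biomass with log-normal scatter (`esb_sdlog`), which sets the planted
#' ESB–DB association strength.
#'
#' @param genotypes Tibble from [generate_genotypes()].
#' @param design `"rcbd6"` or `"splitplot"`.
#' @param seed Integer seed.
#' @param reps Blocks for the split-plot design (rcbd6 always uses 6).
#' @param noise_scale Master noise multiplier; 0 gives deterministic
#'   expectations (counts rounded), 1 the default noise model.
#' @param esb_sdlog Log-scale sd of the ESB given DB (association
#'   strength; default 0.10 yields a Pearson r of about 0.9 at n = 96).
#' @param ib_day,fl_day,harvest_day Stage days.
#' @return A tibble with columns `genotype`, `treatment`, `block`, `db`,
#'   `sy`, `brn`, `bdn`, `ph`, `sn`, `esb`.
#' @export
generate_experiment <- function(genotypes,
                                design = c("rcbd6", "splitplot"),
                                seed = 1, reps = 3, noise_scale = 1,
                                esb_sdlog = 0.10,
                                ib_day = 66, fl_day = 100,
                                harvest_day = 146) {
  design <- match.arg(design)
  if (!nrow(genotypes)) stop_invalid("`genotypes` must be non-empty")
  check_scalar_number(noise_scale, "noise_scale", min = 0)
  treatments <- if (design == "rcbd6") TREATMENTS else c("C", "IB50FL50")
  n_blocks <- if (design == "rcbd6") 6L else as.integer(reps)
  if (n_blocks < 1) stop_invalid("`reps` must be >= 1")
  grid <- tidyr::expand_grid(
    genotype = genotypes$genotype,
    treatment = treatments,
    block = paste0("B", seq_len(n_blocks))
  )
  with_seed(seed, {
    block_eff <- setNames(rlnorm(n_blocks, 0, 0.05 * noise_scale),
                          paste0("B", seq_len(n_blocks)))
    rows <- purrr::pmap(grid, function(genotype, treatment, block) {
      g <- genotypes[genotypes$genotype == genotype, ]
      ex <- trait_expectations(g, treatment, ib_day, fl_day, harvest_day)
      be <- block_eff[[block]]
      if (noise_scale == 0) {
        db <- ex$db; sy <- ex$sy; ph <- ex$ph
        brn <- round(ex$brn); bdn <- round(ex$bdn); sn <- round(ex$sn)
        esb <- ex$esb
      } else {
        db <- ex$db * be * rlnorm(1, 0, 0.15 * noise_scale)
        sy <- ex$sy * be * rlnorm(1, 0, 0.15 * noise_scale)
        ph <- ex$ph * rlnorm(1, 0, 0.04 * noise_scale)
        brn <- rpois(1, ex$brn)
        bdn <- rpois(1, ex$bdn)
        sn <- rpois(1, ex$sn)
        esb <- 6 * db * rlnorm(1, 0, esb_sdlog * noise_scale)
      }
      tibble(genotype = genotype, treatment = treatment, block = block,
             db = db, sy = min(sy, 0.95 * db), brn = brn, bdn = bdn,
             ph = ph, sn = sn, esb = esb)
    })
    list_rbind(rows)
  })
}

#' Simulate dynamic growth series of true ESB
#'
#' Per genotype x treatment x block x imaging day, the noiseless ESB
#' trajectory follows the development fraction of [development_fraction()]
#' (so stress curves separate from control only after the stress-onset
#' day), times block and residual log-normal noise.
#'
#' @inheritParams generate_experiment
#' @param treatments Treatments to simulate.
#' @param days Imaging days (default every 3 days from day 15 to 146,
#'   mirroring a regular conveyor imaging schedule).
#' @return A tibble `(genotype, treatment, block, day, esb)`.
#' @export
generate_growth_series <- function(genotypes, treatments = c("C", "IB50FL50"),
                                   days = seq(15, 146, by = 3),
                                   seed = 1, reps = 3, noise_scale = 1,
                                   ib_day = 66, fl_day = 100) {
  if (!nrow(genotypes)) stop_invalid("`genotypes` must be non-empty")
  grid <- tidyr::expand_grid(
    genotype = genotypes$genotype,
    treatment = treatments,
    block = paste0("B", seq_len(reps))
  )
  with_seed(seed, {
    block_eff <- setNames(rlnorm(reps, 0, 0.05 * noise_scale),
                          paste0("B", seq_len(reps)))
    rows <- purrr::pmap(grid, function(genotype, treatment, block) {
      g <- genotypes[genotypes$genotype == genotype, ]
      dev <- development_fraction(days, treatment, g$drought_sensitivity,
                                  ib_day, fl_day)
      noise <- if (noise_scale == 0) 1 else {
        rlnorm(length(days), 0, 0.06 * noise_scale)
      }
      be <- block_eff[[block]]
      tibble(genotype = genotype, treatment = treatment, block = block,
             day = days,
             esb = 6 * 60 * g$growth_rate * dev * be * noise)
    })
    list_rbind(rows)
  })
}
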