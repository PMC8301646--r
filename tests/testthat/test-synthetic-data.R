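# Generators: genotype panel, growth, experiment tables, pot weights.

test_that("genotype panel is reproducible, valid and unique", {
  a <- generate_genotypes(1, seed = 7)
  b <- generate_genotypes(1, seed = 7)
  expect_identical(a, b)

  big <- generate_genotypes(200, seed = 1)
  expect_equal(nrow(big), 200)
  expect_equal(dplyr::n_distinct(big$genotype), 200)

  small <- generate_genotypes(4, seed = 3)
  expect_true(all(small$drought_sensitivity >= 0 & small$drought_sensitivity <= 1))
  expect_true(all(small$senescence_propensity >= 0 & small$senescence_propensity <= 1))
  expect_true(all(small$growth_rate > 0))
  expect_true(all(small$yield_per_biomass > 0))

  expect_error(generate_genotypes(0, seed = 1), class = "phenodrought_invalid_argument")
})

test_that("tiered panels plant the requested tolerance grouping", {
  g <- generate_genotypes(40, seed = 5, tiers = 4, tier_sd = 0.01)
  expect_equal(sort(unique(g$tier)), 1:4)
  means <- tapply(g$drought_sensitivity, g$tier, mean)
  expect_true(all(diff(means) > 0))
})

test_that("plants start as a bare stem and grow monotonically", {
  g <- demo_genotype(sensitivity = 0.6)
  p0 <- grow_plant(g, "C", day = 0, seed = 11)
  expect_equal(nrow(p0$organs), 1)
  expect_equal(p0$organs$role, "stem")

  days <- c(0, 20, 40, 60, 80, 100)
  cfg <- render_config(noise_sd = 0, salt_pepper = 0)
  n_organs <- vapply(days, function(d) nrow(grow_plant(g, "C", d, seed = 11)$organs),
                     numeric(1))
  areas <- vapply(days, function(d) {
    projected_area(grow_plant(g, "C", d, seed = 11), "side_0", cfg)
  }, numeric(1))
  expect_true(all(diff(n_organs) >= 0))
  expect_true(all(diff(areas) >= 0))
})

test_that("stress reduces area after onset, in proportion to sensitivity", {
  cfg <- render_config(noise_sd = 0, salt_pepper = 0)
  g_sens <- demo_genotype(sensitivity = 0.8)
  g_tol <- demo_genotype(sensitivity = 0.2)
  a_c <- projected_area(grow_plant(g_sens, "C", 80, seed = 9), "side_0", cfg)
  a_s <- projected_area(grow_plant(g_sens, "IB40", 80, seed = 9), "side_0", cfg)
  expect_lt(a_s, a_c)
  # before onset the trajectories agree
  expect_equal(
    grow_plant(g_sens, "IB40", 50, seed = 9)$organs,
    grow_plant(g_sens, "C", 50, seed = 9)$organs
  )
  # reduction is monotone in sensitivity
  red_sens <- 1 - development_fraction(90, "IB40", 0.8) / development_fraction(90, "C", 0)
  red_tol <- 1 - development_fraction(90, "IB40", 0.2) / development_fraction(90, "C", 0)
  expect_gt(red_sens, red_tol)
  expect_error(grow_plant(g_sens, "D70", 80, seed = 9),
               class = "phenodrought_invalid_argument")
})

test_that("geometry is deterministic and honours a requested senescence fraction", {
  g <- demo_genotype()
  p1 <- grow_plant(g, "IB50FL50", 90, seed = 21)
  p2 <- grow_plant(g, "IB50FL50", 90, seed = 21)
  expect_identical(p1$organs, p2$organs)

  for (f in c(0, 0.25, 0.5, 0.9)) {
    p <- grow_plant(g, "C", 90, seed = 21, senescence = f)
    n_non <- sum(p$organs$class == "non_green")
    expect_lte(abs(n_non - f * nrow(p$organs)), 1)
  }
})

test_that("rcbd6 and split-plot designs have the right structure", {
  g4 <- generate_genotypes(4, seed = 3)
  exp1 <- generate_experiment(g4, "rcbd6", seed = 2)
  expect_equal(nrow(exp1), 4 * 4 * 6)
  expect_setequal(unique(exp1$treatment), TREATMENTS)
  expect_equal(dplyr::n_distinct(exp1$block), 6)

  g200 <- generate_genotypes(200, seed = 1)
  exp2 <- generate_experiment(g200, "splitplot", seed = 2, reps = 2)
  expect_equal(dplyr::n_distinct(exp2$genotype), 200)
  expect_setequal(unique(exp2$treatment), c("C", "IB50FL50"))

  expect_true(all(exp1$sy <= exp1$db))
  expect_true(all(exp1$db >= 0 & exp1$sy >= 0 & exp1$brn >= 0))
  expect_error(generate_experiment(g4[0, ], "rcbd6", seed = 1),
               class = "phenodrought_invalid_argument")
})

test_that("zero noise gives identical replicates and planted effect recovery", {
  g <- generate_genotypes(5, seed = 8)
  ex <- generate_experiment(g, "splitplot", seed = 4, reps = 3, noise_scale = 0)
  per_rep <- ex |>
    dplyr::group_by(genotype, treatment) |>
    dplyr::summarise(n_db = dplyr::n_distinct(db), n_sy = dplyr::n_distinct(sy),
                     .groups = "drop")
  expect_true(all(per_rep$n_db == 1) && all(per_rep$n_sy == 1))

  wide <- ex |>
    dplyr::distinct(genotype, treatment, db) |>
    tidyr::pivot_wider(names_from = treatment, values_from = db)
  expect_true(all(wide$C > wide$IB50FL50))  # all sensitivities > 0
})

test_that("experiment tables are reproducible under a fixed seed", {
  g <- generate_genotypes(3, seed = 2)
  expect_identical(generate_experiment(g, "rcbd6", seed = 9),
                   generate_experiment(g, "rcbd6", seed = 9))
})

test_that("growth series separate from control only after stress onset", {
  g <- generate_genotypes(3, seed = 6)
  ser <- generate_growth_series(g, days = seq(15, 146, by = 3), seed = 1,
                                noise_scale = 0, reps = 1)
  wide <- ser |>
    dplyr::select(genotype, treatment, day, esb) |>
    tidyr::pivot_wider(names_from = treatment, values_from = esb)
  pre <- wide[wide$day <= 66, ]
  post <- wide[wide$day > 69, ]
  expect_equal(pre$C, pre$IB50FL50)
  expect_true(all(post$C > post$IB50FL50))
  # control curves are non-decreasing
  for (gt in unique(ser$genotype)) {
    cc <- ser$esb[ser$genotype == gt & ser$treatment == "C"]
    expect_true(all(diff(cc) >= 0))
  }
})
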