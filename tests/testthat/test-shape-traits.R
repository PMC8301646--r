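# Digital shape traits: pixel counts, hull, caliper, rectangles.

test_that("ESB sums the four views in kilopixels", {
  mk <- function(n) { m <- matrix(FALSE, 80, 80); m[seq_len(n)] <- TRUE; m }
  masks <- list(side_0 = mk(1000), side_120 = mk(2000),
                side_240 = mk(3000), top = mk(4000))
  expect_equal(estimated_shoot_biomass(masks), 10)
  empty <- list(side_0 = mk(0), side_120 = mk(0), side_240 = mk(0), top = mk(0))
  expect_equal(estimated_shoot_biomass(empty), 0)
  onev <- empty; onev$top <- mk(500)
  expect_equal(estimated_shoot_biomass(onev), 0.5)
  expect_error(estimated_shoot_biomass(masks[-1]),
               class = "phenodrought_invalid_argument")
})

test_that("green/non-green counts are exact label counts", {
  cm <- matrix(0L, 10, 10)
  cm[1:60] <- 1L; cm[61:100] <- 2L
  expect_equal(green_nongreen_counts(cm), c(green = 60, non_green = 40))
  expect_equal(green_nongreen_counts(matrix(0L, 3, 3)),
               c(green = 0, non_green = 0))
})

test_that("bounding box is the tight half-open box over pixel centres", {
  m <- matrix(FALSE, 10, 10); m[8, 6] <- TRUE  # (x=5, y=7)
  bb <- bounding_box(m)
  expect_equal(unlist(bb[c("x0", "y0", "x1", "y1", "area")]),
               c(x0 = 5, y0 = 7, x1 = 6, y1 = 8, area = 1))
  m2 <- matrix(FALSE, 10, 10); m2[1, 1] <- TRUE; m2[5, 10] <- TRUE
  expect_equal(bounding_box(m2)$area, 50)
  expect_true(bounding_box(matrix(FALSE, 3, 3))$empty)
  # oracle: min/max scan
  for (case in 1:5) {
    m3 <- random_mask(30, c(20, 20), seed = case)
    pts <- mask_pts(m3)
    bb3 <- bounding_box(m3)
    expect_equal(bb3$area,
                 (max(pts[, 1]) - min(pts[, 1]) + 1) *
                   (max(pts[, 2]) - min(pts[, 2]) + 1))
  }
})

test_that("convex hull area handles unit squares and degenerate masks", {
  m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE
  expect_equal(convex_hull_area(m), 1)
  lin <- matrix(FALSE, 5, 5); lin[cbind(1:3, 1:3)] <- TRUE
  expect_equal(convex_hull_area(lin), 0)
  expect_equal(convex_hull_area(matrix(FALSE, 4, 4)), 0)
})

test_that("hull area matches the gift-wrapping oracle on random masks", {
  for (case in 1:25) {
    m <- random_mask(sample(4:60, 1), c(24, 24), seed = 400 + case)
    expect_equal(convex_hull_area(m), oracle_hull_area(mask_pts(m)),
                 tolerance = 1e-12)
  }
})

test_that("caliper length covers both modes and matches the all-pairs oracle", {
  m <- matrix(FALSE, 6, 6); m[1, 1] <- TRUE; m[5, 4] <- TRUE  # (0,0), (3,4)
  expect_equal(caliper_length(m, "feret"), 5)
  expect_equal(caliper_length(m, "vertical"), 4)
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  expect_equal(caliper_length(single), 0)
  for (case in 1:25) {
    m2 <- random_mask(sample(2:60, 1), c(24, 24), seed = 500 + case)
    expect_equal(caliper_length(m2, "feret"), oracle_feret(mask_pts(m2)),
                 tolerance = 1e-12)
  }
})

test_that("minimum-area rectangle: square, collinear, and oracle agreement", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  mar <- min_area_rectangle(m)
  expect_equal(mar$area, 1)
  diag_m <- matrix(FALSE, 8, 8); diag_m[cbind(1:5, 1:5)] <- TRUE
  expect_equal(min_area_rectangle(diag_m)$area, 0)
  for (case in 1:25) {
    m2 <- random_mask(sample(5:40, 1), c(24, 24), seed = 600 + case)
    got <- min_area_rectangle(m2)$area
    edge <- oracle_mar_edges(mask_pts(m2))
    sweep_min <- oracle_mar_sweep(mask_pts(m2), step_deg = 0.5)
    if (edge > 0) {
      expect_lt(abs(got - edge) / edge, 1e-9)
      expect_lte(got, sweep_min * (1 + 1e-9))
    } else {
      expect_equal(got, 0)
    }
  }
})

test_that("containment chain CHA <= MAR <= BB holds with equality for rectangles", {
  for (case in 1:30) {
    m <- random_mask(sample(5:80, 1), c(24, 24), seed = 700 + case)
    cha <- convex_hull_area(m)
    mar <- min_area_rectangle(m)$area
    pts <- mask_pts(m)
    bb <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
    expect_lte(cha, mar + 1e-9)
    expect_lte(mar, bb + 1e-9)
  }
  rect <- matrix(FALSE, 12, 12); rect[3:7, 2:10] <- TRUE
  pts <- mask_pts(rect)
  bb_centres <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
  expect_equal(min_area_rectangle(rect)$area, bb_centres)
})

test_that("adding a pixel never decreases any shape trait", {
  m <- random_mask(40, c(20, 20), seed = 900)
  base <- c(sum(m), convex_hull_area(m), caliper_length(m),
            min_area_rectangle(m)$area, bounding_box(m)$area)
  free <- which(!m)
  withr::with_seed(901, picks <- sample(free, 25))
  for (px in picks) {
    m2 <- m; m2[px] <- TRUE
    now <- c(sum(m2), convex_hull_area(m2), caliper_length(m2),
             min_area_rectangle(m2)$area, bounding_box(m2)$area)
    expect_true(all(now >= base - 1e-9))
  }
})

test_that("quarter-turn rotation leaves CHA, CL and MAR unchanged", {
  m <- random_mask(60, c(22, 22), seed = 950)
  rot90 <- t(m)[, nrow(m):1]
  expect_equal(convex_hull_area(rot90), convex_hull_area(m), tolerance = 1e-12)
  expect_equal(caliper_length(rot90), caliper_length(m), tolerance = 1e-12)
  expect_equal(min_area_rectangle(rot90)$area, min_area_rectangle(m)$area,
               tolerance = 1e-9)
})

test_that("compile_digital_traits aggregates per plant and flags gaps", {
  g <- demo_genotype()
  p <- grow_plant(g, "C", 70, seed = 3)
  iset <- render_views(p, render_config(noise_sd = 0, salt_pepper = 0), seed = 5)
  x <- purrr::imap(iset$truth_class, function(cm, v) {
    tibble::tibble(plant_id = "p1", day = 70, view = v, class_map = list(cm))
  }) |> purrr::list_rbind()
  tr <- compile_digital_traits(x)
  expect_equal(nrow(tr), 1)
  expect_false(tr$incomplete)
  expect_equal(tr$esb * 1000, sum(vapply(iset$truth_class, function(z) sum(z > 0L),
                                         numeric(1))))
  expect_gt(tr$cha, 0)
  expect_true(all(c("cl", "mar_area", "bb_area") %in% names(tr)))
  lng <- traits_long(tr)
  expect_setequal(unique(lng$view), VIEW_KEYS)

  # missing view: row flagged, ESB omitted
  tr2 <- compile_digital_traits(x[-1, ])
  expect_true(tr2$incomplete)
  expect_true(is.na(tr2$esb))

  # empty masks: zero row with empty flag
  x0 <- x
  x0$class_map <- purrr::map(x0$class_map, function(z) { z[] <- 0L; z })
  tr0 <- compile_digital_traits(x0)
  expect_true(tr0$empty)
  expect_equal(tr0$esb, 0)
  expect_equal(tr0$cha, 0)
})

test_that("ESB grows over time for a noiseless control plant", {
  g <- demo_genotype()
  cfg <- render_config(noise_sd = 0, salt_pepper = 0)
  rows <- list()
  for (d in c(50, 80)) {
    p <- grow_plant(g, "C", d, seed = 3)
    iset <- render_views(p, cfg, seed = 5)
    rows <- c(rows, purrr::imap(iset$truth_class, function(cm, v) {
      tibble::tibble(plant_id = "p1", day = d, view = v, class_map = list(cm))
    }))
  }
  tr <- compile_digital_traits(purrr::list_rbind(rows)) |> dplyr::arrange(day)
  expect_true(all(diff(tr$esb) >= 0))
})
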