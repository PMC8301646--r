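# Segmentation operators and the composed per-view pipeline.

test_that("crop_roi obeys half-open pixel arithmetic", {
  img <- array(stats::runif(10 * 10 * 3, 0, 255), dim = c(10, 10, 3))
  expect_identical(crop_roi(img, c(0, 0, 10, 10)), img)
  out <- crop_roi(img, c(2, 2, 5, 5))
  expect_equal(dim(out), c(3, 3, 3))
  expect_equal(out[1, 1, ], img[3, 3, ])  # (x0, y0) becomes (0, 0)
  expect_error(crop_roi(img, c(2, 2, 11, 5)), class = "phenodrought_invalid_argument")
  expect_error(crop_roi(img, c(5, 0, 5, 5)), class = "phenodrought_invalid_argument")
})

test_that("ROI cropping removes a rendered cabinet border completely", {
  g <- demo_genotype()
  p <- grow_plant(g, "C", 60, seed = 3)
  cfg <- render_config(frame_margin = 4, noise_sd = 0, salt_pepper = 0)
  iset <- render_views(p, cfg, seed = 2)
  img <- iset$views$side_0
  n_border <- sum(img[, , 1] == cfg$frame_color[1] &
                    img[, , 2] == cfg$frame_color[2] &
                    img[, , 3] == cfg$frame_color[3])
  expect_gt(n_border, 0)
  crop <- crop_roi(img, c(4, 4, cfg$width - 4, cfg$height - 4))
  n_after <- sum(crop[, , 1] == cfg$frame_color[1] &
                   crop[, , 2] == cfg$frame_color[2] &
                   crop[, , 3] == cfg$frame_color[3])
  expect_equal(n_after, 0)
})

test_that("colour candidate masks apply interval predicates with hue wrap-around", {
  cfg <- seg_config(hsi_rule = list(h = c(60, 180), s = c(0, 1), i = c(0, 255)))
  green_img <- solid_color_image(c(0, 255, 0), 2, 2)
  m <- color_candidate_masks(green_img, cfg)
  expect_true(all(m$mask_hsi))

  cfg2 <- seg_config(lab_rule = list(l = c(0, 100), a = c(-128, -1), b = c(-128, 127)))
  gray_img <- solid_color_image(c(128, 128, 128), 2, 2)
  expect_false(any(color_candidate_masks(gray_img, cfg2)$mask_lab))

  # wrapped hue interval catches pure red (h = 0)
  cfg3 <- seg_config(hsi_rule = list(h = c(350, 10), s = c(0, 1), i = c(0, 255)))
  red_img <- solid_color_image(c(255, 0, 0), 2, 2)
  expect_true(all(color_candidate_masks(red_img, cfg3)$mask_hsi))
  # brute-force check of the wrapped predicate on a hue sweep
  hs <- seq(0, 359.5, by = 0.5)
  in_wrapped <- hs >= 350 | hs <= 10
  pred <- vapply(hs, function(h) h >= 350 || h <= 10, logical(1))
  expect_identical(pred, in_wrapped)

  bad <- seg_config(lab_rule = list(l = c(90, 10), a = c(-128, 127), b = c(-128, 127)))
  expect_error(color_candidate_masks(gray_img, bad),
               class = "phenodrought_invalid_argument")
})

test_that("combine_logical is the exact pixelwise boolean", {
  a <- matrix(TRUE, 4, 5); b <- matrix(FALSE, 4, 5)
  expect_true(all(combine_logical(a, b, "or")))
  expect_false(any(combine_logical(a, b, "and")))
  withr::with_seed(1, {
    x <- matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8)
    y <- matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8)
  })
  manual_and <- matrix(FALSE, 8, 8)
  manual_or <- matrix(FALSE, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    manual_and[r, c] <- x[r, c] && y[r, c]
    manual_or[r, c] <- x[r, c] || y[r, c]
  }
  expect_identical(combine_logical(x, y, "and"), manual_and)
  expect_identical(combine_logical(x, y, "or"), manual_or)
  expect_error(combine_logical(a, matrix(TRUE, 5, 4)),
               class = "phenodrought_invalid_argument")
})

test_that("adaptive threshold matches its definition on simple cases", {
  chan <- matrix(100, 12, 12)
  prior <- matrix(TRUE, 12, 12)
  expect_false(any(adaptive_threshold(chan, 5, offset = 1, prior)))

  chan2 <- matrix(0, 21, 21)
  chan2[9:13, 9:13] <- 200
  m <- adaptive_threshold(chan2, 11, offset = 10, prior = matrix(TRUE, 21, 21))
  expect_true(all(m[9:13, 9:13]))
  expect_false(any(m[1:5, ]))

  expect_false(any(adaptive_threshold(chan2, 11, 10, matrix(FALSE, 21, 21))))
  expect_error(adaptive_threshold(chan, 4, 0, prior),
               class = "phenodrought_invalid_argument")
})

test_that("adaptive threshold equals the exhaustive per-pixel oracle", {
  for (case in 1:8) {
    withr::with_seed(100 + case, {
      h <- sample(5:20, 1); w <- sample(5:20, 1)
      chan <- matrix(stats::runif(h * w, 0, 255), h, w)
      prior <- matrix(sample(c(TRUE, FALSE), h * w, TRUE, prob = c(0.7, 0.3)), h, w)
      window <- sample(c(3, 5, 7), 1)
      offset <- stats::runif(1, -20, 20)
    })
    expect_identical(adaptive_threshold(chan, window, offset, prior),
                     oracle_adaptive_threshold(chan, window, offset, prior))
  }
})

test_that("median filter keeps constants, removes speckle, matches the oracle", {
  allt <- matrix(TRUE, 6, 6)
  expect_identical(median_filter(allt, 3), allt)
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_false(any(median_filter(single, 3)))
  for (case in 1:8) {
    m <- random_mask(sample(20:120, 1), c(16, 16), seed = 200 + case)
    k <- sample(c(3, 5), 1)
    expect_identical(median_filter(m, k), oracle_median_filter(m, k))
  }
  expect_error(median_filter(allt, 2), class = "phenodrought_invalid_argument")
})

test_that("median filter with kernel 3 is near-idempotent on convex blobs", {
  blob <- matrix(FALSE, 20, 20)
  blob[5:15, 6:14] <- TRUE
  once <- median_filter(blob, 3)
  twice <- median_filter(once, 3)
  changed_first <- sum(blob != once)
  changed_second <- sum(once != twice)
  expect_lte(changed_second, changed_first)
})

test_that("morphological cleanup fills holes, drops small parts, erodes correctly", {
  sq <- matrix(FALSE, 12, 12)
  sq[2:11, 2:11] <- TRUE
  holed <- sq; holed[6, 6] <- FALSE
  expect_identical(morphological_clean(holed, 0, 0), sq)

  two <- matrix(FALSE, 30, 30)
  two[2:3, 2:3] <- TRUE           # area 4 (will vanish)
  two[10:27, 5:25] <- TRUE        # area 378 (survives)
  cleaned <- morphological_clean(two, 0, min_area = 50)
  expect_equal(sum(cleaned), 18 * 21)
  expect_false(any(cleaned[2:3, 2:3]))

  solid3 <- matrix(FALSE, 7, 7)
  solid3[3:5, 3:5] <- TRUE
  eroded <- morphological_clean(solid3, erosion_iters = 1, min_area = 0)
  expected <- matrix(FALSE, 7, 7); expected[4, 4] <- TRUE
  expect_identical(eroded, expected)

  # size-capped filling keeps large enclosed pockets open
  ring <- matrix(FALSE, 20, 20)
  ring[3:17, 3:17] <- TRUE
  ring[6:14, 6:14] <- FALSE   # 81-px pocket
  expect_identical(morphological_clean(ring, 0, 0, max_hole_area = 25), ring)
  expect_equal(sum(morphological_clean(ring, 0, 0, max_hole_area = Inf)), 15 * 15)
})

test_that("compose_objects unions components and flags empty masks", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[7:9, 7:9] <- TRUE
  comp <- compose_objects(m)
  expect_equal(comp$n_components, 2)
  expect_equal(sum(comp$mask), 4 + 9)
  expect_false(comp$no_plant)

  empty <- compose_objects(matrix(FALSE, 5, 5))
  expect_true(empty$no_plant)
  expect_false(any(empty$mask))

  single <- compose_objects(m & (row(m) < 5))
  expect_identical(single$mask, m & (row(m) < 5))
})

test_that("nearest-neighbour classification is exact for reference colours and ties to green", {
  green <- rbind(c(0, 200, 0))
  nongreen <- rbind(c(139, 69, 19))
  img <- solid_color_image(c(139, 69, 19), 3, 3)
  mask <- matrix(TRUE, 3, 3)
  cm <- classify_color_nn(img, mask, green, nongreen, space = "rgb")
  expect_true(all(cm == 2L))
  img2 <- solid_color_image(c(0, 200, 0), 3, 3)
  expect_true(all(classify_color_nn(img2, mask, green, nongreen, "rgb") == 1L))
  # equidistant pixel goes to green
  tie <- classify_color_nn(solid_color_image(c(10, 0, 0), 1, 1),
                           matrix(TRUE, 1, 1),
                           rbind(c(0, 0, 0)), rbind(c(20, 0, 0)), "rgb")
  expect_equal(tie[1, 1], 1L)
  expect_error(classify_color_nn(img, mask, green[0, , drop = FALSE], nongreen),
               class = "phenodrought_invalid_argument")
})

test_that("nearest-neighbour classification equals the exhaustive oracle", {
  green <- default_green_palette()
  nongreen <- default_nongreen_palette()
  for (case in 1:6) {
    withr::with_seed(300 + case, {
      h <- sample(4:10, 1); w <- sample(4:10, 1)
      img <- array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3))
      mask <- matrix(sample(c(TRUE, FALSE), h * w, TRUE), h, w)
    })
    for (space in c("rgb", "lab")) {
      expect_identical(classify_color_nn(img, mask, green, nongreen, space),
                       oracle_classify_nn(img, mask, green, nongreen, space))
    }
  }
})

test_that("the composed pipeline recovers the rendered plant faithfully", {
  g <- generate_genotypes(3, seed = 3)
  cfg <- render_config(noise_sd = 0, salt_pepper = 0)
  for (i in 1:3) {
    p <- grow_plant(g[i, ], "C", 80, seed = 40 + i)
    iset <- render_views(p, cfg, seed = 50 + i)
    seg <- segment_plant(iset$views$side_0, seg_config())
    tm <- iset$truth_mask$side_0
    iou <- sum(seg$mask & tm) / sum(seg$mask | tm)
    expect_gte(iou, 0.95)
  }
})

test_that("segmenting a background-only image flags no plant", {
  img <- solid_color_image(c(25, 28, 32), 80, 80)
  seg <- segment_plant(img, seg_config())
  expect_true(seg$no_plant)
  expect_false(any(seg$mask))
  expect_true(all(seg$class_map == 0L))
})

test_that("green/non-green fractions track the rendered senescence", {
  g <- demo_genotype()
  p <- grow_plant(g, "IB50FL50", 90, seed = 7, senescence = 0.3)
  iset <- render_views(p, render_config(noise_sd = 0, salt_pepper = 0), seed = 2)
  seg <- segment_plant(iset$views$side_0, seg_config())
  truth_frac <- sum(iset$truth_class$side_0 == 2L) / sum(iset$truth_class$side_0 > 0L)
  est_frac <- sum(seg$class_map == 2L) / sum(seg$class_map > 0L)
  expect_lt(abs(est_frac - truth_frac), 0.05)
})

test_that("class map partitions the final mask exactly", {
  g <- demo_genotype()
  p <- grow_plant(g, "IB40", 85, seed = 4)
  iset <- render_views(p, render_config(), seed = 6)
  seg <- segment_plant(iset$views$side_120, seg_config())
  expect_equal(sum(seg$class_map == 1L) + sum(seg$class_map == 2L), sum(seg$mask))
  expect_identical(seg$class_map > 0L, seg$mask)
})

test_that("cleaning never invents plant pixels outside filled holes", {
  g <- demo_genotype()
  p <- grow_plant(g, "C", 80, seed = 4)
  iset <- render_views(p, render_config(), seed = 6)
  seg <- segment_plant(iset$views$side_0, seg_config())
  # final mask (minus median smoothing and hole fills) stays inside the
  # colour-candidate mask: no pixels appear far from candidates
  extra <- seg$mask & !seg$stages$combined
  # every invented pixel must touch the smoothed mask (junction smoothing
  # or a filled pinhole), never lie in open background
  if (any(extra)) {
    grown <- seg$stages$smoothed
    nr <- nrow(grown); nc <- ncol(grown)
    for (rep in 1:2) {
      grown <- grown |
        rbind(grown[-1, ], FALSE) | rbind(FALSE, grown[-nr, ]) |
        cbind(grown[, -1], FALSE) | cbind(FALSE, grown[, -nc])
    }
    expect_true(all(grown[extra]))
  } else {
    succeed()
  }
})
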