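# Segmentation: raw RGB view -> composed plant mask + green/non-green classes.
#
# Conventions used by every windowed operator:
#   * masks are logical matrices, rows = image rows (y), cols = x;
#   * window/kernel sizes are odd; borders are mirrored (symmetric
#     reflection, edge pixel repeated);
#   * connected components are 8-connected (thin diagonal stems), hole
#     filling regards the background as 4-connected.

#' Segmentation configuration
#'
#' Bundles every tunable of the segmentation pipeline. The colour rules are
#' per-channel interval predicates: a pixel is a plant *candidate* in a
#' colour space when it satisfies all of that space's intervals. The hue
#' interval may wrap across 0 degrees (e.g. `c(350, 10)`).
#'
#' Defaults are chosen for dark-cabinet glasshouse imagery: a generous
#' union (`combine_op = "or"`) of an HSI rule (saturated, reasonably bright,
#' hue from yellow-brown through green) and a Lab rule (positive b*, i.e.
#' yellow-to-green vegetation) keeps both healthy and senescent tissue,
#' after which adaptive thresholding on intensity removes residual
#' background and the cleanup stages remove speckle. The threshold window
#' (101 px) is wide relative to the canopy so the local mean stays anchored
#' to the dark background even inside dense plant regions.
#'
#' @param roi Optional ROI as `c(x0, y0, x1, y1)` (half-open, 0-based);
#'   default is the full frame inset by `roi_margin` pixels on every side.
#' @param roi_margin Margin (pixels) removed on each side when `roi` is NULL.
#' @param hsi_rule,lab_rule Lists of channel intervals: `h`, `s`, `i` and
#'   `l`, `a`, `b` respectively, each `c(lower, upper)`.
#' @param combine_op `"or"` or `"and"`: how the HSI and Lab candidate masks
#'   are merged.
#' @param window Odd window size (pixels) of the adaptive threshold.
#' @param offset Signed intensity offset of the adaptive threshold.
#' @param median_kernel Odd kernel size of the binary median filter.
#' @param erosion_iters Binary erosion iterations (3x3 cross element).
#' @param min_component_area Components smaller than this (pixels) are
#'   dropped.
#' @param max_hole_area Largest enclosed hole (pixels) filled during
#'   cleanup; pinholes from sensor speckle are repaired while genuine
#'   background pockets between branches are kept.
#' @param green_palette,nongreen_palette n x 3 matrices of 8-bit RGB
#'   reference colours for the nearest-neighbour tissue classification.
#' @param classify_space `"lab"` or `"rgb"`: space in which nearest
#'   reference colours are sought.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(roi = NULL,
                       roi_margin = 0,
                       hsi_rule = list(h = c(15, 180), s = c(0.2, 1), i = c(40, 255)),
                       lab_rule = list(l = c(20, 100), a = c(-128, 127), b = c(15, 127)),
                       combine_op = c("or", "and"),
                       window = 101,
                       offset = -5,
                       median_kernel = 3,
                       erosion_iters = 0,
                       min_component_area = 50,
                       max_hole_area = 5,
                       green_palette = default_green_palette(),
                       nongreen_palette = default_nongreen_palette(),
                       classify_space = c("lab", "rgb")) {
  combine_op <- match.arg(combine_op)
  classify_space <- match.arg(classify_space)
  if (window %% 2 == 0 || window < 3) stop_invalid("`window` must be odd and >= 3")
  if (median_kernel %% 2 == 0 || median_kernel < 3) {
    stop_invalid("`median_kernel` must be odd and >= 3")
  }
  check_scalar_number(erosion_iters, "erosion_iters", min = 0)
  check_scalar_number(min_component_area, "min_component_area", min = 0)
  if (!nrow(green_palette) || !nrow(nongreen_palette)) {
    stop_invalid("both palette classes must be non-empty")
  }
  structure(
    list(roi = roi, roi_margin = roi_margin,
         hsi_rule = hsi_rule, lab_rule = lab_rule, combine_op = combine_op,
         window = as.integer(window), offset = offset,
         median_kernel = as.integer(median_kernel),
         erosion_iters = as.integer(erosion_iters),
         min_component_area = min_component_area,
         max_hole_area = max_hole_area,
         green_palette = green_palette, nongreen_palette = nongreen_palette,
         classify_space = classify_space),
    class = "seg_config"
  )
}

#' @rdname seg_config
#' @export
default_green_palette <- function() {
  rbind(c(50, 140, 60), c(80, 160, 70), c(35, 110, 45))
}

#' @rdname seg_config
#' @export
default_nongreen_palette <- function() {
  rbind(c(150, 110, 40), c(190, 170, 60), c(120, 90, 35))
}

#' Crop an image to a region of interest
#'
#' The ROI is a half-open rectangle in 0-based pixel coordinates:
#' `x0 <= x < x1`, `y0 <= y < y1`. Cropping removes imaging-unit pixels
#' (cabinet edges, conveyor hardware) before any colour analysis.
#'
#' @param img Numeric H x W x 3 array.
#' @param roi `c(x0, y0, x1, y1)`.
#' @return The cropped image; pixel (0,0) of the output is pixel
#'   `(x0, y0)` of the input.
#' @export
crop_roi <- function(img, roi) {
  check_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  roi <- as.numeric(roi)
  if (length(roi) != 4) stop_invalid("`roi` must be c(x0, y0, x1, y1)")
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h || x0 >= x1 || y0 >= y1) {
    stop_invalid("`roi` lies outside the image or is empty")
  }
  img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
}

roi_or_default <- function(cfg, h, w) {
  if (!is.null(cfg$roi)) return(cfg$roi)
  m <- cfg$roi_margin
  c(m, m, w - m, h - m)
}

interval_mask <- function(chan, bounds, circular = FALSE) {
  lo <- bounds[1]; up <- bounds[2]
  if (!circular && lo > up) stop_invalid("interval lower bound exceeds upper bound")
  if (circular && lo > up) {
    chan >= lo | chan <= up
  } else {
    chan >= lo & chan <= up
  }
}

#' Colour-space candidate masks
#'
#' Evaluates the HSI and Lab interval rules of a [seg_config()] on an image
#' and returns one candidate mask per colour space; each mask is the
#' pixelwise conjunction of that space's channel intervals. The hue
#' interval is circular and may wrap across 0 degrees.
#'
#' @param img Numeric H x W x 3 array.
#' @param cfg A [seg_config()].
#' @return `list(mask_hsi = , mask_lab = )` of logical matrices.
#' @export
color_candidate_masks <- function(img, cfg) {
  check_rgb(img)
  hsi <- to_hsi(img)
  lab <- to_lab(img)
  mask_hsi <- interval_mask(hsi$h, cfg$hsi_rule$h, circular = TRUE) &
    interval_mask(hsi$s, cfg$hsi_rule$s) &
    interval_mask(hsi$i, cfg$hsi_rule$i)
  mask_lab <- interval_mask(lab$l, cfg$lab_rule$l) &
    interval_mask(lab$a, cfg$lab_rule$a) &
    interval_mask(lab$b, cfg$lab_rule$b)
  list(mask_hsi = mask_hsi, mask_lab = mask_lab)
}

#' Combine two binary masks with a logical operation
#'
#' @param a,b Logical matrices of identical dimensions.
#' @param op `"and"` or `"or"`.
#' @return The pixelwise combination.
#' @export
combine_logical <- function(a, b, op = c("or", "and")) {
  op <- match.arg(op)
  check_mask(a, "a"); check_mask(b, "b")
  if (!identical(dim(a), dim(b))) stop_invalid("mask dimensions differ")
  if (op == "and") a & b else a | b
}

# Symmetric (mirror, edge-repeated) index folding for border handling.
mirror_index <- function(idx, n) {
  # idx may lie in (1 - p) .. (n + p); fold until inside 1..n
  period <- 2 * n
  idx <- ((idx - 1) %% period + period) %% period  # 0 .. 2n-1
  ifelse(idx < n, idx + 1, 2 * n - idx)
}

pad_mirror <- function(mat, p) {
  n_r <- nrow(mat); n_c <- ncol(mat)
  rows <- mirror_index(seq(1 - p, n_r + p), n_r)
  cols <- mirror_index(seq(1 - p, n_c + p), n_c)
  mat[rows, cols, drop = FALSE]
}

# Sum over a k x k window at every pixel, mirrored borders; via integral image.
box_sum <- function(mat, k) {
  p <- (k - 1) / 2
  padded <- pad_mirror(mat, p)
  s <- apply(padded, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))  # integral image with zero border
  n_r <- nrow(mat); n_c <- ncol(mat)
  r0 <- seq_len(n_r); c0 <- seq_len(n_c)        # top-left in padded coords
  r1 <- r0 + k; c1 <- c0 + k                    # bottom-right + 1
  s[r1, c1] - s[r0, c1] - s[r1, c0] + s[r0, c0]
}

#' Adaptive (local-mean) thresholding
#'
#' A pixel survives when the prior mask is true there *and* the channel
#' value exceeds the local mean over a `window x window` neighbourhood
#' (mirrored borders) plus `offset`. With a dark imaging background this
#' removes residual background from the colour candidate mask.
#'
#' @param chan Numeric matrix (typically the intensity channel).
#' @param window Odd window size >= 3.
#' @param offset Signed offset added to the local mean.
#' @param prior Logical matrix; the mask being refined.
#' @return Logical matrix.
#' @export
adaptive_threshold <- function(chan, window, offset, prior) {
  if (window %% 2 == 0 || window < 3) stop_invalid("`window` must be odd and >= 3")
  check_mask(prior, "prior")
  if (!identical(dim(chan), dim(prior))) stop_invalid("dimensions differ")
  local_mean <- box_sum(chan, window) / window^2
  prior & (chan > local_mean + offset)
}

#' Binary median (majority) filter
#'
#' Each pixel is replaced by the majority value of its odd-sized square
#' neighbourhood (mirrored borders); on a binary mask the median is the
#' majority vote, which smooths edges and removes isolated pixels.
#'
#' @param mask Logical matrix.
#' @param kernel Odd kernel size >= 3.
#' @return Logical matrix.
#' @export
median_filter <- function(mask, kernel) {
  if (kernel %% 2 == 0 || kernel < 3) stop_invalid("`kernel` must be odd and >= 3")
  check_mask(mask)
  box_sum(mask + 0, kernel) > kernel^2 / 2
}

# Binary erosion with the 3x3 cross element; pixels beyond the border
# count as background.
erode_cross <- function(mask) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, mask[-n_r, , drop = FALSE])
  left <- cbind(mask[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, mask[, -n_c, drop = FALSE])
  mask & up & down & left & right
}

# Label connected components of `mask`; returns an integer matrix
# (0 = background). 8- or 4-connectivity.
label_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  n_r <- nrow(mask)
  pos <- match(idx, idx)  # 1..n
  lookup <- integer(length(mask)); lookup[idx] <- pos
  offs <- if (connectivity == 8) {
    list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  } else {
    list(c(1, 0), c(0, 1))
  }
  edges <- integer(0)
  r <- (idx - 1) %% n_r + 1
  co <- (idx - 1) %/% n_r + 1
  for (o in offs) {
    r2 <- r + o[1]; c2 <- co + o[2]
    ok <- r2 >= 1 & r2 <= n_r & c2 >= 1 & c2 <= ncol(mask)
    nb <- (c2[ok] - 1) * n_r + r2[ok]
    hit <- lookup[nb] > 0
    if (any(hit)) {
      edges <- c(edges, rbind(pos[ok][hit], lookup[nb][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Morphological cleanup: erode, fill holes, drop small components
#'
#' Applies binary erosion (3x3 cross element) `erosion_iters` times, fills
#' fully enclosed holes (background regions not connected to the image
#' border, 4-connectivity), then removes 8-connected components with fewer
#' than `min_area` pixels. By default every enclosed hole is filled;
#' `max_hole_area` restricts filling to holes up to that size, so that
#' sensor speckle inside the plant is repaired without painting over the
#' genuine background pockets a branched silhouette encloses.
#'
#' @param mask Logical matrix.
#' @param erosion_iters Number of erosion passes (>= 0).
#' @param min_area Minimum surviving component area in pixels.
#' @param max_hole_area Largest hole (pixels) that is filled; `Inf` fills
#'   all enclosed holes.
#' @return Logical matrix.
#' @export
morphological_clean <- function(mask, erosion_iters = 0, min_area = 0,
                                max_hole_area = Inf) {
  check_mask(mask)
  check_scalar_number(erosion_iters, "erosion_iters", min = 0)
  for (i in seq_len(erosion_iters)) mask <- erode_cross(mask)
  # fill holes: background components not touching the border
  bg <- label_components(!mask, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  hole_sizes <- tabulate(bg[bg > 0])
  fillable <- setdiff(which(hole_sizes <= max_hole_area), border_labels)
  mask <- mask | (bg > 0 & (bg %in% fillable))
  if (min_area > 0) {
    comp <- label_components(mask, connectivity = 8)
    keep <- which(tabulate(comp[comp > 0]) >= min_area)
    mask <- matrix(comp %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Compose surviving objects into a single plant object
#'
#' The imaging facility guarantees one plant per image, so all surviving
#' components are treated as one object (their union); downstream traits
#' are computed on the union. An empty mask is not an error: it is
#' returned as-is with a `no_plant` flag.
#'
#' @param mask Logical matrix.
#' @return `list(mask = , no_plant = , n_components = )`.
#' @export
compose_objects <- function(mask) {
  check_mask(mask)
  comp <- label_components(mask, connectivity = 8)
  n <- max(comp)
  list(mask = mask, no_plant = !any(mask), n_components = n)
}

#' Nearest-neighbour green / non-green tissue classification
#'
#' Every plant pixel is assigned the class of its nearest reference colour
#' by Euclidean distance in the chosen space (`"lab"` by default, where
#' perceptual distances are more uniform than in RGB). Ties are broken
#' toward green for determinism. Non-plant pixels are background.
#'
#' @param img Numeric H x W x 3 array.
#' @param mask Logical plant mask of matching dimensions.
#' @param green_palette,nongreen_palette n x 3 matrices of reference RGB
#'   colours (both non-empty).
#' @param space `"lab"` or `"rgb"`.
#' @return An integer matrix class map: 0 background, 1 green, 2 non-green.
#' @export
classify_color_nn <- function(img, mask,
                              green_palette = default_green_palette(),
                              nongreen_palette = default_nongreen_palette(),
                              space = c("lab", "rgb")) {
  space <- match.arg(space)
  check_rgb(img); check_mask(mask)
  if (!identical(dim(img)[1:2], dim(mask))) stop_invalid("dimensions differ")
  if (is.null(dim(green_palette)) || is.null(dim(nongreen_palette)) ||
      !nrow(green_palette) || !nrow(nongreen_palette)) {
    stop_invalid("both palette classes must be non-empty n x 3 matrices")
  }
  cm <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(cm)
  n_px <- nrow(mask) * ncol(mask)
  px <- cbind(img[idx], img[idx + n_px], img[idx + 2 * n_px])
  refs <- rbind(green_palette, nongreen_palette)
  if (space == "lab") {
    px <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
    refs <- rgb_refs_to_lab(refs)
  }
  d2 <- outer(rowSums(px^2), rowSums(refs^2), "+") - 2 * px %*% t(refs)
  n_green <- nrow(green_palette)
  d_green <- apply(d2[, seq_len(n_green), drop = FALSE], 1, min)
  d_non <- apply(d2[, -seq_len(n_green), drop = FALSE], 1, min)
  cm[idx] <- ifelse(d_green <= d_non, 1L, 2L)  # ties go to green
  cm
}

#' Segment one plant view
#'
#' Runs the full per-view pipeline: ROI crop, HSI and Lab colour-candidate
#' masks, logical combination, adaptive thresholding on intensity, binary
#' median filtering, morphological cleanup (erode / fill / drop small),
#' object composition, and nearest-neighbour green vs non-green
#' classification.
#'
#' @param img Numeric H x W x 3 array, 8-bit channel values.
#' @param cfg A [seg_config()].
#' @return An object of class `segmentation`: `class_map` (0 background,
#'   1 green, 2 non-green), `mask` (logical plant mask), `no_plant` flag,
#'   `n_components` found before composition, `roi` used, and `stages`, a
#'   named list of intermediate masks for debugging.
#' @export
segment_plant <- function(img, cfg = seg_config()) {
  check_rgb(img)
  roi <- roi_or_default(cfg, dim(img)[1], dim(img)[2])
  cropped <- crop_roi(img, roi)
  cand <- color_candidate_masks(cropped, cfg)
  combined <- combine_logical(cand$mask_hsi, cand$mask_lab, cfg$combine_op)
  intensity <- to_hsi(cropped)$i
  thresholded <- adaptive_threshold(intensity, cfg$window, cfg$offset, combined)
  smoothed <- median_filter(thresholded, cfg$median_kernel)
  cleaned <- morphological_clean(smoothed, cfg$erosion_iters,
                                 cfg$min_component_area, cfg$max_hole_area)
  composed <- compose_objects(cleaned)
  class_map <- classify_color_nn(cropped, composed$mask,
                                 cfg$green_palette, cfg$nongreen_palette,
                                 cfg$classify_space)
  structure(
    list(class_map = class_map, mask = composed$mask,
         no_plant = composed$no_plant, n_components = composed$n_components,
         roi = roi,
         stages = list(mask_hsi = cand$mask_hsi, mask_lab = cand$mask_lab,
                       combined = combined, thresholded = thresholded,
                       smoothed = smoothed, cleaned = cleaned)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>", paste(dim(x$mask), collapse = " x "), "px;",
      sum(x$mask), "plant px (", sum(x$class_map == 1L), "green /",
      sum(x$class_map == 2L), "non-green )",
      if (x$no_plant) "- NO PLANT DETECTED" else "", "\n")
  invisible(x)
}
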