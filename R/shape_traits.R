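# Digital shape traits computed from segmented plant masks.
#
# All geometric descriptors are computed on true-pixel CENTRES (0-based
# x = column, y = row), so the convex-hull area of a single pixel is 0
# while pixel-count "areas" (ESB, green/non-green) count pixels.

#' Estimated shoot biomass from four views
#'
#' ESB is the number of plant pixels summed over the three side views and
#' the top view, in kilopixels — the standard non-destructive biomass proxy
#' of conveyor phenotyping platforms.
#'
#' @param masks Named list of four logical masks keyed `side_0`, `side_120`,
#'   `side_240`, `top`.
#' @return ESB in kilopixels.
#' @examples
#' m <- matrix(TRUE, 10, 10)
#' estimated_shoot_biomass(list(side_0 = m, side_120 = m, side_240 = m, top = m))
#' @export
estimated_shoot_biomass <- function(masks) {
  need <- c("side_0", "side_120", "side_240", "top")
  if (!all(need %in% names(masks))) {
    stop_invalid(paste("missing view(s):",
                       paste(setdiff(need, names(masks)), collapse = ", ")))
  }
  sum(vapply(masks[need], sum, numeric(1))) / 1000
}

#' Green and non-green pixel counts of a class map
#'
#' @param cm Integer class map (0 background, 1 green, 2 non-green).
#' @return Named numeric vector `c(green = , non_green = )`.
#' @export
green_nongreen_counts <- function(cm) {
  c(green = sum(cm == 1L), non_green = sum(cm == 2L))
}

#' Axis-aligned bounding box of a mask
#'
#' Tightest half-open box over true-pixel centres; `x1`/`y1` are exclusive
#' (max + 1), so the area of a single pixel's box is 1.
#'
#' @param mask Logical matrix.
#' @return `list(x0, y0, x1, y1, area, empty)`.
#' @export
bounding_box <- function(mask) {
  check_mask(mask)
  pts <- mask_points(mask)
  if (!nrow(pts)) {
    return(list(x0 = 0, y0 = 0, x1 = 0, y1 = 0, area = 0, empty = TRUE))
  }
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1]) + 1
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2]) + 1
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
       area = (x1 - x0) * (y1 - y0), empty = FALSE)
}

# Convex hull vertices (counter-clockwise) of an n x 2 point matrix;
# NULL when fewer than 3 distinct points or all collinear.
hull_vertices <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(NULL)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[h, , drop = FALSE]
  if (nrow(v) < 3) return(NULL)
  v
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Convex hull area of a mask
#'
#' Shoelace area of the convex hull of true-pixel centres; degenerate
#' masks (fewer than three non-collinear pixels) have area 0.
#'
#' @param mask Logical matrix.
#' @return Area in squared pixels.
#' @export
convex_hull_area <- function(mask) {
  check_mask(mask)
  v <- hull_vertices(mask_points(mask))
  if (is.null(v)) return(0)
  shoelace(v)
}

#' Caliper length of a mask
#'
#' `mode = "feret"` (default): the maximum Feret diameter, i.e. the largest
#' Euclidean distance between any two true-pixel centres (attained at hull
#' vertices). `mode = "vertical"`: the vertical extent (max row - min row),
#' the literal top-to-bottom reading of plant height.
#'
#' @param mask Logical matrix.
#' @param mode `"feret"` or `"vertical"`.
#' @return Length in pixels (0 for empty or single-pixel masks).
#' @export
caliper_length <- function(mask, mode = c("feret", "vertical")) {
  mode <- match.arg(mode)
  check_mask(mask)
  pts <- unique(mask_points(mask))
  if (nrow(pts) < 2) return(0)
  if (mode == "vertical") return(max(pts[, 2]) - min(pts[, 2]))
  v <- hull_vertices(pts)
  if (is.null(v)) v <- pts  # collinear: all-pairs on the (few) points
  max(dist(v))
}

#' Minimum-area enclosing rectangle of a mask
#'
#' Rotating-calipers construction on the convex hull of true-pixel
#' centres: the optimal rectangle has a side collinear with a hull edge,
#' so the exact minimum is the smallest rotated bounding box over all hull
#' edge directions. Collinear point sets have area 0.
#'
#' @param mask Logical matrix.
#' @return `list(area, corners, angle)`: area in squared pixels, the four
#'   rectangle corners (4 x 2 matrix, pixel-centre coordinates), and the
#'   rectangle orientation in radians.
#' @export
min_area_rectangle <- function(mask) {
  check_mask(mask)
  pts <- unique(mask_points(mask))
  if (nrow(pts) < 3) {
    return(list(area = 0, corners = NULL, angle = 0))
  }
  v <- hull_vertices(pts)
  if (is.null(v)) return(list(area = 0, corners = NULL, angle = 0))
  edges <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- list(area = Inf, corners = NULL, angle = 0)
  for (th in angles) {
    # rotate by -th so the edge direction lands on the x-axis
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    p <- v %*% rot
    xr <- range(p[, 1]); yr <- range(p[, 2])
    area <- diff(xr) * diff(yr)
    if (area < best$area) {
      corners <- cbind(c(xr[1], xr[2], xr[2], xr[1]),
                       c(yr[1], yr[1], yr[2], yr[2])) %*% t(rot)
      best <- list(area = area, corners = corners, angle = th)
    }
  }
  best
}

#' Compile per-plant digital traits from segmented views
#'
#' Aggregates per-view class maps into one row of digital traits per plant
#' per timepoint: ESB (all four views, kilopixels), a green-tissue-only
#' ESB, green/non-green pixel counts, and shape descriptors (convex hull
#' area, caliper length, minimum-area rectangle, bounding box) from the
#' `side_0` view. Per-view shape values for all views are attached as the
#' `"per_view"` attribute (a tidy tibble) and via [traits_long()].
#'
#' @param x A tibble with columns `plant_id`, `day`, `view`, and
#'   `class_map` (a list column of integer class maps, 0/1/2).
#' @return A tibble with one row per `plant_id` x `day`: `esb`,
#'   `esb_green`, `green_px`, `nongreen_px`, `cha`, `cl`, `mar_area`,
#'   `bb_area`, `empty`, `incomplete`.
#' @export
compile_digital_traits <- function(x) {
  stopifnot(all(c("plant_id", "day", "view", "class_map") %in% names(x)))
  need <- c("side_0", "side_120", "side_240", "top")
  per_view <- x |>
    mutate(mask = map(.data$class_map, ~ .x > 0L)) |>
    mutate(
      plant_px = map_dbl(.data$mask, sum),
      green_px = map_dbl(.data$class_map, ~ sum(.x == 1L)),
      nongreen_px = map_dbl(.data$class_map, ~ sum(.x == 2L)),
      cha = map_dbl(.data$mask, convex_hull_area),
      cl = map_dbl(.data$mask, caliper_length),
      mar_area = map_dbl(.data$mask, ~ min_area_rectangle(.x)$area),
      bb_area = map_dbl(.data$mask, ~ bounding_box(.x)$area)
    ) |>
    select(-"class_map", -"mask")
  wide <- per_view |>
    group_by(.data$plant_id, .data$day) |>
    summarise(
      incomplete = !all(need %in% .data$view),
      esb = ifelse(.data$incomplete[1], NA_real_, sum(.data$plant_px) / 1000),
      esb_green = ifelse(.data$incomplete[1], NA_real_, sum(.data$green_px) / 1000),
      green_px = sum(.data$green_px),
      nongreen_px = sum(.data$nongreen_px),
      cha = .data$cha[match("side_0", .data$view)],
      cl = .data$cl[match("side_0", .data$view)],
      mar_area = .data$mar_area[match("side_0", .data$view)],
      bb_area = .data$bb_area[match("side_0", .data$view)],
      empty = sum(.data$plant_px) == 0,
      .groups = "drop"
    )
  wide[is.na(wide$cha) & !wide$incomplete, c("cha", "cl", "mar_area", "bb_area")] <- 0
  attr(wide, "per_view") <- per_view
  wide
}

#' Long-format per-view traits
#'
#' @param traits The result of [compile_digital_traits()].
#' @return A tidy tibble `(plant_id, day, view, trait, value)`.
#' @export
traits_long <- function(traits) {
  pv <- attr(traits, "per_view")
  if (is.null(pv)) stop_invalid("`traits` must come from compile_digital_traits()")
  pv |>
    tidyr::pivot_longer(cols = c("plant_px", "green_px", "nongreen_px",
                                 "cha", "cl", "mar_area", "bb_area"),
                        names_to = "trait", values_to = "value")
}
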