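# Rendering: project 3-D plant geometry into the four camera views and
# paint an 8-bit RGB raster with pixel-level ground truth.
#
# Each view is an independent 2-D silhouette projection (no perspective,
# no occlusion model): side views project onto the vertical plane of the
# camera azimuth, the top view onto the ground plane. Sufficient to
# exercise segmentation and shape traits; not a photorealistic renderer.

#' Rendering configuration
#'
#' @param width,height Image dimensions in pixels (>= 64).
#' @param px_per_mm Image scale.
#' @param background Background RGB (dark imaging-cabinet grey).
#' @param frame_margin Width (pixels) of the cabinet-frame band painted
#'   inside the image border; 0 disables it.
#' @param frame_color Frame RGB.
#' @param green_palette,nongreen_palette n x 3 RGB matrices organs are
#'   coloured from (one colour per organ, drawn under the render seed).
#' @param noise_sd Additive Gaussian noise sd on each channel (8-bit
#'   units); default 8.
#' @param salt_pepper Salt-and-pepper rate (fraction of pixels forced to
#'   0 or 255); default 0.001.
#' @return A list of class `render_config`.
#' @export
render_config <- function(width = 144, height = 144, px_per_mm = 0.6,
                          background = c(25, 28, 32),
                          frame_margin = 0, frame_color = c(90, 90, 95),
                          green_palette = default_green_palette(),
                          nongreen_palette = default_nongreen_palette(),
                          noise_sd = 8, salt_pepper = 0.001) {
  if (width < 64 || height < 64) stop_invalid("image dimensions must be >= 64 x 64")
  if (is.null(dim(green_palette)) || !nrow(green_palette) ||
      is.null(dim(nongreen_palette)) || !nrow(nongreen_palette)) {
    stop_invalid("palettes must be non-empty n x 3 matrices")
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(salt_pepper, "salt_pepper", min = 0, max = 1)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         px_per_mm = px_per_mm, background = background,
         frame_margin = as.integer(frame_margin), frame_color = frame_color,
         green_palette = green_palette, nongreen_palette = nongreen_palette,
         noise_sd = noise_sd, salt_pepper = salt_pepper),
    class = "render_config"
  )
}

#' View keys of an image set
#' @export
VIEW_KEYS <- c("side_0", "side_120", "side_240", "top")

# Project one organ row into 2-D pixel coordinates for a view.
# Returns list(type, p0, p1, half_width) or list(type, centre, radius),
# in 0-based pixel-centre coordinates (x right, y down).
project_organ <- function(org, view, cfg, scale = 1) {
  ppm <- cfg$px_per_mm * scale
  w <- cfg$width * scale; h <- cfg$height * scale
  to_px_side <- function(x, y, z, azim) {
    u <- -x * sin(azim) + y * cos(azim)
    cbind(u * ppm + (w - 1) / 2, (h - 3 * scale) - z * ppm)
  }
  to_px_top <- function(x, y) {
    cbind(x * ppm + (w - 1) / 2, (h - 1) / 2 - y * ppm)
  }
  proj <- function(x, y, z) {
    switch(view,
      side_0 = to_px_side(x, y, z, 0),
      side_120 = to_px_side(x, y, z, 2 * pi / 3),
      side_240 = to_px_side(x, y, z, 4 * pi / 3),
      top = to_px_top(x, y),
      stop_invalid(paste("unknown view:", view)))
  }
  if (org$type == "segment") {
    list(type = "segment",
         p0 = proj(org$x0, org$y0, org$z0),
         p1 = proj(org$x1, org$y1, org$z1),
         half_width = org$size * ppm / 2)
  } else {
    list(type = "disc",
         centre = proj(org$x0, org$y0, org$z0),
         radius = org$size * ppm)
  }
}

# Logical mask of pixels covered by a projected primitive on an h x w grid.
rasterize_primitive <- function(prim, h, w) {
  mask <- matrix(FALSE, h, w)
  if (prim$type == "disc") {
    cx <- prim$centre[1]; cy <- prim$centre[2]; r <- prim$radius
    lo_x <- max(0, floor(cx - r)); hi_x <- min(w - 1, ceiling(cx + r))
    lo_y <- max(0, floor(cy - r)); hi_y <- min(h - 1, ceiling(cy + r))
    if (lo_x > hi_x || lo_y > hi_y) return(mask)
    xs <- lo_x:hi_x; ys <- lo_y:hi_y
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    mask[cbind(rep(ys + 1, length(xs))[as.vector(d2 <= r^2)],
               rep(xs + 1, each = length(ys))[as.vector(d2 <= r^2)])] <- TRUE
    return(mask)
  }
  p0 <- prim$p0; p1 <- prim$p1; hw <- prim$half_width
  lo_x <- max(0, floor(min(p0[1], p1[1]) - hw))
  hi_x <- min(w - 1, ceiling(max(p0[1], p1[1]) + hw))
  lo_y <- max(0, floor(min(p0[2], p1[2]) - hw))
  hi_y <- min(h - 1, ceiling(max(p0[2], p1[2]) + hw))
  if (lo_x > hi_x || lo_y > hi_y) return(mask)
  xs <- lo_x:hi_x; ys <- lo_y:hi_y
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) rep(0, length(gx)) else {
    pmin(1, pmax(0, ((gx - p0[1]) * dx + (gy - p0[2]) * dy) / len2))
  }
  d2 <- (gx - (p0[1] + t * dx))^2 + (gy - (p0[2] + t * dy))^2
  hit <- d2 <= hw^2
  mask[cbind(gy[hit] + 1, gx[hit] + 1)] <- TRUE
  mask
}

# Rasterize all organs of a geometry for one view.
# Returns list(mask, class (0/1/2), organ_masks) at the given supersample
# scale. Later organs overwrite earlier ones in the class map.
rasterize_view <- function(p, view, cfg, scale = 1, keep_organ_masks = FALSE) {
  h <- cfg$height * scale; w <- cfg$width * scale
  mask <- matrix(FALSE, h, w)
  cls <- matrix(0L, h, w)
  organ_masks <- if (keep_organ_masks) vector("list", nrow(p$organs)) else NULL
  for (i in seq_len(nrow(p$organs))) {
    org <- p$organs[i, ]
    m <- rasterize_primitive(project_organ(org, view, cfg, scale), h, w)
    mask <- mask | m
    cls[m] <- if (org$class == "green") 1L else 2L
    if (keep_organ_masks) organ_masks[[i]] <- m
  }
  list(mask = mask, class = cls, organ_masks = organ_masks)
}

#' Analytic projected silhouette area of a geometry
#'
#' Area (in view pixels squared) of the union of the projected organ
#' silhouettes, computed by supersampled rasterization (`scale` subpixels
#' per pixel edge) — exact up to rasterization error, and independent of
#' the 1x rendering grid.
#'
#' @param p A [grow_plant()] geometry.
#' @param view One of `VIEW_KEYS`.
#' @param cfg A [render_config()].
#' @param scale Supersampling factor (default 4).
#' @return Projected area in units of rendered pixels.
#' @export
projected_area <- function(p, view, cfg = render_config(), scale = 4) {
  sum(rasterize_view(p, view, cfg, scale = scale)$mask) / scale^2
}

#' Render the four camera views of a plant
#'
#' Paints each organ with a palette colour (green organs from the green
#' palette, senescent organs from the yellow/brown palette; one colour per
#' organ drawn under `seed`) over a dark cabinet background, then applies
#' additive Gaussian noise and salt-and-pepper speckle. Ground-truth masks
#' and class maps are returned alongside the rasters.
#'
#' @param p A [grow_plant()] geometry.
#' @param cfg A [render_config()].
#' @param seed Integer seed (organ colours and noise).
#' @param plant_id,day Identifiers carried into the image set.
#' @return An object of class `image_set`: `views` (named list of
#'   H x W x 3 arrays, 8-bit values), `truth_mask` (logical matrices),
#'   `truth_class` (0/1/2 integer matrices), `plant_id`, `day`.
#' @export
render_views <- function(p, cfg = render_config(), seed = 1,
                         plant_id = "plant", day = p$day) {
  stopifnot(inherits(p, "plant_geometry"))
  with_seed(seed, {
    n_org <- nrow(p$organs)
    col_idx <- ifelse(p$organs$class == "green",
                      sample.int(nrow(cfg$green_palette), n_org, replace = TRUE),
                      sample.int(nrow(cfg$nongreen_palette), n_org, replace = TRUE))
    views <- list(); truth_mask <- list(); truth_class <- list()
    for (view in VIEW_KEYS) {
      ras <- rasterize_view(p, view, cfg, scale = 1, keep_organ_masks = TRUE)
      h <- cfg$height; w <- cfg$width
      chans <- lapply(cfg$background, function(v) matrix(v, h, w))
      if (cfg$frame_margin > 0) {
        band <- matrix(FALSE, h, w)
        m <- cfg$frame_margin
        band[c(seq_len(m), h - seq_len(m) + 1), ] <- TRUE
        band[, c(seq_len(m), w - seq_len(m) + 1)] <- TRUE
        for (k in 1:3) chans[[k]][band] <- cfg$frame_color[k]
      }
      for (i in seq_len(n_org)) {
        m <- ras$organ_masks[[i]]
        colr <- if (p$organs$class[i] == "green") {
          cfg$green_palette[col_idx[i], ]
        } else {
          cfg$nongreen_palette[col_idx[i], ]
        }
        for (k in 1:3) chans[[k]][m] <- colr[k]
      }
      img <- array(0, dim = c(h, w, 3))
      for (k in 1:3) {
        ch <- chans[[k]]
        if (cfg$noise_sd > 0) ch <- ch + rnorm(h * w, 0, cfg$noise_sd)
        img[, , k] <- pmin(255, pmax(0, ch))
      }
      if (cfg$salt_pepper > 0) {
        n_sp <- stats::rbinom(1, h * w, cfg$salt_pepper)
        if (n_sp > 0) {
          px <- sample.int(h * w, n_sp)
          val <- sample(c(0, 255), n_sp, replace = TRUE)
          for (k in 1:3) {
            ch <- img[, , k]; ch[px] <- val; img[, , k] <- ch
          }
        }
      }
      img <- round(img)  # 8-bit quantisation
      views[[view]] <- img
      truth_mask[[view]] <- ras$mask
      truth_class[[view]] <- ras$class
    }
    structure(list(views = views, truth_mask = truth_mask,
                   truth_class = truth_class,
                   plant_id = plant_id, day = day),
              class = "image_set")
  })
}

#' Write an image set to PNG files
#'
#' Views as 8-bit RGB PNGs, truth masks as single-channel 0/255 PNGs.
#' Requires the `png` package.
#'
#' @param iset An [render_views()] image set.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_image_set <- function(iset, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_invalid("the `png` package is required to write images")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (view in names(iset$views)) {
    f <- file.path(dir, sprintf("%s_d%03d_%s.png", iset$plant_id, iset$day, view))
    png::writePNG(iset$views[[view]] / 255, f)
    fm <- file.path(dir, sprintf("%s_d%03d_%s_mask.png", iset$plant_id, iset$day, view))
    png::writePNG(iset$truth_mask[[view]] * 1, fm)
    paths <- c(paths, f, fm)
  }
  invisible(paths)
}

#' @export
print.image_set <- function(x, ...) {
  cat("<image_set>", x$plant_id, "day", x$day, "-",
      length(x$views), "views,",
      paste(dim(x$views[[1]])[1:2], collapse = " x "), "px\n")
  invisible(x)
}
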