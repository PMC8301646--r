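# Independent brute-force oracles and small fixture builders used across
# the suite. Every oracle is written from the operation's definition, not
# from the implementation it checks.

random_mask <- function(n_px, dim = c(32, 32), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, dim[1], dim[2])
    m[sample.int(prod(dim), min(n_px, prod(dim)))] <- TRUE
    m
  })
}

mask_pts <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# --- geometry oracles -------------------------------------------------------

# Gift-wrapping (Jarvis march) convex hull area via the shoelace formula.
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  v <- pts[hull, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# All-pairs maximum distance.
oracle_feret <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# Minimum-area rectangle by edge-aligned search over the oracle's own hull.
oracle_mar_edges <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  e <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  best <- Inf
  for (i in seq_len(nrow(e))) {
    th <- atan2(e[i, 2], e[i, 1])
    # rotation by -th aligns the edge with the x-axis
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    p <- v %*% rot
    best <- min(best, diff(range(p[, 1])) * diff(range(p[, 2])))
  }
  best
}

# Dense angle sweep: rectangle area at every angle on a 0.1-degree grid.
# Can only overestimate the true minimum.
oracle_mar_sweep <- function(pts, step_deg = 0.1) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  angles <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  for (th in angles) {
    rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    p <- v %*% rot
    best <- min(best, diff(range(p[, 1])) * diff(range(p[, 2])))
  }
  best
}

# --- per-pixel operator oracles --------------------------------------------

# symmetric (edge-repeated) mirroring of an out-of-range index
oracle_mirror <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_local_mean <- function(chan, window, r, c) {
  p <- (window - 1) / 2
  acc <- 0
  for (dr in -p:p) for (dc in -p:p) {
    acc <- acc + chan[oracle_mirror(r + dr, nrow(chan)),
                      oracle_mirror(c + dc, ncol(chan))]
  }
  acc / window^2
}

oracle_adaptive_threshold <- function(chan, window, offset, prior) {
  out <- matrix(FALSE, nrow(chan), ncol(chan))
  for (r in seq_len(nrow(chan))) for (c in seq_len(ncol(chan))) {
    out[r, c] <- prior[r, c] &&
      chan[r, c] > oracle_local_mean(chan, window, r, c) + offset
  }
  out
}

oracle_median_filter <- function(mask, kernel) {
  p <- (kernel - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    acc <- 0
    for (dr in -p:p) for (dc in -p:p) {
      acc <- acc + mask[oracle_mirror(r + dr, nrow(mask)),
                        oracle_mirror(c + dc, ncol(mask))]
    }
    out[r, c] <- acc > kernel^2 / 2
  }
  out
}

oracle_classify_nn <- function(img, mask, green, nongreen, space = "lab") {
  to_feat <- function(rgb) {
    if (space == "lab") {
      grDevices::convertColor(matrix(rgb / 255, ncol = 3),
                              from = "sRGB", to = "Lab")[1, ]
    } else {
      rgb
    }
  }
  cm <- matrix(0L, nrow(mask), ncol(mask))
  gf <- t(apply(green, 1, to_feat))
  nf <- t(apply(nongreen, 1, to_feat))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    f <- to_feat(c(img[r, c, 1], img[r, c, 2], img[r, c, 3]))
    dg <- min(colSums((t(gf) - f)^2))
    dn <- min(colSums((t(nf) - f)^2))
    cm[r, c] <- if (dg <= dn) 1L else 2L
  }
  cm
}

# --- linear-model oracle ----------------------------------------------------

# Adjusted genotype means by direct dense least squares on the cell-mean
# parameterisation: value ~ 0 + genotype + block (block sum-to-zero),
# adjusted mean = genotype coefficient (blocks average out).
oracle_blue <- function(df) {
  gl <- sort(unique(df$genotype))
  bl <- sort(unique(df$block))
  X_g <- outer(df$genotype, gl, "==") * 1
  # sum-to-zero block coding: last block = -(sum of others)
  X_b <- outer(df$block, bl[-length(bl)], "==") * 1 -
    (df$block == bl[length(bl)]) * 1
  X <- cbind(X_g, X_b)
  beta <- solve(t(X) %*% X, t(X) %*% df$value)
  stats::setNames(beta[seq_along(gl)], gl)
}

# --- misc fixtures ----------------------------------------------------------

solid_color_image <- function(rgb, h = 8, w = 8) {
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

demo_genotype <- function(sensitivity = 0.5, seed = 42) {
  g <- generate_genotypes(1, seed = seed)
  g$drought_sensitivity <- sensitivity
  g
}

# Balanced genotype x block table with known planted effects.
make_blocked_data <- function(n_g = 4, n_b = 3, sigma = 0.5, seed = 1,
                              block_effects = NULL) {
  withr::with_seed(seed, {
    geno_eff <- stats::rnorm(n_g, 50, 8)
    if (is.null(block_effects)) block_effects <- stats::rnorm(n_b, 0, 2)
    df <- tidyr::expand_grid(genotype = sprintf("G%02d", seq_len(n_g)),
                             block = sprintf("B%d", seq_len(n_b)))
    df$value <- geno_eff[match(df$genotype, sprintf("G%02d", seq_len(n_g)))] +
      block_effects[match(df$block, sprintf("B%d", seq_len(n_b)))] +
      stats::rnorm(nrow(df), 0, sigma)
    list(df = df, geno_eff = geno_eff)
  })
}
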