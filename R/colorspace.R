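#' Convert an RGB image to hue, saturation, intensity channels
#'
#' Uses the classical HSI decomposition on 8-bit channels: intensity
#' `I = (R + G + B) / 3` (0–255), saturation `S = 1 - min(R,G,B)/I` for
#' `I > 0` (0 otherwise), and hue from the standard angular formula in
#' degrees on \[0, 360). Hue is undefined for achromatic pixels and is set
#' to 0 there (with `S = 0`, so such pixels fail any saturated-hue rule).
#'
#' @param img Numeric H x W x 3 array, channels in \[0, 255\].
#' @return A list of three H x W matrices: `h` (degrees), `s` (\[0,1\]),
#'   `i` (\[0,255\]).
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_hsi(px) # h = 0, s = 1, i = 85
#' @export
to_hsi <- function(img) {
  check_rgb(img)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2])
  g <- matrix(img[, , 2], d[1], d[2])
  b <- matrix(img[, , 3], d[1], d[2])
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- ((r - g) + (r - b)) / 2
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1)) * 180 / pi
  h <- ifelse(den > 0, ifelse(b <= g, theta, 360 - theta), 0)
  h[h >= 360] <- 0
  list(h = h, s = s, i = i)
}

#' Convert an RGB image to CIE L*a*b* channels
#'
#' Standard sRGB (D65) to CIE L*a*b* conversion, including the sRGB gamma
#' linearisation, via [grDevices::convertColor()]. `L*` is lightness
#' (0–100), `a*` runs green (negative) to magenta (positive), `b*` blue
#' (negative) to yellow (positive).
#'
#' @inheritParams to_hsi
#' @return A list of three H x W matrices: `l`, `a`, `b`.
#' @export
to_lab <- function(img) {
  check_rgb(img)
  d <- dim(img)
  flat <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  list(l = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

# Lab coordinates of an n x 3 matrix of 8-bit RGB reference colours.
rgb_refs_to_lab <- function(refs) {
  grDevices::convertColor(refs / 255, from = "sRGB", to = "Lab")
}
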