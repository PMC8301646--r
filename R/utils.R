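# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003 * seq_len(n)) %% .Machine$integer.max
}

stop_invalid <- function(msg) {
  abort(msg, class = "phenodrought_invalid_argument")
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    stop_invalid(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(min), format(max)))
  }
  invisible(x)
}

# Binary mask = logical matrix (rows = y, cols = x, 0-based pixel coords).
check_mask <- function(mask, name = "mask") {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop_invalid(sprintf("`%s` must be a logical matrix", name))
  }
  invisible(mask)
}

# RGB image = numeric H x W x 3 array with channel values in [0, 255].
check_rgb <- function(img, name = "img") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop_invalid(sprintf("`%s` must be an H x W x 3 array", name))
  }
  invisible(img)
}

# Coordinates of true pixels as (x, y) centres, 0-based.
mask_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}
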