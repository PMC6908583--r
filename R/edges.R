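#' Canny edge-detection parameters
#'
#' The conditioning input of every class generator is the channel-wise Canny
#' edge map of a tile. `sigma` is the Gaussian smoothing SD in px of the
#' tile's native resolution; `sigma = 2` and `sigma = 5` are the shipped
#' presets. Hysteresis thresholds are expressed as fractions of the channel's
#' full 8-bit intensity range (gradient magnitudes are normalised to
#' intensity units), and are stored with every trained model so
#' classification always reuses the training-time conditioning. Absolute
#' thresholds make edge counts decrease monotonically with `sigma`:
#' heavier smoothing weakens every gradient.
#'
#' @param sigma Gaussian smoothing SD in px (> 0).
#' @param low_fraction Hysteresis low threshold as a fraction of the channel
#'   intensity range (255).
#' @param high_fraction Hysteresis high threshold, `> low_fraction`, `<= 1`.
#' @return An `edge_params` object.
#' @export
edge_params <- function(sigma = 2, low_fraction = 0.02, high_fraction = 0.04) {
  assert_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop_invalid("`sigma` must be > 0")
  assert_scalar_number(low_fraction, "low_fraction")
  assert_scalar_number(high_fraction, "high_fraction")
  if (low_fraction < 0 || low_fraction >= high_fraction || high_fraction > 1)
    stop_invalid("need 0 <= low_fraction < high_fraction <= 1")
  structure(list(sigma = sigma, low_fraction = low_fraction,
                 high_fraction = high_fraction),
            class = "edge_params")
}

# Reflective padding of a matrix by r pixels on every side.
pad_reflect <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(min(r, H))), seq_len(H), H + 1 - rev(seq_len(min(r, H))))
  if (r > H) stop_invalid("padding radius exceeds image size")
  ci <- c(rev(seq_len(min(r, W))), seq_len(W), W + 1 - rev(seq_len(min(r, W))))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with reflective borders.
gaussian_blur <- function(m, sigma, truncate = 3) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  p <- pad_reflect(m, r)
  # rows then cols, via shifted sums (BLAS-free but vectorised)
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0, H, W + 2 * r)
  for (i in seq_along(k)) acc <- acc + k[i] * p[(i - 1) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * acc[, (i - 1) + seq_len(W), drop = FALSE]
  out
}

# Shift a matrix by (dr, dc), zero-filling vacated entries.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Canny on a single channel (0-255 double matrix). Returns 0/1 matrix.
canny_channel <- function(m, params) {
  g <- gaussian_blur(m, params$sigma)
  gp <- pad_reflect(g, 1L)
  H <- nrow(m); W <- ncol(m)
  core <- function(dr, dc) gp[1 + dr + seq_len(H), 1 + dc + seq_len(W), drop = FALSE]
  # Sobel gradients: gx increases with column index, gy with row index
  gx <- (core(-1, 1) + 2 * core(0, 1) + core(1, 1)) -
        (core(-1, -1) + 2 * core(0, -1) + core(1, -1))
  gy <- (core(1, -1) + 2 * core(1, 0) + core(1, 1)) -
        (core(-1, -1) + 2 * core(-1, 0) + core(-1, 1))
  # normalise by the Sobel gain (4 for a unit step) so magnitudes are in
  # intensity units and thresholds can be absolute fractions of 255
  mag <- sqrt(gx * gx + gy * gy) / 4
  if (max(mag) == 0) return(matrix(0, H, W))

  # non-maximum suppression with linear interpolation of the two magnitude
  # samples one pixel away along the true gradient direction
  adx <- abs(gx); ady <- abs(gy)
  sdx <- ifelse(gx >= 0, 1L, -1L)   # column step of the gradient
  sdy <- ifelse(gy >= 0, 1L, -1L)   # row step of the gradient
  sh <- function(dr, dc) shift_mat(mag, dr, dc)
  S <- list()
  for (dr in -1:1) for (dc in -1:1)
    S[[paste(dr, dc)]] <- if (dr == 0 && dc == 0) mag else sh(dr, dc)
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  horiz <- adx >= ady
  w <- matrix(0, H, W)
  w[horiz] <- (ady / pmax(adx, .Machine$double.eps))[horiz]
  w[!horiz] <- (adx / pmax(ady, .Machine$double.eps))[!horiz]
  for (sy in c(-1L, 1L)) for (sx in c(-1L, 1L)) {
    msk <- horiz & sdy == sy & sdx == sx
    if (any(msk)) {
      a <- S[[paste(0L, sx)]]; b <- S[[paste(sy, sx)]]
      n1[msk] <- ((1 - w) * a + w * b)[msk]
      a <- S[[paste(0L, -sx)]]; b <- S[[paste(-sy, -sx)]]
      n2[msk] <- ((1 - w) * a + w * b)[msk]
    }
    msk <- !horiz & sdy == sy & sdx == sx
    if (any(msk)) {
      a <- S[[paste(sy, 0L)]]; b <- S[[paste(sy, sx)]]
      n1[msk] <- ((1 - w) * a + w * b)[msk]
      a <- S[[paste(-sy, 0L)]]; b <- S[[paste(-sy, -sx)]]
      n2[msk] <- ((1 - w) * a + w * b)[msk]
    }
  }
  nms <- mag
  nms[!(mag >= n1 & mag >= n2)] <- 0

  lo <- params$low_fraction * 255
  hi <- params$high_fraction * 255
  strong <- nms > hi
  weak <- nms > lo
  if (!any(strong)) return(matrix(0, H, W))

  # hysteresis: 8-connected propagation of strong into weak, to fixed point
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(cur, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  mode(cur) <- "numeric"
  cur
}

#' Compute the 3-channel edge condition of an RGB tile
#'
#' Channel `i` of the mask is the Canny edge map of tile channel `i` alone,
#' computed on the raw 0-255 intensities with the given smoothing `sigma` and
#' hysteresis thresholds. This is the generator's only input at inference;
#' it drains all color variation out of the tile, preserving structure.
#'
#' @param tile H x W x 3 array on the 0-255 scale, both dimensions >= 16.
#'   Grayscale or 4-channel inputs are an error (no silent conversion).
#' @param params An [edge_params()].
#' @return An `edge_condition`: list with `mask` (H x W x 3, values in
#'   \{0, 1\}), `params`, and `source_shape`.
#' @export
detect_edges <- function(tile, params = edge_params()) {
  assert_tile(tile)
  if (!inherits(params, "edge_params"))
    stop_invalid("`params` must be an edge_params object")
  d <- dim(tile)
  if (d[1] < 16L || d[2] < 16L)
    stop_invalid("tile must be at least 16 px in each dimension")
  mask <- array(0, dim = d)
  for (ch in 1:3) mask[, , ch] <- canny_channel(tile[, , ch], params)
  structure(list(mask = mask, params = params, source_shape = d[1:2]),
            class = "edge_condition")
}

#' Render an edge condition as an 8-bit RGB raster
#'
#' Edge pixels render at 255 in their own channel, so a pixel that is an
#' edge in all three channels renders white and single-channel edges render
#' in that channel's color.
#'
#' @param cond An `edge_condition` from [detect_edges()].
#' @return H x W x 3 array with values in \{0, 255\}.
#' @export
condition_to_raster <- function(cond) {
  if (!inherits(cond, "edge_condition"))
    stop_invalid("`cond` must be an edge_condition")
  cond$mask * 255
}

#' Edge-pixel fraction of a condition
#'
#' Mean over all channels and pixels of the binary mask; a summary of how
#' much structure the condition carries.
#' @param cond An `edge_condition`.
#' @return Scalar in [0, 1].
#' @export
edge_density <- function(cond) {
  if (!inherits(cond, "edge_condition"))
    stop_invalid("`cond` must be an edge_condition")
  mean(cond$mask)
}
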