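#' Define a synthetic texture class
#'
#' A texture class emulates one tissue population as seen in small H&E tile
#' crops: elliptical nucleus-like blobs (optionally with a gland/ring motif)
#' and wavy fiber strokes drawn over a background hue, plus additive Gaussian
#' intensity noise. The two shipped defaults (see [default_texture_specs()])
#' are built so that class identity is carried by *structure* (and therefore
#' survives in per-channel Canny edge maps), not only by color.
#'
#' @param name Class label; nonempty string, unique within an experiment.
#' @param nucleus_density Expected nuclei per 1000 px^2 (Poisson intensity).
#' @param nucleus_radius_range Length-2 px interval for ellipse semi-axes.
#' @param fiber_count Expected number of wavy strokes per 64 x 64 px of
#'   area (count proportional to raster area with stochastic rounding, so
#'   larger rasters carry proportionally more strokes).
#' @param fiber_waviness Dimensionless waviness amplitude factor (>= 0).
#' @param palette List with `fg` and `bg` RGB triplets on the 0-255 scale.
#' @param noise_sd Additive Gaussian intensity SD on the 0-255 scale.
#' @param seed RNG seed for all generation from this spec.
#' @param ring_fraction Fraction of nuclei drawn as rings (gland motif).
#' @param fiber_width Stroke half-width support in px.
#' @param fiber_length Stroke length in px (strokes are finite chords).
#'
#' @return An object of class `texture_class_spec`.
#' @export
texture_class_spec <- function(name, nucleus_density = 0,
                               nucleus_radius_range = c(3, 6),
                               fiber_count = 0, fiber_waviness = 0,
                               palette = list(fg = c(70, 50, 140),
                                              bg = c(235, 215, 230)),
                               noise_sd = 0, seed = 1L,
                               ring_fraction = 0, fiber_width = 1.4,
                               fiber_length = 100) {
  assert_string(name, "name")
  assert_scalar_number(nucleus_density, "nucleus_density")
  if (nucleus_density < 0) stop_invalid("`nucleus_density` must be >= 0")
  if (length(nucleus_radius_range) != 2L || any(nucleus_radius_range <= 0) ||
      nucleus_radius_range[1] > nucleus_radius_range[2])
    stop_invalid("`nucleus_radius_range` must be an increasing positive px interval")
  assert_scalar_number(fiber_count, "fiber_count")
  if (fiber_count < 0) stop_invalid("`fiber_count` must be >= 0")
  assert_scalar_number(fiber_waviness, "fiber_waviness")
  if (fiber_waviness < 0) stop_invalid("`fiber_waviness` must be >= 0")
  if (!is.list(palette) || !all(c("fg", "bg") %in% names(palette)))
    stop_invalid("`palette` must be a list with `fg` and `bg` RGB triplets")
  for (k in c("fg", "bg")) {
    v <- palette[[k]]
    if (length(v) != 3L || any(v < 0) || any(v > 255))
      stop_invalid("palette$%s must be 3 values in [0, 255]", k)
  }
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0 || noise_sd > 255) stop_invalid("`noise_sd` must be in [0, 255]")
  structure(list(name = name,
                 nucleus_density = nucleus_density,
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 fiber_count = fiber_count,
                 fiber_waviness = fiber_waviness,
                 palette = list(fg = as.numeric(palette$fg),
                                bg = as.numeric(palette$bg)),
                 noise_sd = noise_sd,
                 seed = assert_count(seed, "seed", min = 0L),
                 ring_fraction = ring_fraction,
                 fiber_width = fiber_width,
                 fiber_length = fiber_length),
            class = "texture_class_spec")
}

#' Shipped default texture classes
#'
#' `"tumorlike"`: dense, dark (hematoxylin-hued) elliptical blobs, a fraction
#' drawn as rings to mimic gland cross-sections. `"stromalike"`: sparse wavy
#' eosin-hued fibers with occasional small nuclei. Foreground coverage of the
#' two classes is approximately matched so that when palettes are equalised a
#' pixel-mean classifier cannot separate them, while their edge-map densities
#' still differ by well over a factor of 1.5.
#'
#' @param palette_drained If `TRUE`, both classes share one palette, removing
#'   all color information so that only structure distinguishes them.
#' @param seed Base RNG seed; each class derives its own sub-seed.
#' @return Named list of [texture_class_spec()] objects.
#' @export
default_texture_specs <- function(palette_drained = FALSE, seed = 42L) {
  assert_flag(palette_drained, "palette_drained")
  hema <- list(fg = c(82, 54, 144), bg = c(233, 213, 228))
  eosin <- list(fg = c(186, 84, 128), bg = c(246, 230, 236))
  if (palette_drained) eosin <- hema
  list(
    tumorlike = texture_class_spec(
      name = "tumorlike",
      nucleus_density = 1.6,
      nucleus_radius_range = c(3, 6),
      fiber_count = 0,
      fiber_waviness = 0,
      palette = hema,
      noise_sd = 6,
      seed = derive_seed(seed, 101L),
      ring_fraction = 0.4),
    stromalike = texture_class_spec(
      name = "stromalike",
      nucleus_density = 0.08,
      nucleus_radius_range = c(2, 3.5),
      fiber_count = 2,
      fiber_waviness = 1.5,
      palette = eosin,
      noise_sd = 6,
      seed = derive_seed(seed, 202L),
      fiber_width = 2.05)
  )
}

# Stamp an anti-aliased filled (or ring) ellipse into coverage matrix `cov`.
stamp_ellipse <- function(cov, cy, cx, a, b, theta, ring = FALSE) {
  H <- nrow(cov); W <- ncol(cov)
  r <- ceiling(max(a, b)) + 1L
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(cov)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  d <- sqrt(u * u + v * v)          # normalized radial distance, 1 at rim
  scale <- min(a, b)                # px per unit of d, for ~1 px AA ramp
  alpha <- clamp01((1 - d) * scale + 0.5)
  if (ring) {
    inner <- clamp01((0.55 - d) * scale + 0.5)
    alpha <- clamp01(alpha - inner)
  }
  cov[ys, xs] <- pmax(cov[ys, xs], alpha)
  cov
}

# Stamp an anti-aliased wavy stroke of half-width w and length len.
stamp_fiber <- function(cov, H, W, waviness, w, len) {
  # random finite chord, perturbed by a sinusoid
  theta <- stats::runif(1, 0, pi)
  cx <- stats::runif(1, 0.1 * W, 0.9 * W)
  cy <- stats::runif(1, 0.1 * H, 0.9 * H)
  tt <- seq(-len / 2, len / 2, by = 0.4)
  amp <- waviness * 4
  freq <- stats::runif(1, 0.5, 1.5) * 2 * pi / len
  phase <- stats::runif(1, 0, 2 * pi)
  off <- amp * sin(freq * tt * 2 + phase)
  px <- cx + tt * cos(theta) - off * sin(theta)
  py <- cy + tt * sin(theta) + off * cos(theta)
  keep <- px >= -2 & px <= W + 2 & py >= -2 & py <= H + 2
  px <- px[keep]; py <- py[keep]
  rad <- ceiling(w) + 1L
  for (i in seq_along(px)) {
    ys <- max(1L, floor(py[i] - rad)):min(H, ceiling(py[i] + rad))
    xs <- max(1L, floor(px[i] - rad)):min(W, ceiling(px[i] + rad))
    if (!length(ys) || !length(xs)) next
    d <- sqrt(outer((ys - py[i])^2, rep(1, length(xs))) +
              outer(rep(1, length(ys)), (xs - px[i])^2))
    alpha <- clamp01(w / 2 + 0.5 - d)
    cov[ys, xs] <- pmax(cov[ys, xs], alpha)
  }
  cov
}

# Draw one H x W texture raster from a spec; assumes RNG already seeded.
draw_texture <- function(spec, H, W) {
  cov <- matrix(0, H, W)
  n_nuc <- stats::rpois(1, spec$nucleus_density * H * W / 1000)
  if (n_nuc > 0) {
    for (i in seq_len(n_nuc)) {
      cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
      ab <- stats::runif(2, spec$nucleus_radius_range[1],
                         spec$nucleus_radius_range[2])
      th <- stats::runif(1, 0, pi)
      ring <- stats::runif(1) < spec$ring_fraction
      cov <- stamp_ellipse(cov, cy, cx, ab[1], ab[2], th, ring = ring)
    }
  }
  if (spec$fiber_count > 0) {
    lam <- spec$fiber_count * H * W / 4096
    n_fib <- floor(lam) + stats::rbinom(1, 1, lam - floor(lam))
    for (i in seq_len(n_fib))
      cov <- stamp_fiber(cov, H, W, spec$fiber_waviness, spec$fiber_width,
                         spec$fiber_length)
  }
  out <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- spec$palette$bg[ch] * (1 - cov) + spec$palette$fg[ch] * cov
    if (spec$noise_sd > 0)
      plane <- plane + stats::rnorm(H * W, sd = spec$noise_sd)
    out[, , ch] <- clamp255(plane)
  }
  round(out)
}

#' Generate labeled synthetic tiles
#'
#' Generation is a pure function of `(spec, n, tile_size)`: each tile is drawn
#' under a sub-seed derived from `spec$seed` and the tile index, so repeated
#' calls are bit-identical and tile `i` does not depend on `n`.
#'
#' @param spec A [texture_class_spec()].
#' @param n Number of tiles (>= 1).
#' @param tile_size Square tile edge in px (>= 32).
#' @return List of `tile_size x tile_size x 3` arrays (0-255), each carrying a
#'   `label` attribute equal to `spec$name`.
#' @export
generate_tiles <- function(spec, n, tile_size) {
  if (!inherits(spec, "texture_class_spec"))
    stop_invalid("`spec` must be a texture_class_spec")
  n <- assert_count(n, "n", min = 1L)
  tile_size <- assert_count(tile_size, "tile_size", min = 32L)
  lapply(seq_len(n), function(i) {
    tile <- with_rng(derive_seed(spec$seed, i),
                     draw_texture(spec, tile_size, tile_size))
    set_tile_meta(tile, label = spec$name, source_id = spec$name)
  })
}

#' Generate a synthetic high-power field
#'
#' A high-power field (HPF) is a raster strictly larger than the working tile
#' size, used for region-level classification by majority vote over sampled
#' windows. `layout` assigns texture classes to a coarse block grid; `NULL`
#' fills the whole field with the first spec (a homogeneous field).
#'
#' @param specs List of [texture_class_spec()] with unique names.
#' @param size Length-2 (height, width) in px.
#' @param layout `NULL`, or a character matrix of spec names; the field is
#'   split into equal blocks matching `dim(layout)`.
#' @param seed RNG seed.
#' @return List with `pixels` (H x W x 3 array), `true_label` (majority class
#'   by area), and `layout` (H x W character matrix of per-pixel labels).
#' @export
generate_hpf <- function(specs, size, layout = NULL, seed = 1L) {
  if (!is.list(specs) || length(specs) == 0L)
    stop_invalid("`specs` must be a nonempty list of texture_class_spec")
  if (inherits(specs, "texture_class_spec")) specs <- list(specs)
  for (s in specs) if (!inherits(s, "texture_class_spec"))
    stop_invalid("all elements of `specs` must be texture_class_spec")
  if (length(size) == 1L) size <- c(size, size)
  H <- assert_count(size[1], "size[1]", min = 2L)
  W <- assert_count(size[2], "size[2]", min = 2L)
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stop_invalid("spec names must be unique")
  if (is.null(layout)) layout <- matrix(names(specs)[1], 1, 1)
  if (!is.matrix(layout) || !is.character(layout))
    stop_invalid("`layout` must be NULL or a character matrix of spec names")
  if (!all(layout %in% names(specs)))
    stop_invalid("layout names not all present in `specs`")

  # per-pixel label map from the block layout
  ridx <- ceiling(seq_len(H) / H * nrow(layout))
  cidx <- ceiling(seq_len(W) / W * ncol(layout))
  labmap <- layout[ridx, cidx, drop = FALSE]

  pixels <- array(0, dim = c(H, W, 3))
  used <- unique(as.vector(layout))
  for (k in seq_along(used)) {
    nm <- used[k]
    full <- with_rng(derive_seed(seed, k), draw_texture(specs[[nm]], H, W))
    sel <- labmap == nm
    for (ch in 1:3) {
      plane <- pixels[, , ch]
      plane[sel] <- full[, , ch][sel]
      pixels[, , ch] <- plane
    }
  }
  counts <- table(factor(labmap, levels = sort(used)))
  true_label <- names(counts)[which.max(counts)]  # ties: lexicographic first
  list(pixels = pixels, true_label = true_label, layout = labmap)
}
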