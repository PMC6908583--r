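#' Stereology sampling grid
#'
#' A square grid of points laid across an image. Each grid point is the
#' top-left corner (0-based) of a half-open `tile_size` square
#' `[r, r+T) x [c, c+T)`. The default spacing equals the tile size, giving
#' non-overlapping tiles.
#'
#' @param tile_size Square edge in px (>= 1).
#' @param spacing Px between grid points (>= 1); defaults to `tile_size`.
#' @param offset Length-2 (row, col) px offset of the first grid point.
#' @return A `stereology_grid`.
#' @export
stereology_grid <- function(tile_size, spacing = tile_size,
                            offset = c(0L, 0L)) {
  tile_size <- assert_count(tile_size, "tile_size", min = 1L)
  spacing <- assert_count(spacing, "spacing", min = 1L)
  if (length(offset) != 2L || any(offset < 0))
    stop_invalid("`offset` must be two non-negative px values")
  structure(list(tile_size = tile_size, spacing = spacing,
                 offset = as.integer(offset)),
            class = "stereology_grid")
}

#' Binary annotation mask
#'
#' @param mask Logical (or strictly 0/1) matrix aligned to a source image.
#' @param label Class name carried by every tile sampled from this mask.
#' @return An `annotation_mask`.
#' @export
annotation_mask <- function(mask, label) {
  if (!is.matrix(mask)) stop_invalid("`mask` must be a matrix")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop_invalid("`mask` must be strictly binary")
    mask <- mask == 1
  }
  if (!is.logical(mask)) stop_invalid("`mask` must be logical or 0/1")
  structure(list(mask = mask, label = assert_string(label, "label")),
            class = "annotation_mask")
}

#' Sample tiles from an annotated image by stereology
#'
#' For every grid point, the tile-size square anchored there (top-left
#' corner) is emitted iff it lies strictly inside the annotation: by
#' default every pixel of the square must be mask-true (`containment = 1`);
#' a containment fraction below 1 relaxes this. Emitted tiles carry the
#' mask's label and the 0-based (row, col) of their top-left corner.
#'
#' @param image H x W x 3 RGB raster (0-255 scale).
#' @param mask An [annotation_mask()] with the same H x W.
#' @param grid A [stereology_grid()].
#' @param source_id Optional identifier stamped on every tile (e.g. slide id).
#' @param containment Minimum fraction of mask-true pixels per square.
#' @return List of labeled tiles with `row`/`col` attributes.
#' @export
stereology_sample <- function(image, mask, grid, source_id = NULL,
                              containment = 1.0) {
  assert_tile(image, "image")
  if (!inherits(mask, "annotation_mask"))
    stop_invalid("`mask` must be an annotation_mask")
  if (!inherits(grid, "stereology_grid"))
    stop_invalid("`grid` must be a stereology_grid")
  d <- dim(image)
  if (!identical(dim(mask$mask), d[1:2]))
    stop_invalid("mask (%dx%d) is not aligned to the image (%dx%d)",
                 nrow(mask$mask), ncol(mask$mask), d[1], d[2])
  assert_scalar_number(containment, "containment")
  if (containment <= 0 || containment > 1)
    stop_invalid("`containment` must be in (0, 1]")
  ts <- grid$tile_size
  # summed-area table for O(1) containment counts per square
  mm <- mask$mask * 1
  sat <- matrix(0, d[1] + 1L, d[2] + 1L)
  sat[-1, -1] <- t(apply(apply(mm, 2, cumsum), 1, cumsum))
  rect_sum <- function(r0, c0) # 0-based top-left, ts square
    sat[r0 + ts + 1L, c0 + ts + 1L] - sat[r0 + 1L, c0 + ts + 1L] -
      sat[r0 + ts + 1L, c0 + 1L] + sat[r0 + 1L, c0 + 1L]
  rows <- seq(grid$offset[1], d[1] - ts, by = grid$spacing)
  cols <- seq(grid$offset[2], d[2] - ts, by = grid$spacing)
  if (grid$offset[1] > d[1] - ts) rows <- integer(0)
  if (grid$offset[2] > d[2] - ts) cols <- integer(0)
  need <- containment * ts * ts
  out <- list()
  for (r0 in rows) for (c0 in cols) {
    if (rect_sum(r0, c0) >= need) {
      tile <- image[r0 + seq_len(ts), c0 + seq_len(ts), , drop = FALSE]
      out[[length(out) + 1L]] <-
        set_tile_meta(tile, label = mask$label, row = r0, col = c0,
                      source_id = source_id)
    }
  }
  out
}

#' Write a tile set to disk with a manifest
#'
#' One PNG per tile plus `manifest.csv` with columns `path`, `label`,
#' `source_id`, `row`, `col`, `tile_size`. Refuses to overwrite an existing
#' manifest.
#'
#' @param tiles List of labeled tiles.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
write_tileset <- function(tiles, out_dir) {
  if (!is.list(tiles)) stop_invalid("`tiles` must be a list of tiles")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(out_dir, "manifest.csv")
  if (file.exists(mpath))
    stop_conflict("a manifest already exists at %s", mpath)
  rows <- lapply(seq_along(tiles), function(i) {
    t <- tiles[[i]]
    label <- tile_label(t)
    if (is.null(label)) label <- "unlabeled"
    fname <- sprintf("%s_%04d.png", label, i)
    write_tile(t, file.path(out_dir, fname))
    data.frame(path = fname, label = label,
               source_id = attr(t, "source_id") %||% NA_character_,
               row = attr(t, "row") %||% NA_integer_,
               col = attr(t, "col") %||% NA_integer_,
               tile_size = dim(t)[1])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
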