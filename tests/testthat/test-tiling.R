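test_that("a full mask yields the exact non-overlapping grid", {
  img <- array(7, dim = c(1024, 1024, 3))
  am <- annotation_mask(matrix(TRUE, 1024, 1024), "tumor")
  tiles <- stereology_sample(img, am, stereology_grid(256, 256))
  expect_length(tiles, 16)
  expected <- as.matrix(expand.grid(row = c(0, 256, 512, 768),
                                    col = c(0, 256, 512, 768)))
  got <- corners_of(tiles)
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(expected[, 1], expected[, 2]))
  expect_true(all(vapply(tiles, function(t)
    identical(tile_label(t), "tumor"), logical(1))))
  # an all-false mask yields nothing
  expect_length(stereology_sample(img, annotation_mask(
    matrix(FALSE, 1024, 1024), "x"), stereology_grid(256, 256)), 0)
})

test_that("sampled squares match the brute-force containment oracle", {
  set.seed(99)
  H <- 300
  cx <- 150; cy <- 150
  circ <- outer(seq_len(H) - cy, seq_len(H) - cx,
                function(a, b) sqrt(a^2 + b^2) < 100)
  img <- array(sample(0:255, H * H * 3, TRUE), dim = c(H, H, 3))
  for (spacing in c(16, 32, 64)) {
    tiles <- stereology_sample(img, annotation_mask(circ, "c"),
                               stereology_grid(64, spacing))
    bf <- brute_force_corners(circ, 64, spacing)
    got <- corners_of(tiles)
    expect_equal(if (is.null(got)) 0 else nrow(got),
                 if (is.null(bf)) 0 else nrow(bf))
    if (!is.null(bf))
      expect_setequal(paste(got[, 1], got[, 2]), paste(bf[, 1], bf[, 2]))
  }
  # emitted tiles never overlap mask-false pixels
  tiles <- stereology_sample(img, annotation_mask(circ, "c"),
                             stereology_grid(64, 32))
  for (t in tiles) {
    r0 <- attr(t, "row"); c0 <- attr(t, "col")
    expect_true(all(circ[r0 + 1:64, c0 + 1:64]))
    expect_identical(t[, , , drop = TRUE],
                     img[r0 + 1:64, c0 + 1:64, ])
  }
})

test_that("tile count is monotone in spacing and consistent under translation", {
  set.seed(5)
  blob <- matrix(FALSE, 200, 200)
  blob[30:170, 40:190] <- TRUE
  img <- array(0, dim = c(200, 200, 3))
  counts <- vapply(c(8, 16, 32, 64), function(sp)
    length(stereology_sample(img, annotation_mask(blob, "b"),
                             stereology_grid(32, sp))), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # shifting image + mask by one spacing shifts coordinates identically
  sp <- 16
  shifted <- matrix(FALSE, 200, 200)
  shifted[30:170 + sp, 40:190] <- blob[30:170, 40:190]
  t1 <- stereology_sample(img, annotation_mask(blob, "b"),
                          stereology_grid(32, sp))
  t2 <- stereology_sample(img, annotation_mask(shifted, "b"),
                          stereology_grid(32, sp))
  c1 <- corners_of(t1); c2 <- corners_of(t2)
  keep <- c1[, 1] + sp + 32 <= 200   # rows whose shifted square stays inside
  expect_setequal(paste(c1[keep, 1] + sp, c1[keep, 2]),
                  paste(c2[, 1], c2[, 2]))
})

test_that("misaligned masks and bad grids are rejected", {
  img <- array(0, dim = c(100, 100, 3))
  expect_invalid(stereology_sample(img, annotation_mask(
    matrix(TRUE, 50, 100), "x"), stereology_grid(32)))
  expect_invalid(stereology_grid(0))
  expect_invalid(stereology_grid(32, spacing = 0))
  expect_invalid(annotation_mask(matrix(2, 4, 4), "x"))
})

test_that("tile sets write losslessly with a faithful manifest", {
  img <- generate_hpf(default_texture_specs()["tumorlike"],
                      c(128, 128), seed = 20)$pixels
  am <- annotation_mask(matrix(TRUE, 128, 128), "tumorlike")
  tiles <- stereology_sample(img, am, stereology_grid(64, 64),
                             source_id = "hpf_20")
  d <- tempfile("tiles_")
  manifest <- write_tileset(tiles, d)
  expect_equal(nrow(manifest), 4)
  expect_length(list.files(d, pattern = "\\.png$"), 4)
  for (i in seq_len(nrow(manifest))) {
    back <- read_tile(file.path(d, manifest$path[i]))
    expect_identical(back, unclass_tile(tiles[[i]]))
    # re-crop from the source at the manifest coordinates
    r0 <- manifest$row[i]; c0 <- manifest$col[i]
    expect_equal(back, img[r0 + 1:64, c0 + 1:64, ])
  }
  expect_error(write_tileset(tiles, d), class = "ganrecon_conflict")
})
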