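test_that("a structureless spec yields constant-background tiles", {
  flat <- texture_class_spec("flat", nucleus_density = 0, fiber_count = 0,
                             noise_sd = 0,
                             palette = list(fg = c(0, 0, 0),
                                            bg = c(120, 80, 200)),
                             seed = 5)
  tiles <- generate_tiles(flat, 3, 32)
  expect_length(tiles, 3)
  for (t in tiles) {
    expect_identical(dim(t), c(32L, 32L, 3L))
    expect_equal(unique(as.vector(t[, , 1])), 120)
    expect_equal(unique(as.vector(t[, , 2])), 80)
    expect_equal(unique(as.vector(t[, , 3])), 200)
    expect_identical(attr(t, "label"), "flat")
  }
})

test_that("tile generation is a pure function of (spec, n, tile_size)", {
  spec <- default_texture_specs()$tumorlike
  a <- generate_tiles(spec, 4, 64)
  b <- generate_tiles(spec, 4, 64)
  expect_identical(a, b)
  # tile i must not depend on how many tiles were requested
  c2 <- generate_tiles(spec, 2, 64)
  expect_identical(a[1:2], c2)
})

test_that("invalid generation arguments are rejected", {
  spec <- default_texture_specs()$tumorlike
  expect_invalid(generate_tiles(spec, 0, 64))
  expect_invalid(generate_tiles(spec, 5, 16))
  expect_invalid(texture_class_spec("x", nucleus_density = -1))
  expect_invalid(texture_class_spec("x",
                                    palette = list(fg = c(0, 0, 300),
                                                   bg = c(1, 1, 1))))
  expect_invalid(texture_class_spec(""))
})

test_that("default classes differ in edge density by at least 1.5x", {
  specs <- default_texture_specs()
  ep <- edge_params(sigma = 2)
  dens <- function(spec) mean(vapply(generate_tiles(spec, 30, 64),
                                     function(t) edge_density(detect_edges(t, ep)),
                                     numeric(1)))
  dt <- dens(specs$tumorlike)
  ds <- dens(specs$stromalike)
  expect_gte(max(dt, ds) / min(dt, ds), 1.5)
})

test_that("with palettes drained, structure (not color) separates the classes", {
  # nearest-centroid on per-tile mean intensity must be near chance, while
  # the same classifier on edge density must separate well
  specs <- default_texture_specs(palette_drained = TRUE)
  ep <- edge_params(sigma = 2)
  a <- generate_tiles(specs$tumorlike, 40, 64)
  b <- generate_tiles(specs$stromalike, 40, 64)
  centroid_acc <- function(f) {
    va <- vapply(a, f, numeric(1)); vb <- vapply(b, f, numeric(1))
    ca <- mean(va[1:20]); cb <- mean(vb[1:20])
    mean(c(abs(va[21:40] - ca) < abs(va[21:40] - cb),
           abs(vb[21:40] - cb) < abs(vb[21:40] - ca)))
  }
  pixel_acc <- centroid_acc(mean)
  edge_acc <- centroid_acc(function(t) edge_density(detect_edges(t, ep)))
  expect_lt(pixel_acc, 0.75)
  expect_gte(edge_acc, 0.85)
})

test_that("homogeneous and split HPF layouts are honoured", {
  specs <- default_texture_specs()
  h <- generate_hpf(specs["tumorlike"], c(160, 160), seed = 9)
  expect_identical(h$true_label, "tumorlike")
  expect_identical(dim(h$pixels), c(160L, 160L, 3L))
  expect_true(all(h$layout == "tumorlike"))

  lay <- matrix(c("tumorlike", "stromalike"), 1, 2)
  h2 <- generate_hpf(unname(specs), c(128, 128), layout = lay, seed = 9)
  expect_true(all(h2$layout[, 1:64] == "tumorlike"))
  expect_true(all(h2$layout[, 65:128] == "stromalike"))
  # left half must equal the pure-tumorlike field on those pixels
  pure <- generate_hpf(specs["tumorlike"], c(128, 128), seed = 9)
  expect_identical(h2$pixels[, 1:64, ], pure$pixels[, 1:64, ])
})

test_that("HPF generation is deterministic and validates input", {
  specs <- default_texture_specs()
  a <- generate_hpf(specs["stromalike"], c(140, 150), seed = 4)
  b <- generate_hpf(specs["stromalike"], c(140, 150), seed = 4)
  expect_identical(a, b)
  expect_invalid(generate_hpf(list(), c(128, 128)))
})
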