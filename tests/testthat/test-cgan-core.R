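test_that("discriminator loss matches its analytic values", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(0.9, 0.1), -2 * log(0.9), tolerance = 1e-12)
  expect_lt(discriminator_loss(1, 0), 1e-10)       # perfect-discriminator limit
  expect_invalid(discriminator_loss(1.2, 0.5))
  expect_invalid(discriminator_loss(0.5, -0.1))
})

test_that("generator loss decomposes exactly into its weighted terms", {
  cfg <- training_config(lambda_mse = 100, lambda_adv = 1)
  a <- array(0.3, dim = c(4, 4, 3))
  lb <- generator_loss(0.5, a, a, cfg)
  expect_equal(lb$g_adv, log(2), tolerance = 1e-12)
  expect_equal(lb$g_mse, 0)
  b <- a + 0.1
  lb2 <- generator_loss(0.5, a, b, cfg)
  expect_equal(lb2$g_mse, 0.01, tolerance = 1e-12)
  expect_equal(lb2$g_total, log(2) + 1, tolerance = 1e-12)
  # generator-wins limit
  expect_lt(generator_loss(1 - 1e-15, a, a, cfg)$g_total, 1e-10)
  expect_invalid(generator_loss(0.5, a, array(0, dim = c(4, 4, 2)), cfg))
  # decomposition on random inputs, arbitrary weights
  for (s in 1:25) {
    set.seed(s)
    cfg2 <- training_config(lambda_mse = runif(1, 0, 200),
                            lambda_adv = runif(1, 0.01, 5))
    x <- array(runif(48, -1, 1), dim = c(4, 4, 3))
    y <- array(runif(48, -1, 1), dim = c(4, 4, 3))
    p <- runif(1, 0.01, 0.99)
    lb <- generator_loss(p, x, y, cfg2)
    expect_equal(lb$g_total,
                 cfg2$lambda_adv * lb$g_adv + cfg2$lambda_mse * lb$g_mse,
                 tolerance = 1e-12)
  }
})

test_that("losses are monotone in the discriminator's probabilities", {
  grid <- seq(0.05, 0.95, by = 0.1)
  cfg <- training_config()
  a <- array(0, dim = c(2, 2, 3))
  g_adv <- vapply(grid, function(p) generator_loss(p, a, a, cfg)$g_adv,
                  numeric(1))
  expect_true(all(diff(g_adv) < 0))                 # better fooling, lower loss
  d_real <- vapply(grid, function(p) discriminator_loss(p, 0.5), numeric(1))
  d_fake <- vapply(grid, function(p) discriminator_loss(0.5, p), numeric(1))
  expect_true(all(diff(d_real) < 0))
  expect_true(all(diff(d_fake) > 0))
})

test_that("generator builds are deterministic with the declared shape contract", {
  gs <- generator_spec(depth = 2, base_filters = 8)
  g1 <- build_generator(gs, 64, seed = 3)
  g2 <- build_generator(gs, 64, seed = 3)
  expect_identical(g1$params, g2$params)
  x <- array(0, dim = c(64, 64, 3))
  y <- generator_forward(g1, x)
  expect_identical(dim(y), c(64L, 64L, 3L))
  expect_true(all(is.finite(y)))
  expect_true(all(abs(y) <= 1))
  expect_invalid(build_generator(gs, 62))
  expect_invalid(generator_spec(depth = 1))
})

test_that("generator parameter count equals the layer-by-layer sum", {
  # architecture: 4x4 stride-2 encoder convs, 3x3 bottleneck, 3x3 decoder
  # convs on (up + skip) channels, 3x3 output conv on (ch1 + input)
  count_conv <- function(k, cin, cout) k * k * cin * cout + cout
  hand <- function(depth, base, cin = 3) {
    ch <- pmin(base * 2^(seq_len(depth) - 1), 8 * base)
    total <- 0
    prev <- cin
    for (i in seq_len(depth)) {
      total <- total + count_conv(4, prev, ch[i]); prev <- ch[i]
    }
    total <- total + count_conv(3, ch[depth], ch[depth])
    cur <- ch[depth]
    for (j in seq_len(depth - 1)) {
      skip <- ch[depth - j]
      total <- total + count_conv(3, cur + skip, skip)
      cur <- skip
    }
    total + count_conv(3, cur + cin, 3)
  }
  for (cfg in list(c(2, 8), c(3, 16), c(4, 8))) {
    g <- build_generator(generator_spec(depth = cfg[1],
                                        base_filters = cfg[2]), 64)
    expect_identical(n_parameters(g), as.integer(hand(cfg[1], cfg[2])))
  }
})

test_that("discriminator outputs a normalised probability pair", {
  ds <- discriminator_spec(conv_stages = 2, base_filters = 8)
  d1 <- build_discriminator(ds, 32, seed = 4)
  d2 <- build_discriminator(ds, 32, seed = 4)
  expect_identical(d1$params, d2$params)
  p <- discriminator_forward(d1, array(0, dim = c(32, 32, 6)))
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # hand count: two 4x4 convs then a dense 2-way head on pooled features
  hand <- (4 * 4 * 6 * 8 + 8) + (4 * 4 * 8 * 16 + 16) + (16 * 2 + 2)
  expect_identical(n_parameters(d1), as.integer(hand))
  expect_invalid(build_discriminator(ds, 30))
})

test_that("training reduces the reconstruction loss and is bit-reproducible", {
  spec <- default_texture_specs()$tumorlike
  tiles <- rep(generate_tiles(spec, 1, 32), 8)
  cfg <- training_config(epochs = 8, batch_size = 2, learning_rate = 2e-3,
                         seed = 31)
  m <- train_class_model(tiles, edge_params(sigma = 2), tiny_gspec(),
                         tiny_dspec(), cfg)
  mse <- vapply(m$training_log, `[[`, numeric(1), "g_mse")
  expect_lt(mse[length(mse)], mse[1])
  m2 <- train_class_model(tiles, edge_params(sigma = 2), tiny_gspec(),
                          tiny_dspec(), cfg)
  expect_identical(m$fingerprint, m2$fingerprint)
  expect_identical(m$generator_weights, m2$generator_weights)
})

test_that("training sees one class only: mixed labels rejected, context ignored", {
  specs <- default_texture_specs()
  mixed <- c(generate_tiles(specs$tumorlike, 2, 32),
             generate_tiles(specs$stromalike, 2, 32))
  expect_invalid(train_class_model(mixed, edge_params(), tiny_gspec(),
                                   tiny_dspec(), tiny_cfg(1)))
  # other-class data existing on disk must not influence the result
  tiles <- generate_tiles(specs$tumorlike, 4, 32)
  other_dir <- tempfile("other_class_")
  m1 <- train_class_model(tiles, edge_params(), tiny_gspec(), tiny_dspec(),
                          tiny_cfg(9))
  dir.create(other_dir)
  write_tileset(generate_tiles(specs$stromalike, 4, 32), other_dir)
  m2 <- train_class_model(tiles, edge_params(), tiny_gspec(), tiny_dspec(),
                          tiny_cfg(9))
  expect_identical(m1$fingerprint, m2$fingerprint)
})

test_that("reconstruction is deterministic, shaped, and 8-bit bounded", {
  m <- tiny_model("tumorlike")
  tile <- generate_tiles(default_texture_specs()$tumorlike, 1, 32)[[1]]
  r1 <- reconstruct(m, tile)
  r2 <- reconstruct(m, tile)
  expect_identical(r1, r2)
  expect_identical(dim(r1), dim(tile))
  expect_true(all(r1 >= 0 & r1 <= 255))
  expect_true(all(r1 == round(r1)))
  expect_invalid(reconstruct(m, generate_tiles(default_texture_specs()$tumorlike,
                                               1, 64)[[1]]))
})
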