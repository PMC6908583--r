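# Shared fixtures. Small trained models are expensive, so they are built
# once per test run and memoised in this environment.

fixture_env <- new.env(parent = emptyenv())

tiny_gspec <- function() generator_spec(depth = 2L, base_filters = 8L)
tiny_dspec <- function() discriminator_spec(conv_stages = 2L,
                                            base_filters = 8L)

tiny_cfg <- function(seed, epochs = 2L) {
  training_config(epochs = epochs, batch_size = 2L, learning_rate = 2e-3,
                  seed = seed)
}

# A third structurally distinct synthetic class (large sparse rings).
mucinlike_spec <- function(seed = 77L) {
  texture_class_spec("mucinlike", nucleus_density = 0.25,
                     nucleus_radius_range = c(5, 9),
                     palette = list(fg = c(150, 130, 190),
                                    bg = c(240, 236, 244)),
                     noise_sd = 6, seed = seed, ring_fraction = 1)
}

tiny_model <- function(class = c("tumorlike", "stromalike", "mucinlike"),
                       seed = NULL, n = 8L, tile_size = 32L) {
  class <- match.arg(class)
  key <- paste0("model_", class, "_", seed %||% "d")
  m <- fixture_env[[key]]
  if (!is.null(m)) return(m)
  spec <- if (class == "mucinlike") mucinlike_spec()
          else default_texture_specs()[[class]]
  seed <- seed %||% switch(class, tumorlike = 21L, stromalike = 22L,
                           mucinlike = 23L)
  tiles <- generate_tiles(spec, n, tile_size)
  m <- train_class_model(tiles, edge_params(sigma = 2), tiny_gspec(),
                         tiny_dspec(), tiny_cfg(seed))
  fixture_env[[key]] <- m
  m
}

tiny_registry <- function() {
  r <- fixture_env$registry
  if (!is.null(r)) return(r)
  r <- add_class(add_class(model_registry(), tiny_model("tumorlike")),
                 tiny_model("stromalike"))
  fixture_env$registry <- r
  r
}

# Random unstructured tile (uniform noise), for property tests.
random_tile <- function(seed, size = 32L) {
  with_seed_local(seed, {
    array(sample(0:255, size * size * 3, replace = TRUE),
          dim = c(size, size, 3))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_invalid <- function(expr) {
  expect_error(expr, class = "ganrecon_invalid_argument")
}

# Brute-force containment oracle: enumerate every grid square and test
# full containment pixel-by-pixel.
brute_force_corners <- function(mask, tile_size, spacing,
                                offset = c(0L, 0L), containment = 1) {
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  r0 <- offset[1]
  while (r0 + tile_size <= H) {
    c0 <- offset[2]
    while (c0 + tile_size <= W) {
      sub <- mask[r0 + seq_len(tile_size), c0 + seq_len(tile_size)]
      if (sum(sub) >= containment * tile_size^2)
        out <- rbind(out, c(r0, c0))
      c0 <- c0 + spacing
    }
    r0 <- r0 + spacing
  }
  out
}

corners_of <- function(tiles)
  if (length(tiles) == 0) NULL else
    t(vapply(tiles, function(t) c(attr(t, "row"), attr(t, "col")),
             numeric(2)))


clamp255_test <- function(x) { x[x > 255] <- 255; x[x < 0] <- 0; x }

unclass_tile <- function(t) {
  attributes(t) <- list(dim = dim(t))
  t
}
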