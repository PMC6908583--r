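# The scaled-down study conditions exercised by the end-to-end tests:
# 64 px tiles, 200 training tiles per class, U-Net depth 3 with 16 base
# filters, 5 epochs, sigma = 2 conditioning. Built once and memoised.

study_conditions <- list(
  tile_size = 64L,
  n_train = 200L,
  n_test = 60L,
  epochs = 5L,
  batch_size = 1L,
  learning_rate = 2e-3,
  sigma = 2,
  gspec = function() generator_spec(depth = 3L, base_filters = 16L),
  dspec = function() discriminator_spec(conv_stages = 3L, base_filters = 16L)
)

study_registry <- function() {
  r <- fixture_env$study
  if (!is.null(r)) return(r)
  sc <- study_conditions
  specs <- default_texture_specs()
  ep <- edge_params(sigma = sc$sigma)
  reg <- model_registry()
  seeds <- c(tumorlike = 101L, stromalike = 102L)
  tiles <- list()
  for (nm in names(specs)) {
    all <- generate_tiles(specs[[nm]], sc$n_train + sc$n_test, sc$tile_size)
    cfg <- training_config(epochs = sc$epochs, batch_size = sc$batch_size,
                           learning_rate = sc$learning_rate,
                           seed = seeds[[nm]])
    reg <- add_class(reg, train_class_model(all[seq_len(sc$n_train)], ep,
                                            sc$gspec(), sc$dspec(), cfg))
    tiles[[nm]] <- all[sc$n_train + seq_len(sc$n_test)]
  }
  r <- list(registry = reg, test_tiles = tiles)
  fixture_env$study <- r
  r
}
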