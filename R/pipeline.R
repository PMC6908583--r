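#' Pipeline run configuration
#'
#' One declarative object driving the whole simulate -> train -> classify ->
#' evaluate demo pipeline. Every stochastic stage receives an explicit seed
#' derived from `seed`, so a config fully determines the run: re-running it
#' reproduces identical model fingerprints and identical report bytes.
#'
#' @param out_dir Output directory for all artifacts.
#' @param classes Named list of [texture_class_spec()]s (two or more).
#' @param n_train,n_test Tiles per class for training and held-out testing.
#' @param tile_size Tile edge in px.
#' @param sigma_preset `"sigma_2"`, `"sigma_5"`, or a positive number for a
#'   custom smoothing SD. Unknown presets are rejected before any work.
#' @param metric Dissimilarity metric for classification.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param n_hpf Homogeneous synthetic high-power fields to classify.
#' @param hpf_size HPF edge in px (>= 2x tile size).
#' @param n_windows Windows sampled per HPF.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir,
                       classes = default_texture_specs(),
                       n_train = 24L, n_test = 12L, tile_size = 64L,
                       sigma_preset = "sigma_2", metric = "mse",
                       epochs = 1L, batch_size = 1L, learning_rate = 2e-3,
                       n_hpf = 4L, hpf_size = 160L, n_windows = 20L,
                       seed = 1L) {
  assert_string(out_dir, "out_dir")
  if (!is.list(classes) || length(classes) < 2L)
    stop_invalid("`classes` must list at least two texture_class_spec")
  sigma <- if (is.numeric(sigma_preset)) {
    assert_scalar_number(sigma_preset, "sigma_preset")
    if (sigma_preset <= 0) stop_invalid("custom sigma must be > 0")
    sigma_preset
  } else {
    switch(as.character(sigma_preset),
           sigma_2 = 2, sigma_5 = 5,
           stop_invalid("unknown sigma preset '%s' (use sigma_2, sigma_5, or a number)",
                        sigma_preset))
  }
  metric <- match.arg(tolower(metric), c("mse", "ssim", "psnr"))
  structure(list(out_dir = out_dir, classes = classes,
                 n_train = assert_count(n_train, "n_train"),
                 n_test = assert_count(n_test, "n_test"),
                 tile_size = assert_count(tile_size, "tile_size", min = 32L),
                 sigma_preset = as.character(sigma_preset), sigma = sigma,
                 metric = metric,
                 epochs = assert_count(epochs, "epochs"),
                 batch_size = assert_count(batch_size, "batch_size"),
                 learning_rate = assert_scalar_number(learning_rate,
                                                      "learning_rate"),
                 n_hpf = assert_count(n_hpf, "n_hpf"),
                 hpf_size = assert_count(hpf_size, "hpf_size"),
                 n_windows = assert_count(n_windows, "n_windows"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "run_config")
}

#' Run the full demo pipeline from a config
#'
#' Stages: generate per-class tiles; train one cGAN per class; classify
#' held-out tiles and homogeneous synthetic HPFs; write the registry, the
#' effective config (`config.yaml`) and a `report.json` under
#' `cfg$out_dir`. The report contains no timestamps, so identical configs
#' produce byte-identical reports.
#'
#' @param cfg A [run_config()].
#' @param gspec,dspec Network specifications shared by every class model.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(cfg, gspec = generator_spec(depth = 3L,
                                                     base_filters = 16L),
                         dspec = discriminator_spec(conv_stages = 3L,
                                                    base_filters = 16L)) {
  if (!inherits(cfg, "run_config")) stop_invalid("`cfg` must be a run_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  epar <- edge_params(sigma = cfg$sigma)
  class_names <- sort_labels(vapply(cfg$classes, `[[`, "", "name"))
  specs <- stats::setNames(cfg$classes[order(vapply(cfg$classes, `[[`, "",
                                                    "name"))], class_names)

  # stage: simulate
  train_tiles <- list(); test_tiles <- list()
  for (nm in class_names) {
    all <- generate_tiles(specs[[nm]], cfg$n_train + cfg$n_test,
                          cfg$tile_size)
    train_tiles[[nm]] <- all[seq_len(cfg$n_train)]
    test_tiles[[nm]] <- all[cfg$n_train + seq_len(cfg$n_test)]
  }

  # stage: train one model per class
  reg <- model_registry()
  for (i in seq_along(class_names)) {
    nm <- class_names[i]
    tc <- training_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                          learning_rate = cfg$learning_rate,
                          seed = derive_seed(cfg$seed, 10L + i))
    reg <- add_class(reg, train_class_model(train_tiles[[nm]], epar,
                                            gspec, dspec, tc))
  }
  save_registry(reg, file.path(cfg$out_dir, "registry"))

  # stage: classify held-out tiles
  truth <- character(0); pred <- character(0)
  for (nm in class_names) {
    for (t in test_tiles[[nm]]) {
      truth <- c(truth, nm)
      pred <- c(pred, classify_tile(reg, t, metric = cfg$metric)$predicted_label)
    }
  }
  pos <- {
    hit <- grep("^tumor", class_names, value = TRUE)
    if (length(hit)) hit[1] else class_names[1]
  }
  tp <- sum(pred == pos & truth == pos); fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos); tn <- sum(pred != pos & truth != pos)
  cc <- confusion_counts(tp, fp, fn, tn, pos)
  p <- as.numeric(precision(cc)); s <- as.numeric(sensitivity(cc))

  # stage: HPF majority vote on homogeneous fields
  hpf_correct <- 0L
  hpf_results <- list()
  for (i in seq_len(cfg$n_hpf)) {
    nm <- class_names[(i - 1L) %% length(class_names) + 1L]
    hp <- generate_hpf(specs[nm], c(cfg$hpf_size, cfg$hpf_size),
                       seed = derive_seed(cfg$seed, 100L + i))
    res <- classify_hpf(reg, hp$pixels, n_windows = cfg$n_windows,
                        window_size = cfg$tile_size,
                        seed = derive_seed(cfg$seed, 200L + i),
                        metric = cfg$metric)
    hpf_results[[i]] <- list(true_label = hp$true_label,
                             predicted_label = res$predicted_label,
                             votes = as.list(res$votes))
    if (res$predicted_label == hp$true_label) hpf_correct <- hpf_correct + 1L
  }

  report <- list(
    package_version = as.character(utils::packageVersion("ganrecon")),
    config = list(classes = as.list(class_names), n_train = cfg$n_train,
                  n_test = cfg$n_test, tile_size = cfg$tile_size,
                  sigma_preset = cfg$sigma_preset, sigma = cfg$sigma,
                  metric = cfg$metric, epochs = cfg$epochs,
                  batch_size = cfg$batch_size,
                  learning_rate = cfg$learning_rate, n_hpf = cfg$n_hpf,
                  hpf_size = cfg$hpf_size, n_windows = cfg$n_windows,
                  seed = cfg$seed),
    fingerprints = lapply(reg$entries, `[[`, "fingerprint"),
    tile_level = list(positive_label = pos, tp = tp, fp = fp, fn = fn,
                      tn = tn,
                      accuracy = round(100 * mean(pred == truth), 2),
                      precision = round(p, 2), sensitivity = round(s, 2),
                      f1 = round(f1(p, s), 2)),
    hpf_level = list(n_hpf = cfg$n_hpf, n_correct = hpf_correct,
                     accuracy = round(100 * hpf_correct / cfg$n_hpf, 2),
                     results = hpf_results))

  yaml::write_yaml(report$config, file.path(cfg$out_dir, "config.yaml"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
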