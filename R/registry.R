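#' Create an empty model registry
#'
#' The registry is the modular collection of independently trained class
#' generators. Adding or removing a class never touches the other entries:
#' every pre-existing model's weights (and therefore its fingerprint and its
#' reconstruction errors on any tile) are bit-identical before and after.
#' Entries are kept in lexicographic label order (C locale), which defines
#' iteration order and downstream tie-breaking.
#'
#' @param tile_size Common tile size in px; may be `NULL` until the first
#'   model is added.
#' @return A `model_registry`.
#' @export
model_registry <- function(tile_size = NULL) {
  structure(list(entries = structure(list(), names = character(0)),
                 tile_size = tile_size,
                 created = format(Sys.time(), tz = "UTC"),
                 modified = format(Sys.time(), tz = "UTC")),
            class = "model_registry")
}

sort_labels <- function(x) sort(x, method = "radix")

#' Add a trained class model to a registry
#'
#' @param registry A [model_registry()].
#' @param model A `class_model` from [train_class_model()].
#' @return The updated registry.
#' @export
add_class <- function(registry, model) {
  if (!inherits(registry, "model_registry"))
    stop_invalid("`registry` must be a model_registry")
  if (!inherits(model, "class_model"))
    stop_invalid("`model` must be a class_model")
  if (model$label %in% names(registry$entries))
    stop_conflict("class '%s' is already registered", model$label)
  if (is.null(registry$tile_size)) {
    registry$tile_size <- model$tile_size
  } else if (registry$tile_size != model$tile_size) {
    stop_invalid("model tile size %d does not match registry tile size %d",
                 model$tile_size, registry$tile_size)
  }
  registry$entries[[model$label]] <- model
  registry$entries <- registry$entries[sort_labels(names(registry$entries))]
  registry$modified <- format(Sys.time(), tz = "UTC")
  registry
}

#' Remove a class from a registry
#'
#' @param registry A [model_registry()].
#' @param label Registered class label.
#' @return The updated registry; remaining entries are untouched.
#' @export
remove_class <- function(registry, label) {
  if (!inherits(registry, "model_registry"))
    stop_invalid("`registry` must be a model_registry")
  assert_string(label, "label")
  if (!label %in% names(registry$entries))
    stop_not_found("no class '%s' in the registry", label)
  registry$entries[[label]] <- NULL
  registry$modified <- format(Sys.time(), tz = "UTC")
  registry
}

#' @export
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry> %d class(es), tile size %s\n",
              length(x$entries),
              if (is.null(x$tile_size)) "unset" else x$tile_size))
  for (nm in names(x$entries))
    cat(sprintf("  %-16s fingerprint %s\n", nm, x$entries[[nm]]$fingerprint))
  invisible(x)
}

#' Registered class labels, in canonical (lexicographic) order
#' @param registry A [model_registry()].
#' @return Character vector.
#' @export
registry_labels <- function(registry) names(registry$entries)

REGISTRY_VERSION <- 1L

serialize_edge_params <- function(p) list(sigma = p$sigma,
                                          low_fraction = p$low_fraction,
                                          high_fraction = p$high_fraction)

#' Save a registry to disk
#'
#' Layout: one subdirectory per class holding `weights.rds`,
#' `metadata.yaml` and `training_log.csv`, plus a top-level `registry.yaml`
#' index. Adding a class to a saved registry is a pure directory addition.
#'
#' @param registry A [model_registry()].
#' @param path Directory to create/write.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  if (!inherits(registry, "model_registry"))
    stop_invalid("`registry` must be a model_registry")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(version = REGISTRY_VERSION,
                        tile_size = registry$tile_size,
                        labels = as.list(names(registry$entries)),
                        created = registry$created,
                        modified = registry$modified),
                   file.path(path, "registry.yaml"))
  for (nm in names(registry$entries)) {
    m <- registry$entries[[nm]]
    cdir <- file.path(path, nm)
    dir.create(cdir, showWarnings = FALSE)
    saveRDS(m$generator_weights, file.path(cdir, "weights.rds"),
            compress = FALSE)
    yaml::write_yaml(list(label = m$label,
                          fingerprint = m$fingerprint,
                          tile_size = m$tile_size,
                          generator_spec = unclass(m$generator_spec),
                          edge_params = serialize_edge_params(m$edge_params),
                          training_config = unclass(m$training_config)),
                     file.path(cdir, "metadata.yaml"))
    log <- do.call(rbind, lapply(seq_along(m$training_log), function(i) {
      l <- m$training_log[[i]]
      data.frame(epoch = i, d_loss = l$d_loss, g_adv = l$g_adv,
                 g_mse = l$g_mse, g_total = l$g_total)
    }))
    utils::write.csv(log, file.path(cdir, "training_log.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Load a registry from disk
#'
#' Fingerprints are recomputed from the stored weights and checked against
#' the saved metadata; any mismatch, missing file, or unknown layout version
#' is a format error naming the offending entry.
#'
#' @param path Directory written by [save_registry()].
#' @return A [model_registry()].
#' @export
load_registry <- function(path) {
  idx_path <- file.path(path, "registry.yaml")
  if (!file.exists(idx_path))
    stop_format("no registry.yaml under %s", path)
  idx <- yaml::read_yaml(idx_path)
  if (is.null(idx$version) || idx$version > REGISTRY_VERSION)
    stop_format("registry layout version %s is not supported",
                format(idx$version))
  reg <- model_registry(tile_size = idx$tile_size)
  reg$created <- idx$created
  for (nm in unlist(idx$labels)) {
    cdir <- file.path(path, nm)
    wpath <- file.path(cdir, "weights.rds")
    mpath <- file.path(cdir, "metadata.yaml")
    if (!file.exists(wpath))
      stop_format("class '%s': missing weights file %s", nm, wpath)
    if (!file.exists(mpath))
      stop_format("class '%s': missing metadata file %s", nm, mpath)
    meta <- yaml::read_yaml(mpath)
    weights <- readRDS(wpath)
    fp <- model_fingerprint(weights)
    if (!identical(fp, meta$fingerprint))
      stop_format("class '%s': weights fingerprint %s does not match stored %s",
                  nm, fp, meta$fingerprint)
    gs <- do.call(generator_spec, meta$generator_spec)
    epar <- do.call(edge_params, meta$edge_params)
    tc <- do.call(training_config, meta$training_config)
    log <- NULL
    lpath <- file.path(cdir, "training_log.csv")
    if (file.exists(lpath)) {
      df <- utils::read.csv(lpath)
      log <- lapply(seq_len(nrow(df)), function(i)
        structure(as.list(df[i, c("d_loss", "g_adv", "g_mse", "g_total")]),
                  class = "loss_bundle"))
    }
    model <- structure(list(label = meta$label,
                            generator_weights = weights,
                            generator_spec = gs,
                            tile_size = meta$tile_size,
                            edge_params = epar,
                            training_config = tc,
                            training_log = log,
                            fingerprint = fp),
                       class = "class_model")
    reg <- add_class(reg, model)
  }
  reg$modified <- idx$modified
  reg
}
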