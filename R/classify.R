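#' Dissimilarity between a tile and its reconstruction
#'
#' All three metrics are oriented as dissimilarities so that the arg-min
#' winner rule applies uniformly: `"mse"` is the mean squared difference
#' over all pixels and channels on the 0-255 scale; `"ssim"` is `1 - SSIM`
#' (mean structural similarity, 11x11 Gaussian window with SD 1.5,
#' K1 = 0.01, K2 = 0.03, dynamic range 255); `"psnr"` is `200 - PSNR` in dB
#' (the 200 dB shift exceeds any finite 8-bit PSNR at supported sizes, so
#' the value is >= 0 and 0 for identical images).
#'
#' @param metric One of `"mse"`, `"ssim"`, `"psnr"`.
#' @param original,reconstruction Arrays of identical shape, 0-255 scale.
#' @return Non-negative scalar; 0 for identical images.
#' @export
dissimilarity <- function(metric, original, reconstruction) {
  metric <- match.arg(tolower(metric), c("mse", "ssim", "psnr"))
  if (!identical(dim(original), dim(reconstruction)))
    stop_invalid("original and reconstruction shapes differ")
  switch(metric,
         mse = mean((original - reconstruction)^2),
         ssim = 1 - ssim_index(original, reconstruction),
         psnr = {
           mse <- mean((original - reconstruction)^2)
           if (mse == 0) 0 else max(0, 200 - 10 * log10(255^2 / mse))
         })
}

# Mean SSIM over channels (Wang et al. convention, dynamic range 255).
ssim_index <- function(a, b, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  c1 <- (k1 * 255)^2; c2 <- (k2 * 255)^2
  per_ch <- function(x, y) {
    mx <- gaussian_blur(x, sigma)
    my <- gaussian_blur(y, sigma)
    vx <- gaussian_blur(x * x, sigma) - mx * mx
    vy <- gaussian_blur(y * y, sigma) - my * my
    cxy <- gaussian_blur(x * y, sigma) - mx * my
    mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx * mx + my * my + c1) * (vx + vy + c2)))
  }
  if (length(dim(a)) == 2L) return(per_ch(a, b))
  mean(vapply(seq_len(dim(a)[3]),
              function(ch) per_ch(a[, , ch], b[, , ch]), numeric(1)))
}

#' Classify a tile by minimum reconstruction error
#'
#' Every class generator in the registry reconstructs the tile from its edge
#' condition (using that model's stored edge parameters); the generator with
#' the smallest dissimilarity is declared the winner and the tile is labeled
#' as that class. Exact ties go to the lexicographically smaller label and
#' are flagged.
#'
#' @param registry A nonempty [model_registry()].
#' @param tile RGB tile matching the registry tile size.
#' @param metric Dissimilarity metric; see [dissimilarity()].
#' @return A `classification_result`: `per_class_errors` (named, in label
#'   order), `predicted_label`, `metric`, `tie_broken`.
#' @export
classify_tile <- function(registry, tile, metric = "mse") {
  if (!inherits(registry, "model_registry"))
    stop_invalid("`registry` must be a model_registry")
  if (length(registry$entries) == 0L)
    stop_state("the registry holds no trained class models")
  assert_tile(tile)
  metric <- match.arg(tolower(metric), c("mse", "ssim", "psnr"))
  errs <- vapply(registry$entries, function(m)
    dissimilarity(metric, tile * 1.0, reconstruct(m, tile) * 1.0),
    numeric(1))
  best <- min(errs)
  winners <- names(errs)[errs == best]
  structure(list(per_class_errors = errs,
                 predicted_label = sort_labels(winners)[1],
                 metric = metric,
                 tie_broken = length(winners) > 1L),
            class = "classification_result")
}

#' Classify a high-power field by majority vote over random windows
#'
#' Samples `n_windows` window corners uniformly with replacement (seeded),
#' classifies every window with [classify_tile()], and takes the majority
#' vote. A vote tie goes to the label with the smaller summed dissimilarity
#' across its winning windows, then lexicographic; ties are flagged.
#'
#' @param registry A nonempty [model_registry()].
#' @param hpf RGB raster at least the window size in each dimension.
#' @param n_windows Number of windows (the classic protocol uses 50).
#' @param window_size Window edge in px; defaults to the registry tile size.
#' @param seed RNG seed for window sampling.
#' @param metric Dissimilarity metric.
#' @return An `hpf_result`: `window_results`, `votes` (named count vector),
#'   `predicted_label`, `n_windows`, `tie_broken`.
#' @export
classify_hpf <- function(registry, hpf, n_windows = 50L, window_size = NULL,
                         seed = 1L, metric = "mse") {
  if (!inherits(registry, "model_registry"))
    stop_invalid("`registry` must be a model_registry")
  if (length(registry$entries) == 0L)
    stop_state("the registry holds no trained class models")
  assert_tile(hpf, "hpf")
  n_windows <- assert_count(n_windows, "n_windows", min = 1L)
  if (is.null(window_size)) window_size <- registry$tile_size
  window_size <- assert_count(window_size, "window_size", min = 1L)
  d <- dim(hpf)
  if (d[1] < window_size || d[2] < window_size)
    stop_invalid("HPF (%dx%d) is smaller than the %d px window",
                 d[1], d[2], window_size)
  corners <- with_rng(seed, cbind(
    sample.int(d[1] - window_size + 1L, n_windows, replace = TRUE) - 1L,
    sample.int(d[2] - window_size + 1L, n_windows, replace = TRUE) - 1L))
  results <- lapply(seq_len(n_windows), function(i) {
    r0 <- corners[i, 1]; c0 <- corners[i, 2]
    win <- hpf[r0 + seq_len(window_size), c0 + seq_len(window_size), ,
               drop = FALSE]
    res <- classify_tile(registry, win, metric = metric)
    res$row <- r0; res$col <- c0
    res
  })
  labels <- registry_labels(registry)
  preds <- vapply(results, `[[`, "", "predicted_label")
  votes <- vapply(labels, function(l) sum(preds == l), integer(1))
  top <- max(votes)
  winners <- labels[votes == top]
  tie <- length(winners) > 1L
  if (tie) {
    sums <- vapply(winners, function(l)
      sum(vapply(results[preds == l], function(r) r$per_class_errors[[l]],
                 numeric(1))), numeric(1))
    winners <- winners[sums == min(sums)]
  }
  structure(list(window_results = results, votes = votes,
                 predicted_label = sort_labels(winners)[1],
                 n_windows = n_windows, tie_broken = tie),
            class = "hpf_result")
}
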