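#' Training configuration for a class cGAN
#'
#' Defaults follow the pix2pix convention: reconstruction weight 100 against
#' adversarial weight 1, Adam with learning rate 2e-4 and first-moment decay
#' 0.5. The GAN noise term z is realised as decoder dropout by default
#' (`noise_mode = "dropout"`), disabled at inference so reconstruction, and
#' hence classification, is deterministic; `noise_mode = "input"` instead
#' appends an explicit Gaussian noise channel to the condition (zeros at
#' inference).
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param beta1 Adam first-moment decay.
#' @param lambda_mse Weight of the reconstruction (MSE) term.
#' @param lambda_adv Weight of the adversarial term.
#' @param seed RNG seed governing initialisation, shuffling, dropout.
#' @param noise_mode `"dropout"` or `"input"`.
#' @param saturating Use the saturating adversarial generator term
#'   `log(1 - D)` instead of the non-saturating `-log D`.
#' @param clip_norm Global gradient-norm cap applied per update to each
#'   network (Inf disables). Small GANs without normalisation layers can
#'   tanh-saturate when the discriminator's input gradients spike;
#'   clipping keeps the generator alive.
#' @return A `training_config` object.
#' @export
training_config <- function(epochs = 5L, batch_size = 4L,
                            learning_rate = 2e-4, beta1 = 0.5,
                            lambda_mse = 100, lambda_adv = 1,
                            seed = 1L, noise_mode = c("dropout", "input"),
                            saturating = FALSE, clip_norm = 5) {
  epochs <- assert_count(epochs, "epochs", min = 1L)
  batch_size <- assert_count(batch_size, "batch_size", min = 1L)
  assert_scalar_number(learning_rate, "learning_rate")
  assert_scalar_number(beta1, "beta1")
  assert_scalar_number(lambda_mse, "lambda_mse")
  assert_scalar_number(lambda_adv, "lambda_adv")
  if (lambda_mse < 0 || lambda_adv < 0)
    stop_invalid("loss weights must be >= 0")
  if (lambda_mse + lambda_adv <= 0)
    stop_invalid("at least one loss weight must be positive")
  noise_mode <- match.arg(noise_mode)
  assert_scalar_number_or_inf(clip_norm, "clip_norm")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, beta1 = beta1,
                 lambda_mse = lambda_mse, lambda_adv = lambda_adv,
                 seed = assert_count(seed, "seed", min = 0L),
                 noise_mode = noise_mode,
                 saturating = assert_flag(saturating, "saturating"),
                 clip_norm = clip_norm),
            class = "training_config")
}

# Normalisation between 8-bit intensities and the model scale [-1, 1].
to_model_scale <- function(x) x / 127.5 - 1
from_model_scale <- function(y) round(clamp255((y + 1) * 127.5))

# Serialize weights deterministically and hash them. The fingerprint is
# recomputable from the weights alone.
model_fingerprint <- function(weights) {
  strip <- function(l) {
    if (is.list(l)) return(lapply(l, strip))
    l
  }
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  saveRDS(strip(weights), tmp, compress = FALSE, version = 3L)
  unname(tools::md5sum(tmp))
}

# Append the noise channel for "input" mode; `draw` toggles random vs zeros.
with_noise_channel <- function(mask, noise_mode, draw) {
  if (noise_mode != "input") return(mask)
  d <- dim(mask)
  z <- if (draw) array(stats::rnorm(d[1] * d[2]), dim = c(d[1], d[2], 1L))
  else array(0, dim = c(d[1], d[2], 1L))
  concat_ch(mask, z)
}

#' Train a cGAN for a single tissue class
#'
#' Alternates discriminator and generator updates over shuffled mini-batches
#' of one class's tiles. The discriminator sees (condition, tile) pairs as
#' real and (condition, reconstruction) pairs as fake; the generator is
#' driven by the weighted sum of the adversarial term and the mean squared
#' reconstruction error. The function receives the tiles of exactly one
#' class and never reads anything else: training a class is by construction
#' independent of the existence or size of other classes' data.
#'
#' Given the same inputs and seed the result is bit-reproducible.
#'
#' @param tiles List of equally sized RGB tiles sharing one `label`
#'   attribute (mixed labels are an error).
#' @param edge_params The [edge_params()] defining the condition; stored in
#'   the model so classification always reuses it.
#' @param gspec,dspec Network specifications ([generator_spec()],
#'   [discriminator_spec()]).
#' @param cfg A [training_config()].
#' @param label Class label; defaults to the tiles' common label.
#' @return A `class_model`: label, generator weights, specs, params, the
#'   per-epoch training log, and a content fingerprint of the weights.
#' @export
train_class_model <- function(tiles, edge_params = ganrecon::edge_params(),
                              gspec = generator_spec(),
                              dspec = discriminator_spec(),
                              cfg = training_config(), label = NULL) {
  if (!is.list(tiles) || length(tiles) < 1L)
    stop_invalid("`tiles` must be a nonempty list of tiles")
  labels <- unique(vapply(tiles, function(t) {
    l <- tile_label(t)
    if (is.null(l)) NA_character_ else l
  }, ""))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1L)
    stop_invalid("tiles carry mixed labels (%s): one cGAN learns one class",
                 paste(labels, collapse = ", "))
  if (is.null(label)) {
    if (length(labels) == 0L)
      stop_invalid("tiles carry no label and `label` was not given")
    label <- labels
  }
  dims <- unique(vapply(tiles, function(t) paste(dim(t), collapse = "x"), ""))
  if (length(dims) != 1L) stop_invalid("tiles differ in size")
  for (t in tiles) assert_tile(t)
  ts <- dim(tiles[[1]])[1]
  if (dim(tiles[[1]])[2] != ts) stop_invalid("tiles must be square")
  if (cfg$noise_mode == "input" && gspec$in_channels == 3L)
    gspec$in_channels <- 4L

  # conditions are a deterministic function of the tiles; compute once
  conds <- lapply(tiles, function(t) detect_edges(t, edge_params)$mask)
  targets <- lapply(tiles, to_model_scale)
  n <- length(tiles)

  with_rng(cfg$seed, {
    gen <- build_generator(gspec, ts, seed = derive_seed(cfg$seed, 1L))
    disc <- build_discriminator(dspec, ts, seed = derive_seed(cfg$seed, 2L))
    ad_g <- init_adam_tree(gen$params)
    ad_d <- init_adam_tree(disc$params)
    t_g <- 0L; t_d <- 0L
    log <- vector("list", cfg$epochs)

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_d <- ep_adv <- ep_mse <- 0
      nb <- 0L
      for (b in batches) {
        # ---- generator forward (cached for the G step) ------------------
        gfwd <- vector("list", length(b))
        xin <- vector("list", length(b))
        for (q in seq_along(b)) {
          xin[[q]] <- with_noise_channel(conds[[b[q]]], cfg$noise_mode, TRUE)
          gfwd[[q]] <- gen_forward(gen, xin[[q]], training = TRUE)
        }
        # ---- discriminator step -----------------------------------------
        gd <- NULL
        d_loss_b <- 0
        for (q in seq_along(b)) {
          i <- b[q]
          real <- disc_forward(disc, concat_ch(conds[[i]], targets[[i]]))
          fake <- disc_forward(disc, concat_ch(conds[[i]], gfwd[[q]]$y))
          d_loss_b <- d_loss_b +
            discriminator_loss(real$prob[1], fake$prob[1])
          br <- disc_backward(disc, real$cache, real$prob - c(1, 0))
          bf <- disc_backward(disc, fake$cache, fake$prob - c(0, 1))
          gd <- acc_grads(gd, add_grads(strip_dx(br), strip_dx(bf)))
        }
        gd <- scale_grads(gd, 1 / length(b))
        gd <- clip_grads(gd, cfg$clip_norm)
        t_d <- t_d + 1L
        up <- apply_adam_tree(disc$params, gd, ad_d, cfg$learning_rate,
                              cfg$beta1, t_d)
        disc$params <- up$params; ad_d <- up$state
        # ---- generator step (against the updated discriminator) ---------
        gg <- NULL
        adv_b <- mse_b <- 0
        for (q in seq_along(b)) {
          i <- b[q]
          y <- gfwd[[q]]$y
          fake <- disc_forward(disc, concat_ch(conds[[i]], y))
          p1 <- min(max(fake$prob[1], LOSS_EPS), 1 - LOSS_EPS)
          if (cfg$saturating) {
            adv_b <- adv_b + log(1 - p1)
            dlogits <- cfg$lambda_adv * (c(0, 1) - fake$prob)
          } else {
            adv_b <- adv_b - log(p1)
            dlogits <- cfg$lambda_adv * (fake$prob - c(1, 0))
          }
          bd <- disc_backward(disc, fake$cache, dlogits)
          dy_adv <- bd$dx[, , 4:6, drop = FALSE]
          diff <- y - targets[[i]]
          mse_b <- mse_b + mean(diff^2)
          dy <- dy_adv + cfg$lambda_mse * 2 * diff / length(diff)
          gg <- acc_grads(gg, gen_backward(gen, gfwd[[q]]$cache, dy))
        }
        gg <- scale_grads(gg, 1 / length(b))
        gg <- clip_grads(gg, cfg$clip_norm)
        t_g <- t_g + 1L
        up <- apply_adam_tree(gen$params, gg, ad_g, cfg$learning_rate,
                              cfg$beta1, t_g)
        gen$params <- up$params; ad_g <- up$state

        ep_d <- ep_d + d_loss_b / length(b)
        ep_adv <- ep_adv + adv_b / length(b)
        ep_mse <- ep_mse + mse_b / length(b)
        nb <- nb + 1L
      }
      log[[ep]] <- loss_bundle(d_loss = ep_d / nb, g_adv = ep_adv / nb,
                               g_mse = ep_mse / nb, cfg = cfg)
    }

    weights <- gen$params
    structure(list(label = label,
                   generator_weights = weights,
                   generator_spec = gspec,
                   tile_size = ts,
                   edge_params = edge_params,
                   training_config = cfg,
                   training_log = log,
                   fingerprint = model_fingerprint(weights)),
              class = "class_model")
  })
}

#' Reconstruct a tile with a trained class model
#'
#' Computes the edge condition with the model's stored parameters and runs
#' the generator in inference mode (dropout disabled, zero noise channel),
#' so the reconstruction is deterministic.
#'
#' @param model A `class_model`.
#' @param tile RGB tile matching the model's training tile size.
#' @return 8-bit RGB array of the same shape, values in \[0, 255\].
#' @export
reconstruct <- function(model, tile) {
  if (!inherits(model, "class_model"))
    stop_invalid("`model` must be a class_model")
  assert_tile(tile)
  if (dim(tile)[1] != model$tile_size || dim(tile)[2] != model$tile_size)
    stop_invalid("tile is %dx%d but the model was trained on %dx%d",
                 dim(tile)[1], dim(tile)[2], model$tile_size, model$tile_size)
  cond <- detect_edges(tile, model$edge_params)$mask
  x <- with_noise_channel(cond, model$training_config$noise_mode, FALSE)
  gen <- structure(list(spec = model$generator_spec,
                        tile_size = model$tile_size,
                        params = model$generator_weights,
                        cache = new.env(parent = emptyenv())),
                   class = "generator")
  from_model_scale(gen_forward(gen, x, training = FALSE)$y)
}

# ---- gradient-tree bookkeeping -------------------------------------------

strip_dx <- function(g) { g$dx <- NULL; g }

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (!is.list(a)) return(a + b)
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- add_grads(a[[nm]], b[[nm]])
  out
}

acc_grads <- function(acc, g) if (is.null(acc)) g else add_grads(acc, g)

scale_grads <- function(g, s) {
  if (!is.list(g)) return(g * s)
  lapply(g, scale_grads, s = s)
}

grad_sq_norm <- function(g) {
  if (!is.list(g)) return(sum(g * g))
  sum(vapply(g, grad_sq_norm, numeric(1)))
}

# Scale the whole gradient tree so its global L2 norm is at most `cap`.
clip_grads <- function(g, cap) {
  if (!is.finite(cap)) return(g)
  nrm <- sqrt(grad_sq_norm(g))
  if (nrm <= cap) g else scale_grads(g, cap / nrm)
}

init_adam_tree <- function(params) {
  walk <- function(l) {
    if (is.list(l)) {
      if (!is.null(l$W)) return(adam_state_conv(l))
      if (!is.null(l$Wd))
        return(list(Wd = list(m = l$Wd * 0, v = l$Wd * 0),
                    bd = list(m = l$bd * 0, v = l$bd * 0)))
      return(lapply(l, walk))
    }
    NULL
  }
  walk(params)
}

apply_adam_tree <- function(params, grads, state, lr, beta1, t,
                            beta2 = 0.999, eps = 1e-8) {
  step1 <- function(val, g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(val = val - lr * mhat / (sqrt(vhat) + eps), st = st)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      r1 <- step1(p$W, g$dW, s$W); r2 <- step1(p$b, g$db, s$b)
      p$W <- r1$val; p$b <- r2$val
      return(list(params = p, state = list(W = r1$st, b = r2$st)))
    }
    if (is.list(p) && !is.null(p$Wd)) {
      r1 <- step1(p$Wd, g$dWd, s$Wd); r2 <- step1(p$bd, g$dbd, s$bd)
      p$Wd <- r1$val; p$bd <- r2$val
      return(list(params = p, state = list(Wd = r1$st, bd = r2$st)))
    }
    if (is.list(p)) {
      ps <- p; ss <- s
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], s[[i]])
        ps[[i]] <- r$params; ss[[i]] <- r$state
      }
      return(list(params = ps, state = ss))
    }
    list(params = p, state = s)
  }
  walk(params, grads, state)
}
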