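# Adversarial losses in probability form. The discriminator maximises the
# probability of telling real from reconstructed pairs; equivalently it
# minimises the cross entropy -log D(x|y) - log(1 - D(G(y)|y)). The
# generator's adversarial term is the non-saturating -log D(G(y)|y) by
# default (same fixed points as the saturating minimax form, better
# gradients early in training).

LOSS_EPS <- 1e-12

clip_prob <- function(p, name) {
  assert_scalar_number(p, name)
  if (p < 0 || p > 1)
    stop_invalid("`%s` must be a probability in [0, 1] (got %g)", name, p)
  min(max(p, LOSS_EPS), 1 - LOSS_EPS)
}

#' Discriminator cross-entropy loss
#'
#' `-log(d_real) - log(1 - d_fake)`: the negated objective the discriminator
#' maximises in the two-player minimax game, evaluated on one real pair and
#' one reconstructed pair. Probabilities are clipped at a machine-safe
#' epsilon before the logs.
#'
#' @param d_real Discriminator probability of "real" on the (condition,
#'   real tile) pair.
#' @param d_fake Discriminator probability of "real" on the (condition,
#'   reconstruction) pair.
#' @return Non-negative scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  d_real <- clip_prob(d_real, "d_real")
  d_fake <- clip_prob(d_fake, "d_fake")
  -log(d_real) - log(1 - d_fake)
}

#' Generator loss bundle
#'
#' Combines the adversarial term with the mean squared reconstruction error:
#' `g_total = lambda_adv * g_adv + lambda_mse * g_mse`. The adversarial term
#' is the non-saturating `-log(d_fake)` (or, if `cfg$saturating`,
#' `log(1 - d_fake)`, which is negative-valued). `g_mse` is the mean over
#' all pixels and channels of the squared difference between reconstruction
#' and target on the model's normalised scale.
#'
#' @param d_fake Discriminator probability of "real" on the reconstruction.
#' @param reconstruction,target Arrays of identical shape on the model's
#'   normalised intensity scale.
#' @param cfg A [training_config()] supplying `lambda_mse`, `lambda_adv`
#'   and `saturating`.
#' @return A `loss_bundle`: list with `d_loss` (`NA` here), `g_adv`,
#'   `g_mse`, `g_total`.
#' @export
generator_loss <- function(d_fake, reconstruction, target,
                           cfg = training_config()) {
  d_fake <- clip_prob(d_fake, "d_fake")
  if (!identical(dim(reconstruction), dim(target)))
    stop_invalid("reconstruction and target shapes differ")
  g_adv <- if (isTRUE(cfg$saturating)) log(1 - d_fake) else -log(d_fake)
  g_mse <- mean((reconstruction - target)^2)
  loss_bundle(d_loss = NA_real_, g_adv = g_adv, g_mse = g_mse, cfg = cfg)
}

loss_bundle <- function(d_loss, g_adv, g_mse, cfg) {
  structure(list(d_loss = d_loss, g_adv = g_adv, g_mse = g_mse,
                 g_total = cfg$lambda_adv * g_adv + cfg$lambda_mse * g_mse),
            class = "loss_bundle")
}
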