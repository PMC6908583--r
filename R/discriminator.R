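#' Discriminator architecture specification
#'
#' A standard convolutional network over the (condition, image) pair:
#' stride-2 4x4 convolutions with leaky-ReLU, a global average pool, and a
#' dense two-way softmax head giving `(P(real), P(fake))`.
#'
#' @param in_channels Input channels: 6, the 3-channel condition concatenated
#'   with the 3-channel candidate image.
#' @param conv_stages Number of stride-2 conv stages (>= 2); the tile size
#'   must be divisible by `2^conv_stages`.
#' @param base_filters Filters at the first stage.
#' @return A `discriminator_spec` object.
#' @export
discriminator_spec <- function(in_channels = 6L, conv_stages = 3L,
                               base_filters = 16L) {
  structure(list(in_channels = assert_count(in_channels, "in_channels"),
                 conv_stages = assert_count(conv_stages, "conv_stages",
                                            min = 2L),
                 base_filters = assert_count(base_filters, "base_filters",
                                             min = 4L)),
            class = "discriminator_spec")
}

disc_init_params <- function(spec) {
  ch <- gen_channels(spec$conv_stages, spec$base_filters)
  convs <- vector("list", spec$conv_stages)
  cin <- spec$in_channels
  for (i in seq_len(spec$conv_stages)) {
    convs[[i]] <- conv_init(4L, cin, ch[i], stride = 2L, pad = 1L)
    cin <- ch[i]
  }
  list(convs = convs,
       dense = list(Wd = matrix(stats::rnorm(cin * 2L, sd = 0.02), cin, 2L),
                    bd = numeric(2L)))
}

#' Build an untrained discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param tile_size Square tile edge in px, divisible by `2^conv_stages`.
#' @param seed RNG seed for weight initialisation.
#' @return A `discriminator` object.
#' @export
build_discriminator <- function(spec, tile_size, seed = 1L) {
  if (!inherits(spec, "discriminator_spec"))
    stop_invalid("`spec` must be a discriminator_spec")
  tile_size <- assert_count(tile_size, "tile_size", min = 4L)
  if (tile_size %% 2^spec$conv_stages != 0)
    stop_invalid("tile_size %d is not divisible by 2^conv_stages = %d",
                 tile_size, 2^spec$conv_stages)
  params <- with_rng(seed, disc_init_params(spec))
  structure(list(spec = spec, tile_size = tile_size, params = params,
                 cache = new.env(parent = emptyenv())),
            class = "discriminator")
}

# Forward pass on an H x W x 6 input. Returns the probability pair
# (P(real), P(fake)) and the cache for backprop.
disc_forward <- function(disc, x) {
  p <- disc$params; cc <- disc$cache
  s <- disc$spec$conv_stages
  fwd <- vector("list", s)
  cur <- x
  for (i in seq_len(s)) {
    f <- conv_fwd(p$convs[[i]], cur, cc)
    fwd[[i]] <- f
    cur <- lrelu(f$y)
  }
  dpool <- dim(cur)
  v <- .colMeans(cur, dpool[1] * dpool[2], dpool[3])
  logits <- drop(crossprod(p$dense$Wd, v)) + p$dense$bd
  prob <- softmax2(logits)
  list(prob = prob,
       cache = list(fwd = fwd, pooled_dim = dpool, v = v, x = x))
}

# Backward from dL/dlogits. Returns parameter gradients and dL/dinput.
disc_backward <- function(disc, cache, dlogits) {
  p <- disc$params
  s <- disc$spec$conv_stages
  dWd <- outer(cache$v, dlogits)
  dbd <- dlogits
  dv <- drop(p$dense$Wd %*% dlogits)
  dd <- cache$pooled_dim
  dcur <- array(rep(dv / (dd[1] * dd[2]), each = dd[1] * dd[2]), dim = dd)
  g_convs <- vector("list", s)
  for (i in rev(seq_len(s))) {
    dz <- lrelu_grad(cache$fwd[[i]]$y, dcur)
    b <- conv_bwd(p$convs[[i]], cache$fwd[[i]], dz)
    g_convs[[i]] <- list(dW = b$dW, db = b$db)
    dcur <- b$dx
  }
  list(convs = g_convs, dense = list(dWd = dWd, dbd = dbd), dx = dcur)
}

#' Run a discriminator forward
#'
#' @param disc A `discriminator` from [build_discriminator()].
#' @param x H x W x in_channels array: condition concatenated with the
#'   candidate image.
#' @return Length-2 probability vector `(P(real), P(fake))` summing to 1.
#' @export
discriminator_forward <- function(disc, x) {
  if (!inherits(disc, "discriminator"))
    stop_invalid("`disc` must be a discriminator")
  if (!is.array(x) || length(dim(x)) != 3L ||
      dim(x)[3] != disc$spec$in_channels)
    stop_invalid("input must be H x W x %d", disc$spec$in_channels)
  disc_forward(disc, x)$prob
}
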