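#' Generator architecture specification
#'
#' The generator is a U-Net: a convolutional encoder that halves resolution
#' at every stage, a bottleneck, and a decoder that doubles resolution with
#' a skip connection concatenating the mirrored encoder stage. The final
#' stage concatenates the input condition itself and a 3x3 convolution with
#' tanh output maps back to 3 bounded image channels. Decoder upsampling is
#' nearest-neighbour followed by a 3x3 convolution. Stage widths are
#' `min(base_filters * 2^(stage-1), 8 * base_filters)`.
#'
#' @param in_channels Input channels (3 for the edge condition; 4 when noise
#'   is provided as an explicit input channel).
#' @param out_channels Output channels (3, RGB).
#' @param depth Number of down/up-sampling stages (>= 2); the tile size must
#'   be divisible by `2^depth`.
#' @param base_filters Filters at the first stage (>= 8).
#' @param dropout_rate Dropout fraction in the innermost decoder stages,
#'   `[0, 1)`; this realises the GAN noise term when `noise_mode = "dropout"`.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(in_channels = 3L, out_channels = 3L, depth = 3L,
                           base_filters = 16L, dropout_rate = 0.5) {
  depth <- assert_count(depth, "depth", min = 2L)
  base_filters <- assert_count(base_filters, "base_filters", min = 8L)
  assert_scalar_number(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("`dropout_rate` must be in [0, 1)")
  structure(list(in_channels = assert_count(in_channels, "in_channels"),
                 out_channels = assert_count(out_channels, "out_channels"),
                 depth = depth, base_filters = base_filters,
                 dropout_rate = dropout_rate),
            class = "generator_spec")
}

gen_channels <- function(depth, base) pmin(base * 2^(seq_len(depth) - 1L),
                                           8L * base)

# Initialise all generator conv layers; assumes RNG is already seeded.
gen_init_params <- function(spec) {
  ch <- gen_channels(spec$depth, spec$base_filters)
  d <- spec$depth
  enc <- vector("list", d)
  cin <- spec$in_channels
  for (i in seq_len(d)) {
    enc[[i]] <- conv_init(4L, cin, ch[i], stride = 2L, pad = 1L)
    cin <- ch[i]
  }
  bott <- conv_init(3L, ch[d], ch[d], stride = 1L, pad = 1L)
  dec <- vector("list", d - 1L)
  cur <- ch[d]
  for (j in seq_len(d - 1L)) {          # j-th decoder step uses skip a_{d-j}
    skip <- ch[d - j]
    dec[[j]] <- conv_init(3L, cur + skip, skip, stride = 1L, pad = 1L)
    cur <- skip
  }
  out <- conv_init(3L, cur + spec$in_channels, spec$out_channels,
                   stride = 1L, pad = 1L)
  list(enc = enc, bott = bott, dec = dec, out = out)
}

#' Build an untrained U-Net generator
#'
#' @param spec A [generator_spec()].
#' @param tile_size Square tile edge in px; must be divisible by
#'   `2^spec$depth`.
#' @param seed RNG seed for weight initialisation (Gaussian, SD 0.02).
#' @return A `generator` object holding the parameters and spec.
#' @export
build_generator <- function(spec, tile_size, seed = 1L) {
  if (!inherits(spec, "generator_spec"))
    stop_invalid("`spec` must be a generator_spec")
  tile_size <- assert_count(tile_size, "tile_size", min = 4L)
  if (tile_size %% 2^spec$depth != 0)
    stop_invalid("tile_size %d is not divisible by 2^depth = %d",
                 tile_size, 2^spec$depth)
  params <- with_rng(seed, gen_init_params(spec))
  structure(list(spec = spec, tile_size = tile_size, params = params,
                 cache = new.env(parent = emptyenv())),
            class = "generator")
}

# Forward pass. `x` is H x W x in_channels (edge condition, values 0/1, plus
# optional noise channel). When `training`, dropout is applied in the
# innermost decoder stages. Returns output in [-1, 1] plus the cache needed
# for backprop.
gen_forward <- function(gen, x, training = FALSE) {
  sp <- gen$spec; p <- gen$params; cc <- gen$cache
  d <- sp$depth
  n_drop <- min(3L, d - 1L)
  a <- vector("list", d)
  z <- vector("list", d)
  fwd_enc <- vector("list", d)
  cur <- x
  for (i in seq_len(d)) {
    f <- conv_fwd(p$enc[[i]], cur, cc)
    fwd_enc[[i]] <- f
    z[[i]] <- f$y
    a[[i]] <- lrelu(f$y)
    cur <- a[[i]]
  }
  fb <- conv_fwd(p$bott, cur, cc)
  ab <- lrelu(fb$y)
  cur <- ab
  fwd_dec <- vector("list", d - 1L)
  cat_dec <- vector("list", d - 1L)
  drop_mask <- vector("list", d - 1L)
  for (j in seq_len(d - 1L)) {
    up <- upsample2(cur)
    cat <- concat_ch(up, a[[d - j]])
    f <- conv_fwd(p$dec[[j]], cat, cc)
    act <- relu(f$y)
    if (training && sp$dropout_rate > 0 && j <= n_drop) {
      m <- array(stats::runif(length(act)) >= sp$dropout_rate,
                 dim = dim(act)) / (1 - sp$dropout_rate)
      act <- act * m
      drop_mask[[j]] <- m
    }
    fwd_dec[[j]] <- f
    cat_dec[[j]] <- dim(up)[3]
    cur <- act
  }
  up <- upsample2(cur)
  cat_out <- concat_ch(up, x)
  fo <- conv_fwd(p$out, cat_out, cc)
  y <- tanh(fo$y)
  list(y = y,
       cache = list(z = z, a = a, fwd_enc = fwd_enc, fb = fb, ab = ab,
                    fwd_dec = fwd_dec, cat_dec = cat_dec,
                    drop_mask = drop_mask, fo = fo, y = y,
                    up_out_ch = dim(up)[3]))
}

# Backward pass: gradient of a scalar loss wrt all generator parameters,
# given dL/dy. Returns a list of per-layer conv gradients.
gen_backward <- function(gen, cache, dy) {
  sp <- gen$spec; p <- gen$params
  d <- sp$depth
  dz_out <- dy * (1 - cache$y^2)
  bo <- conv_bwd(p$out, cache$fo, dz_out)
  g_out <- list(dW = bo$dW, db = bo$db)
  nch <- cache$up_out_ch
  dup <- bo$dx[, , seq_len(nch), drop = FALSE]   # condition-skip grad dropped
  dcur <- upsample2_bwd(dup)
  dA <- vector("list", d)                        # accumulated encoder grads
  g_dec <- vector("list", d - 1L)
  for (j in rev(seq_len(d - 1L))) {
    if (!is.null(cache$drop_mask[[j]]))
      dcur <- dcur * cache$drop_mask[[j]]
    dz <- relu_grad(cache$fwd_dec[[j]]$y, dcur)
    bd <- conv_bwd(p$dec[[j]], cache$fwd_dec[[j]], dz)
    g_dec[[j]] <- list(dW = bd$dW, db = bd$db)
    nup <- cache$cat_dec[[j]]
    dup <- bd$dx[, , seq_len(nup), drop = FALSE]
    dskip <- bd$dx[, , nup + seq_len(dim(bd$dx)[3] - nup), drop = FALSE]
    i <- d - j
    dA[[i]] <- if (is.null(dA[[i]])) dskip else dA[[i]] + dskip
    dcur <- upsample2_bwd(dup)
  }
  # dcur is now the gradient at the bottleneck output
  dzb <- lrelu_grad(cache$fb$y, dcur)
  bb <- conv_bwd(p$bott, cache$fb, dzb)
  g_bott <- list(dW = bb$dW, db = bb$db)
  dA[[d]] <- if (is.null(dA[[d]])) bb$dx else dA[[d]] + bb$dx
  g_enc <- vector("list", d)
  for (i in rev(seq_len(d))) {
    dz <- lrelu_grad(cache$z[[i]], dA[[i]])
    be <- conv_bwd(p$enc[[i]], cache$fwd_enc[[i]], dz)
    g_enc[[i]] <- list(dW = be$dW, db = be$db)
    if (i > 1L)
      dA[[i - 1L]] <- if (is.null(dA[[i - 1L]])) be$dx else dA[[i - 1L]] + be$dx
  }
  list(enc = g_enc, bott = g_bott, dec = g_dec, out = g_out)
}

#' Number of trainable parameters
#'
#' @param x A `generator`, `discriminator`, or `class_model`.
#' @return Integer count of scalar weights and biases.
#' @export
n_parameters <- function(x) {
  p <- if (inherits(x, "class_model")) x$generator_weights
  else if (inherits(x, c("generator", "discriminator"))) x$params
  else stop_invalid("`x` must be a generator, discriminator or class_model")
  count <- function(l) {
    if (is.list(l)) {
      if (!is.null(l$W)) return(length(l$W) + length(l$b))
      if (!is.null(l$Wd)) return(length(l$Wd) + length(l$bd))
      return(sum(vapply(l, count, numeric(1))))
    }
    0
  }
  as.integer(count(p))
}

#' Run a generator forward in inference mode
#'
#' @param gen A `generator` from [build_generator()].
#' @param condition H x W x in_channels array (the edge condition).
#' @return H x W x out_channels array with values in \[-1, 1\].
#' @export
generator_forward <- function(gen, condition) {
  if (!inherits(gen, "generator")) stop_invalid("`gen` must be a generator")
  if (!is.array(condition) || length(dim(condition)) != 3L ||
      dim(condition)[3] != gen$spec$in_channels)
    stop_invalid("condition must be H x W x %d", gen$spec$in_channels)
  gen_forward(gen, condition, training = FALSE)$y
}
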