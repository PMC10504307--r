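#' Generator architecture specification
#'
#' The generator is a U-Net: an encoding path of convolution + ReLU blocks
#' each followed by 2x2 max pooling, a bottleneck convolution, and a mirrored
#' decoding path of nearest-neighbour upsampling + convolution blocks with
#' skip concatenations from the matching encoder level, closed by a 1-channel
#' tanh head so outputs live in `[-1, 1]` like the normalized targets.
#'
#' @param depth number of down/up-sampling levels (at least 2); input patch
#'   sides must be divisible by `2^depth`.
#' @param base_filters filters at the first level.
#' @param filter_growth per-level filter multiplier.
#' @param max_filters cap on filters per layer.
#' @param kernel_size odd convolution kernel side.
#' @param use_skip_connections concatenate encoder features into the decoder
#'   (default `TRUE`).
#' @param in_channels input channels (3 for fundus patches).
#' @param output_activation `"tanh"` for synthesis, `"sigmoid"` for the
#'   direct-segmentation mode.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 4, base_filters = 64, filter_growth = 2,
                           max_filters = 512, kernel_size = 3,
                           use_skip_connections = TRUE, in_channels = 3,
                           output_activation = c("tanh", "sigmoid")) {
  if (depth < 2) stop("depth must be at least 2")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 filter_growth = filter_growth,
                 max_filters = as.integer(max_filters),
                 kernel_size = as.integer(kernel_size),
                 use_skip_connections = isTRUE(use_skip_connections),
                 in_channels = as.integer(in_channels),
                 output_activation = match.arg(output_activation)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A convolutional classifier over the 4-channel concatenation of a fundus
#' patch and a candidate OCT-A patch: convolution + leaky-ReLU + 2x2
#' max-pool blocks followed by global average pooling and a dense sigmoid
#' head emitting one probability-real score per patch.
#'
#' @param n_conv_blocks number of conv/pool blocks (at least 1).
#' @param base_filters filters in the first block.
#' @param filter_growth per-block filter multiplier.
#' @param max_filters cap on filters per block.
#' @param kernel_size odd convolution kernel side.
#' @param in_channels input channels (3 fundus + 1 OCT-A).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_conv_blocks = 3, base_filters = 32,
                               filter_growth = 2, max_filters = 256,
                               kernel_size = 3, in_channels = 4) {
  if (n_conv_blocks < 1) stop("n_conv_blocks must be at least 1")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  structure(list(n_conv_blocks = as.integer(n_conv_blocks),
                 base_filters = as.integer(base_filters),
                 filter_growth = filter_growth,
                 max_filters = as.integer(max_filters),
                 kernel_size = as.integer(kernel_size),
                 in_channels = as.integer(in_channels)),
            class = "discriminator_spec")
}

gen_filters <- function(spec) {
  pmin(spec$max_filters,
       round(spec$base_filters * spec$filter_growth^(0:spec$depth)))
}

#' Build a generator with seeded initial weights
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for the He-normal weight initialization.
#' @return An object of class `octa_generator`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- spec$kernel_size
  f <- gen_filters(spec)        # f[i] filters at level i; f[depth+1] bottleneck
  d <- spec$depth
  params <- with_seed(seed, {
    p <- list()
    cin <- spec$in_channels
    for (i in seq_len(d)) {
      p[[paste0("enc", i)]] <- init_conv(k, cin, f[i])
      cin <- f[i]
    }
    p[["bottleneck"]] <- init_conv(k, f[d], f[d + 1])
    cin <- f[d + 1]
    for (i in rev(seq_len(d))) {
      p[[paste0("up", i)]] <- init_conv(k, cin, f[i])
      fuse_in <- if (spec$use_skip_connections) 2L * f[i] else f[i]
      p[[paste0("fuse", i)]] <- init_conv(k, fuse_in, f[i])
      cin <- f[i]
    }
    p[["head"]] <- init_conv(k, f[1], 1L, gain = 1)
    p
  })
  structure(list(spec = spec, params = params, seed = seed),
            class = "octa_generator")
}

#' Number of trainable parameters
#'
#' @param net an `octa_generator` or `octa_discriminator`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) n_params(net$params)

check_patch_size <- function(x, depth) {
  d <- dim(x)
  if (d[1] %% 2^depth != 0 || d[2] %% 2^depth != 0)
    stop("patch side (", d[1], "x", d[2], ") must be divisible by 2^depth = ",
         2^depth)
}

#' Run the generator on a normalized fundus patch
#'
#' @param G an [build_generator()] result.
#' @param x numeric array `S x S x in_channels`, values in `[-1, 1]`.
#' @param keep_cache retain intermediate activations for backpropagation.
#' @return The synthetic patch (`S x S x 1`); with `keep_cache = TRUE`, a
#'   list `(y, cache)`.
#' @export
generator_forward <- function(G, x, keep_cache = FALSE) {
  spec <- G$spec; p <- G$params; k <- spec$kernel_size; d <- spec$depth
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  check_patch_size(x, d)
  cache <- new.env(parent = emptyenv())
  cache$x <- x
  conv <- function(h, name) {
    if (keep_cache) {
      cf <- .conv2d_forward_cols(h, p[[name]]$w, p[[name]]$b, k)
      cache[[paste0(name, "_cols")]] <- cf$cols
      cf$y
    } else conv_fw(h, p[[name]]$w, p[[name]]$b, k)
  }
  h <- x
  for (i in seq_len(d)) {
    pre <- conv(h, paste0("enc", i))
    act <- relu_fw(pre)
    pool <- .maxpool2_forward(act)
    cache[[paste0("enc_pre", i)]] <- pre
    cache[[paste0("enc_act", i)]] <- act
    cache[[paste0("pool_in", i)]] <- dim(act)
    cache[[paste0("pool_which", i)]] <- pool$which
    h <- pool$y
  }
  pre <- conv(h, "bottleneck")
  h <- relu_fw(pre)
  cache$bott_pre <- pre
  for (i in rev(seq_len(d))) {
    up <- .upsample2_forward(h)
    pre <- conv(up, paste0("up", i))
    act <- relu_fw(pre)
    cache[[paste0("up_pre", i)]] <- pre
    fuse_in <- if (spec$use_skip_connections) {
      sk <- cache[[paste0("enc_act", i)]]
      arr <- array(0, c(dim(act)[1], dim(act)[2], dim(act)[3] + dim(sk)[3]))
      arr[, , seq_len(dim(act)[3])] <- act
      arr[, , dim(act)[3] + seq_len(dim(sk)[3])] <- sk
      arr
    } else act
    pre <- conv(fuse_in, paste0("fuse", i))
    h <- relu_fw(pre)
    cache[[paste0("fuse_pre", i)]] <- pre
  }
  pre <- conv(h, "head")
  y <- if (spec$output_activation == "tanh") tanh(pre) else sigmoid_fw(pre)
  cache$y <- y
  if (keep_cache) list(y = y, cache = cache) else y
}

# Backpropagate dL/dy through the generator; returns named gradient list.
generator_backward <- function(G, cache, dy) {
  spec <- G$spec; p <- G$params; k <- spec$kernel_size; d <- spec$depth
  grads <- list()
  conv_back <- function(name, dpre) {
    w <- p[[name]]$w
    bw <- .conv2d_backward_cols(cache[[paste0(name, "_cols")]], w, dpre,
                                nrow(w) / (k * k), k)
    grads[[name]] <<- list(w = bw$dw, b = as.numeric(bw$db))
    bw$dx
  }
  y <- cache$y
  dpre <- if (spec$output_activation == "tanh") tanh_bw(y, dy)
          else dy * y * (1 - y)
  dh <- conv_back("head", dpre)
  dskip <- vector("list", d)
  for (i in seq_len(d)) {          # decoder levels in reverse forward order
    dpre <- relu_bw(cache[[paste0("fuse_pre", i)]], dh)
    dfuse <- conv_back(paste0("fuse", i), dpre)
    nf <- dim(cache[[paste0("up_pre", i)]])[3]
    dact <- dfuse[, , seq_len(nf), drop = FALSE]
    if (spec$use_skip_connections)
      dskip[[i]] <- dfuse[, , -seq_len(nf), drop = FALSE]
    dpre <- relu_bw(cache[[paste0("up_pre", i)]], dact)
    dh <- .upsample2_backward(conv_back(paste0("up", i), dpre))
  }
  dpre <- relu_bw(cache$bott_pre, dh)
  dh <- conv_back("bottleneck", dpre)
  for (i in rev(seq_len(d))) {     # encoder levels, input layer last
    din <- cache[[paste0("pool_in", i)]]
    dact <- .maxpool2_backward(dh, cache[[paste0("pool_which", i)]],
                               din[1], din[2])
    if (!is.null(dskip[[i]])) dact <- dact + dskip[[i]]
    dpre <- relu_bw(cache[[paste0("enc_pre", i)]], dact)
    dh <- conv_back(paste0("enc", i), dpre)
  }
  grads
}

#' Build a discriminator with seeded initial weights
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `octa_discriminator`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  k <- spec$kernel_size
  f <- pmin(spec$max_filters,
            round(spec$base_filters *
                    spec$filter_growth^(0:(spec$n_conv_blocks - 1))))
  params <- with_seed(seed, {
    p <- list()
    cin <- spec$in_channels
    for (i in seq_len(spec$n_conv_blocks)) {
      p[[paste0("conv", i)]] <- init_conv(k, cin, f[i])
      cin <- f[i]
    }
    fan <- f[spec$n_conv_blocks]
    p[["dense"]] <- list(w = matrix(rnorm(fan, 0, sqrt(1 / fan)), fan, 1),
                         b = 0)
    p
  })
  structure(list(spec = spec, params = params, seed = seed),
            class = "octa_discriminator")
}

#' Score a (fundus, OCT-A) patch pair as real or synthetic
#'
#' @param D an [build_discriminator()] result.
#' @param x fundus patch `S x S x 3`, normalized.
#' @param y candidate OCT-A patch `S x S x 1`, normalized.
#' @param keep_cache retain activations for backpropagation.
#' @return Scalar score strictly inside `(0, 1)`; with `keep_cache = TRUE`, a
#'   list `(score, cache)`.
#' @export
discriminator_forward <- function(D, x, y, keep_cache = FALSE) {
  spec <- D$spec; p <- D$params; k <- spec$kernel_size
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  z <- array(0, c(dim(x)[1], dim(x)[2], dim(x)[3] + dim(y)[3]))
  z[, , seq_len(dim(x)[3])] <- x
  z[, , dim(x)[3] + seq_len(dim(y)[3])] <- y
  check_patch_size(z, spec$n_conv_blocks)
  cache <- new.env(parent = emptyenv())
  cache$nx <- dim(x)[3]
  h <- z
  for (i in seq_len(spec$n_conv_blocks)) {
    nm <- paste0("conv", i)
    if (keep_cache) {
      cf <- .conv2d_forward_cols(h, p[[nm]]$w, p[[nm]]$b, k)
      cache[[paste0(nm, "_cols")]] <- cf$cols
      pre <- cf$y
    } else pre <- conv_fw(h, p[[nm]]$w, p[[nm]]$b, k)
    act <- lrelu_fw(pre)
    pool <- .maxpool2_forward(act)
    cache[[paste0("pre", i)]] <- pre
    cache[[paste0("act_dim", i)]] <- dim(act)
    cache[[paste0("which", i)]] <- pool$which
    h <- pool$y
  }
  cache$gap_in <- h
  v <- apply(h, 3, mean)
  cache$v <- v
  logit <- sum(v * p$dense$w) + p$dense$b
  score <- sigmoid_fw(logit)
  cache$score <- score
  if (keep_cache) list(score = score, cache = cache) else score
}

# Backprop d(loss)/d(score) through D; returns grads and input gradients
# split into the fundus (dx) and candidate (dy) channels.
discriminator_backward <- function(D, cache, dscore) {
  spec <- D$spec; p <- D$params; k <- spec$kernel_size
  s <- cache$score
  dlogit <- dscore * s * (1 - s)
  grads <- list(dense = list(w = matrix(dlogit * cache$v, ncol = 1),
                             b = dlogit))
  dv <- dlogit * as.numeric(p$dense$w)
  gi <- cache$gap_in
  npx <- dim(gi)[1] * dim(gi)[2]
  dh <- array(rep(dv / npx, each = npx), dim(gi))
  for (i in rev(seq_len(spec$n_conv_blocks))) {
    ad <- cache[[paste0("act_dim", i)]]
    dact <- .maxpool2_backward(dh, cache[[paste0("which", i)]], ad[1], ad[2])
    dpre <- lrelu_bw(cache[[paste0("pre", i)]], dact)
    nm <- paste0("conv", i)
    w <- p[[nm]]$w
    bw <- .conv2d_backward_cols(cache[[paste0(nm, "_cols")]], w, dpre,
                                nrow(w) / (k * k), k)
    grads[[nm]] <- list(w = bw$dw, b = as.numeric(bw$db))
    dh <- bw$dx
  }
  nx <- cache$nx
  list(grads = grads,
       dx = dh[, , seq_len(nx), drop = FALSE],
       dy = dh[, , nx + seq_len(dim(dh)[3] - nx), drop = FALSE])
}

#' Theoretical receptive field of the discriminator's conv stack
#'
#' One feature-map unit after the last pooling block sees a square input
#' window computed by the standard recurrence: each `k x k` convolution adds
#' `(k - 1) * jump` pixels, each 2x2 pool adds `jump` and doubles the jump.
#'
#' @param spec a [discriminator_spec()].
#' @return Receptive field side in pixels.
#' @export
receptive_field <- function(spec) {
  rf <- 1; jump <- 1
  for (i in seq_len(spec$n_conv_blocks)) {
    rf <- rf + (spec$kernel_size - 1) * jump   # conv
    rf <- rf + jump                            # 2x2 pool
    jump <- jump * 2
  }
  rf
}

# ---- losses (the adversarial game and its reconstruction anchor) ---------

#' Reconstruction loss between real and synthetic patches
#'
#' Mean over pixels of `|y - g_x|` (`l1`, the default) or `(y - g_x)^2`
#' (`l2`).
#'
#' @param y real OCT-A patch.
#' @param g_x synthetic patch of the same shape.
#' @param norm `"l1"` or `"l2"`.
#' @return Nonnegative scalar, zero iff the patches are identical.
#' @export
reconstruction_loss <- function(y, g_x, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (!identical(dim(y), dim(g_x)) && length(y) != length(g_x))
    stop("shape mismatch between y and g_x")
  d <- y - g_x
  if (norm == "l1") mean(abs(d)) else mean(d^2)
}

# derivative of reconstruction_loss w.r.t. g_x
reconstruction_grad <- function(y, g_x, norm = "l1") {
  n <- length(y)
  if (norm == "l1") sign(g_x - y) / n else 2 * (g_x - y) / n
}

#' Adversarial loss terms for one (real, fake) score pair
#'
#' The discriminator minimizes `-[log d_real + log(1 - d_fake)]`, i.e.
#' maximizes the value of the adversarial game; the generator minimizes the
#' non-saturating `-log d_fake`. Scores are clamped to `[eps, 1 - eps]`
#' before the logarithms.
#'
#' @param d_real discriminator score on the real pair, in `[0, 1]`.
#' @param d_fake discriminator score on the synthetic pair, in `[0, 1]`.
#' @param eps clamping constant (default `1e-7`).
#' @return List with `l_adv_d`, `l_adv_g`, and `game_value`
#'   (`log d_real + log(1 - d_fake)`, the quantity the two players fight
#'   over).
#' @export
adversarial_loss <- function(d_real, d_fake, eps = 1e-7) {
  if (d_real < 0 || d_real > 1 || d_fake < 0 || d_fake > 1)
    stop("scores must lie in [0, 1]")
  r <- min(max(d_real, eps), 1 - eps)
  f <- min(max(d_fake, eps), 1 - eps)
  list(l_adv_d = -(log(r) + log(1 - f)),
       l_adv_g = -log(f),
       game_value = log(r) + log(1 - f))
}

#' Total generator objective
#'
#' The adversarial term plus `lambda` times the reconstruction term; the
#' reconstruction weight defaults to 100.
#'
#' @param l_rec reconstruction loss value.
#' @param l_adv_g generator adversarial loss value.
#' @param lambda nonnegative reconstruction weight.
#' @return Scalar objective value.
#' @export
generator_objective <- function(l_rec, l_adv_g, lambda = 100) {
  if (lambda < 0) stop("lambda must be nonnegative")
  l_adv_g + lambda * l_rec
}
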