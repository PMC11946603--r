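#' Configure the residual U-Net
#'
#' Architecture hyperparameters of the 2D residual U-Net: a single-channel
#' input, a four-channel (class) output, an encoder/decoder with one
#' stride-2 resolution level per entry of `strides`, residual units with
#' `num_res_units` convolutional subunits per encoder block (one per decoder
#' block), instance normalization, PReLU activations and elementwise dropout.
#' The default configuration is the final published-style model: feature
#' channels `[16, 32, 64, 128]`, strides of 2, 16 residual units per block,
#' dropout 0.3.
#'
#' @param in_channels Number of input channels; fixed to 1 (grayscale).
#' @param out_channels Number of output channels; fixed to 4 (background +
#'   three structures).
#' @param channels Strictly increasing feature-channel counts, length >= 2.
#' @param strides Downsampling stride per level; length `length(channels)-1`.
#' @param num_res_units Convolutional subunits per encoder residual unit.
#' @param kernel_size,up_kernel_size Convolution kernel sizes (odd).
#' @param dropout Dropout probability in `[0, 1)`.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, out_channels = 4L,
                        channels = c(16L, 32L, 64L, 128L),
                        strides = rep(2L, length(channels) - 1L),
                        num_res_units = 16L,
                        kernel_size = 3L, up_kernel_size = 3L,
                        dropout = 0.3) {
  if (in_channels != 1L) stop("in_channels is fixed to 1 (grayscale input)")
  if (out_channels != 4L) stop("out_channels is fixed to 4 (class count)")
  channels <- as.integer(channels)
  if (length(channels) < 2L || any(diff(channels) <= 0L)) {
    stop("'channels' must be a strictly increasing vector of length >= 2")
  }
  strides <- as.integer(strides)
  if (length(strides) != length(channels) - 1L || any(strides < 1L)) {
    stop("'strides' must have length(channels) - 1 positive entries")
  }
  if (kernel_size %% 2L == 0L || up_kernel_size %% 2L == 0L) {
    stop("kernel sizes must be odd")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(
    list(in_channels = 1L, out_channels = 4L, channels = channels,
         strides = strides, num_res_units = as.integer(num_res_units),
         kernel_size = as.integer(kernel_size),
         up_kernel_size = as.integer(up_kernel_size), dropout = dropout),
    class = "unet_config"
  )
}

#' Build a residual U-Net model
#'
#' Constructs the recursive encoder/decoder: each level is
#' `down -> [skip-concatenation around the deeper levels] -> up`. Encoder
#' blocks are residual units whose first subunit carries the stride (the
#' residual path uses a strided convolution, or a 1x1 convolution on channel
#' change at stride 1); the bottleneck is a stride-1 residual unit; decoder
#' blocks are a transposed convolution followed by a single-subunit residual
#' unit (plain convolution with identity skip at the topmost level, where the
#' network emits logits).
#'
#' @param config A [unet_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `resunet` with elements `config`, `net`,
#'   `n_parameters`, `size_divisor` (inputs must have H and W divisible by
#'   this).
#' @export
build_model <- function(config = unet_config(), seed = NULL) {
  stopifnot(inherits(config, "unet_config"))
  builder <- function() unet_block(config$in_channels, config$out_channels,
                                   config$channels, config$strides, config,
                                   is_top = TRUE)
  net <- if (is.null(seed)) builder() else withr::with_seed(seed, builder())
  model <- structure(
    list(config = config, net = net,
         size_divisor = as.integer(prod(config$strides))),
    class = "resunet"
  )
  model$n_parameters <- count_parameters(model)
  model
}

unet_block <- function(inc, outc, channels, strides, cfg, is_top) {
  c1 <- channels[1]
  s1 <- strides[1]
  if (length(channels) > 2L) {
    sub <- unet_block(c1, c1, channels[-1], strides[-1], cfg, is_top = FALSE)
    upc <- 2L * c1
  } else {
    sub <- down_layer(c1, channels[2], 1L, cfg)   # bottleneck
    upc <- c1 + channels[2]
  }
  nn_seq(down_layer(inc, c1, s1, cfg),
         nn_skipcat(sub),
         up_layer(upc, outc, s1, cfg, is_top))
}

adn_layers <- function(cfg) {
  layers <- list(nn_instnorm())
  if (cfg$dropout > 0) layers <- c(layers, list(nn_dropout(cfg$dropout)))
  c(layers, list(nn_prelu()))
}

conv_subunit <- function(inc, outc, stride, cfg, conv_only = FALSE) {
  conv <- nn_conv(inc, outc, cfg$kernel_size, stride)
  if (conv_only) return(conv)
  nn_seq_list(c(list(conv), adn_layers(cfg)))
}

residual_unit <- function(inc, outc, stride, cfg, subunits,
                          last_conv_only = FALSE) {
  subunits <- max(1L, subunits)
  layers <- vector("list", subunits)
  sin <- inc; sstride <- stride
  for (i in seq_len(subunits)) {
    conv_only <- last_conv_only && i == subunits
    layers[[i]] <- conv_subunit(sin, outc, sstride, cfg,
                                conv_only = conv_only)
    sin <- outc; sstride <- 1L
  }
  residual <- NULL
  if (stride != 1L || inc != outc) {
    rk <- if (stride != 1L) cfg$kernel_size else 1L
    residual <- nn_conv(inc, outc, rk, stride)
  }
  nn_resunit(nn_seq_list(layers), residual)
}

down_layer <- function(inc, outc, stride, cfg) {
  if (cfg$num_res_units > 0L) {
    residual_unit(inc, outc, stride, cfg, cfg$num_res_units)
  } else {
    conv_subunit(inc, outc, stride, cfg)
  }
}

up_layer <- function(inc, outc, stride, cfg, is_top) {
  conv_only <- is_top && cfg$num_res_units == 0L
  upconv <- nn_conv(inc, outc, cfg$up_kernel_size, stride, transposed = TRUE)
  up <- if (conv_only) upconv else nn_seq_list(c(list(upconv),
                                                 adn_layers(cfg)))
  if (cfg$num_res_units > 0L) {
    ru <- residual_unit(outc, outc, 1L, cfg, 1L, last_conv_only = is_top)
    nn_seq(up, ru)
  } else {
    up
  }
}

#' Number of trainable parameters of a model
#'
#' @param model A `resunet` from [build_model()].
#' @return Integer parameter count (convolution weights and biases, PReLU
#'   slopes; instance normalization is affine-free).
#' @export
count_parameters <- function(model) {
  leaves <- nn_param_leaves(model$net)
  sum(vapply(leaves, function(p) length(tree_get(model$net, p)), numeric(1)))
}

#' @export
print.resunet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<resunet> channels [%s], strides [%s], %d res units/block, dropout %.2g\n",
    paste(cfg$channels, collapse = ", "),
    paste(cfg$strides, collapse = ", "),
    cfg$num_res_units, cfg$dropout))
  cat(sprintf("  %s trainable parameters; input H,W must be divisible by %d\n",
              format(x$n_parameters, big.mark = ","), x$size_divisor))
  invisible(x)
}

#' Soft Dice loss for multi-class softmax probabilities
#'
#' `1 - mean_k (2 * sum(p_k g_k) + eps) / (sum(p_k) + sum(g_k) + eps)` over
#' the included classes, where `p` are softmax probabilities and `g` the
#' one-hot reference. The background channel is excluded by default.
#'
#' @param probabilities Array `[H, W, 4]` of per-pixel class probabilities.
#' @param reference Array `[H, W, 4]` one-hot reference.
#' @param include_background Include channel 1 in the mean?
#' @param eps Smoothing constant (numerator and denominator), default 1e-5.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(probabilities, reference,
                           include_background = FALSE, eps = 1e-5) {
  if (!identical(dim(probabilities), dim(reference))) {
    stop("shape mismatch between probabilities and reference")
  }
  K <- dim(probabilities)[3]
  ks <- if (include_background) seq_len(K) else 2:K
  dices <- vapply(ks, function(k) {
    p <- probabilities[, , k]; g <- reference[, , k]
    (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  }, numeric(1))
  1 - mean(dices)
}

# loss + gradient wrt logits (softmax + soft dice), used by the trainer
dice_loss_grad <- function(logits, onehot, include_background = FALSE,
                           eps = 1e-5) {
  d <- dim(logits)
  K <- d[3]
  zm <- matrix(logits, d[1] * d[2], K)
  zm <- zm - apply(zm, 1, max)
  em <- exp(zm)
  pm <- em / rowSums(em)
  p <- array(pm, d)
  ks <- if (include_background) seq_len(K) else 2:K
  dldp <- array(0, d)
  dices <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    pk <- p[, , k]; gk <- onehot[, , k]
    num <- 2 * sum(pk * gk) + eps
    den <- sum(pk) + sum(gk) + eps
    dices[j] <- num / den
    # d(1 - mean dice)/dp_k = -(2*g*den - num) / den^2 / |ks|
    dldp[, , k] <- -(2 * gk * den - num) / (den^2) / length(ks)
  }
  # chain through softmax: dz = p * (dldp - sum_k dldp_k p_k)
  dot <- array(rowSums(matrix(dldp, d[1] * d[2], K) * pm), d[1:2])
  dz <- p * (dldp - array(rep(dot, K), d))
  list(loss = 1 - mean(dices), dz = dz, probs = p)
}

softmax_probs <- function(logits) {
  d <- dim(logits)
  zm <- matrix(logits, d[1] * d[2], d[3])
  zm <- zm - apply(zm, 1, max)
  em <- exp(zm)
  array(em / rowSums(em), d)
}

one_hot_mask <- function(labels, K = 4L) {
  d <- dim(labels)
  oh <- array(0, c(d[1], d[2], K))
  for (k in seq_len(K)) oh[, , k] <- (labels == (k - 1L)) * 1
  oh
}

# symmetric zero padding to the next multiple of m, with crop-back info
pad_to_multiple <- function(mat, m) {
  H <- nrow(mat); W <- ncol(mat)
  Ht <- as.integer(ceiling(H / m) * m)
  Wt <- as.integer(ceiling(W / m) * m)
  top <- (Ht - H) %/% 2L
  left <- (Wt - W) %/% 2L
  out <- matrix(0, Ht, Wt)
  out[top + seq_len(H), left + seq_len(W)] <- mat
  list(mat = out, top = top, left = left, H = H, W = W)
}

crop_from_pad <- function(arr, padinfo) {
  arr[padinfo$top + seq_len(padinfo$H),
      padinfo$left + seq_len(padinfo$W), , drop = FALSE]
}
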