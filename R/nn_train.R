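#' Training configuration for the residual U-Net
#'
#' Defaults follow the published recipe: 150 epochs, batch size 2, Adam with
#' initial learning rate 1e-3, reduce-on-plateau scheduling of the learning
#' rate driven by the validation mean Dice (factor 0.5, patience 10), soft
#' Dice loss with softmax normalization (background channel excluded by
#' default), and per-epoch checkpoint selection by validation mean Dice.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Samples per optimizer step.
#' @param lr Initial Adam learning rate (> 0).
#' @param plateau_factor,plateau_patience Reduce-on-plateau multiplier and
#'   patience (epochs without validation improvement before reducing).
#' @param include_background Include the background channel in the loss?
#' @param seed Integer seed for shuffling, dropout and weight init.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 2L, lr = 1e-3,
                         plateau_factor = 0.5, plateau_patience = 10L,
                         include_background = FALSE, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, plateau_factor = plateau_factor,
         plateau_patience = as.integer(plateau_patience),
         include_background = include_background, seed = as.integer(seed)),
    class = "train_config"
  )
}

# extract (image, mask) from a phantom_sample or a plain list
as_training_pair <- function(x) {
  if (inherits(x, "phantom_sample")) return(list(image = x$image, mask = x$mask))
  if (is.list(x) && !is.null(x$image) && !is.null(x$mask)) {
    return(list(image = x$image, mask = x$mask))
  }
  stop("training samples must carry $image and $mask")
}

prepare_sample <- function(pair, divisor) {
  x <- pad_to_multiple(pair$image$pixels / 255, divisor)
  m <- pad_to_multiple(pair$mask$labels, divisor)  # background padding
  list(x = array(x$mat, c(nrow(x$mat), ncol(x$mat), 1L)),
       onehot = one_hot_mask(m$mat), pad = x,
       labels = pair$mask$labels)
}

adam_init <- function(net) {
  leaves <- nn_param_leaves(net)
  state <- lapply(leaves, function(p) {
    v <- tree_get(net, p)
    list(m = v * 0, v = v * 0)
  })
  list(leaves = leaves, state = state, t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(opt$leaves)) {
    p <- opt$leaves[[i]]
    g <- tree_get(grads, grad_path(p))
    s <- opt$state[[i]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    opt$state[[i]] <- s
    upd <- lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    net <- tree_set(net, p, tree_get(net, p) - upd)
  }
  list(net = net, opt = opt)
}

# hard mean Dice over the three foreground classes for one case
hard_mean_dice <- function(pred_labels, ref_labels) {
  mean(vapply(tmj_classes(), function(k) {
    p <- pred_labels == k; g <- ref_labels == k
    cc <- list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g))
    dice_coefficient(cc)
  }, numeric(1)))
}

#' Train a residual U-Net
#'
#' Trains with Adam on the soft Dice loss, evaluates the hard validation mean
#' Dice (foreground classes) after every epoch, keeps the best-epoch weights,
#' and reduces the learning rate on a validation plateau. Deterministic for a
#' fixed `config$seed`.
#'
#' @param model A `resunet` from [build_model()].
#' @param train_set,val_set Lists of samples carrying `$image` ([us_image()])
#'   and `$mask` ([label_mask()]); `phantom_sample` objects work directly.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return An object of class `unet_run`: `model` (best-epoch weights),
#'   `final_model`, `log` (data.frame epoch/train_loss/val_dice/lr),
#'   `best_epoch`, `config`.
#' @export
train_model <- function(model, train_set, val_set,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "resunet"), inherits(config, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("train_set and val_set must be non-empty")
  }
  div <- model$size_divisor
  train_prep <- lapply(lapply(train_set, as_training_pair), prepare_sample, div)
  val_pairs <- lapply(val_set, as_training_pair)

  net <- model$net
  opt <- adam_init(net)
  lr <- config$lr
  best_dice <- -Inf
  best_net <- net
  best_epoch <- 0L
  stall <- 0L
  log <- vector("list", config$epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(seq_along(train_prep))
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
      ep_loss <- 0
      for (batch in batches) {
        grads <- NULL
        bloss <- 0
        for (i in batch) {
          smp <- train_prep[[i]]
          fw <- nn_forward(net, smp$x, training = TRUE)
          lg <- dice_loss_grad(fw$y, smp$onehot,
                               include_background = config$include_background)
          bw <- nn_backward(net, lg$dz, fw$cache)
          grads <- grads_add(grads, bw$grads)
          bloss <- bloss + lg$loss
        }
        grads <- grads_scale(grads, 1 / length(batch))
        step <- adam_step(net, grads, opt, lr)
        net <- step$net
        opt <- step$opt
        ep_loss <- ep_loss + bloss
      }
      ep_loss <- ep_loss / length(train_prep)

      model$net <- net
      val_dice <- mean(vapply(val_pairs, function(p) {
        pred <- predict_mask(model, p$image)
        hard_mean_dice(pred$labels, p$mask$labels)
      }, numeric(1)))

      if (val_dice > best_dice + 1e-9) {
        best_dice <- val_dice
        best_net <- net
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > config$plateau_patience) {
          lr <- lr * config$plateau_factor
          stall <- 0L
          if (verbose) message(sprintf("epoch %d: lr reduced to %g", epoch, lr))
        }
      }
      log[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_dice = val_dice, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %g",
                        epoch, ep_loss, val_dice, lr))
      }
    }
  })

  model$net <- best_net
  final_model <- model
  final_model$net <- net
  structure(
    list(model = model, final_model = final_model,
         log = do.call(rbind, log), best_epoch = best_epoch,
         best_val_dice = best_dice, config = config),
    class = "unet_run"
  )
}

#' @export
print.unet_run <- function(x, ...) {
  cat(sprintf(
    "<unet_run> %d epochs; best epoch %d (val mean Dice %.4f); final loss %.4f\n",
    nrow(x$log), x$best_epoch, x$best_val_dice,
    x$log$train_loss[nrow(x$log)]))
  invisible(x)
}

#' Per-pixel class probabilities for an image
#'
#' Intensities are scaled to `[0, 1]`, the frame is zero-padded symmetrically
#' to the model's size divisor, passed through the network in evaluation mode
#' (dropout off), softmax-normalized, and cropped back: probabilities are
#' non-negative and sum to 1 at every pixel.
#'
#' @param model A `resunet` or a `unet_run` (its best model is used).
#' @param image A [us_image()].
#' @return Array `[H, W, 4]` of class probabilities.
#' @export
predict_probs <- function(model, image) {
  if (inherits(model, "unet_run")) model <- model$model
  stopifnot(inherits(model, "resunet"), inherits(image, "us_image"))
  pad <- pad_to_multiple(image$pixels / 255, model$size_divisor)
  x <- array(pad$mat, c(nrow(pad$mat), ncol(pad$mat), 1L))
  logits <- nn_forward(model$net, x, training = FALSE)$y
  crop_from_pad(softmax_probs(logits), pad)
}

probs_to_mask <- function(probs, spacing_mm, id) {
  d <- dim(probs)
  lab <- matrix(max.col(matrix(probs, d[1] * d[2], d[3]),
                        ties.method = "first") - 1L, d[1], d[2])
  label_mask(lab, spacing_mm = spacing_mm, id = id)
}

predict_mask <- function(model, image) {
  probs_to_mask(predict_probs(model, image), image$spacing_mm, image$id)
}

#' Ensemble prediction over several trained runs
#'
#' Averages the runs' softmax probability maps pixelwise, then takes the
#' argmax; a single run degenerates to its plain prediction.
#'
#' @param runs List of `unet_run` (or `resunet`) objects with identical
#'   architecture configurations.
#' @param image A [us_image()].
#' @return A list of class `segmentation_result`: `class_probabilities`
#'   (`[H, W, 4]`, pixelwise mean over runs) and `label_mask` (argmax
#'   [label_mask()]).
#' @export
ensemble_predict <- function(runs, image) {
  if (length(runs) == 0) stop("need at least one trained run")
  models <- lapply(runs, function(r) if (inherits(r, "unet_run")) r$model else r)
  cfg0 <- models[[1]]$config
  for (m in models[-1]) {
    if (!identical(m$config, cfg0)) stop("runs have mismatched configurations")
  }
  probs <- lapply(models, predict_probs, image = image)
  avg <- Reduce(`+`, probs) / length(probs)
  structure(
    list(class_probabilities = avg,
         label_mask = probs_to_mask(avg, image$spacing_mm, image$id)),
    class = "segmentation_result"
  )
}

#' Segment an image and postprocess the mask
#'
#' Full inference path: ensemble softmax averaging, argmax, then
#' connected-component filtering ([filter_components()]).
#'
#' @param runs List of trained runs (or a single run/model).
#' @param image A [us_image()].
#' @param threshold_fraction,connectivity Passed to [filter_components()].
#' @return A postprocessed [label_mask()].
#' @export
predict_case <- function(runs, image, threshold_fraction = 0.6,
                         connectivity = 8) {
  if (!is.list(runs) || inherits(runs, c("unet_run", "resunet"))) {
    runs <- list(runs)
  }
  res <- ensemble_predict(runs, image)
  filter_components(res$label_mask, threshold_fraction = threshold_fraction,
                    connectivity = connectivity)
}
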