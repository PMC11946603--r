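# Independent closed-form parameter counter for the residual U-Net topology
# (counting only; never builds weight arrays).
count_formula <- function(channels, strides, nru, k = 3, inc = 1, outc = 4) {
  conv_p <- function(ci, co, kk) kk * kk * ci * co + co
  resunit_p <- function(ci, co, stride, subunits, last_conv_only = FALSE) {
    subunits <- max(1, subunits)
    total <- conv_p(ci, co, k) + (subunits - 1) * conv_p(co, co, k)
    total <- total + subunits - as.integer(last_conv_only)  # PReLU slopes
    if (stride != 1) total <- total + conv_p(ci, co, k)
    else if (ci != co) total <- total + conv_p(ci, co, 1)
    total
  }
  up_p <- function(ci, co, is_top) {
    conv_p(ci, co, k) + 1 + resunit_p(co, co, 1, 1, last_conv_only = is_top)
  }
  block <- function(bin, bout, ch, st, is_top) {
    c1 <- ch[1]
    if (length(ch) > 2) {
      sub <- block(c1, c1, ch[-1], st[-1], FALSE)
      upc <- 2 * c1
    } else {
      sub <- resunit_p(c1, ch[2], 1, nru)
      upc <- c1 + ch[2]
    }
    resunit_p(bin, c1, st[1], nru) + sub + up_p(upc, bout, is_top)
  }
  block(inc, outc, channels, strides, TRUE)
}

test_that("architecture configuration is validated", {
  expect_error(unet_config(in_channels = 4), "fixed to 1")
  expect_error(unet_config(out_channels = 2), "fixed to 4")
  expect_error(unet_config(channels = c(16, 8)), "increasing")
  expect_error(unet_config(channels = 16L), "length >= 2")
  expect_error(unet_config(channels = c(4, 8), strides = c(2, 2)),
               "length")
  expect_error(unet_config(kernel_size = 4), "odd")
  expect_error(unet_config(dropout = 1), "dropout")
  cfg <- unet_config(channels = c(4L, 8L), strides = 2L, num_res_units = 1L)
  expect_s3_class(cfg, "unet_config")
})

test_that("parameter counts match a hand count and the closed form", {
  # channels (2,3), stride 2, 1 res unit, 4 output channels; hand count:
  #  down 1->2 s2: conv 20 + PReLU 1 + strided residual 20          = 41
  #  bottleneck 2->3 s1: conv 57 + PReLU 1 + 1x1 residual 9         = 67
  #  up (2+3)->4: tconv 184 + PReLU 1 + final conv 148 (id skip)    = 333
  tiny <- build_model(unet_config(channels = c(2L, 3L), strides = 2L,
                                  num_res_units = 1L, dropout = 0), seed = 1)
  expect_identical(tiny$n_parameters, 441)
  expect_identical(count_formula(c(2, 3), 2, 1), 441)

  for (case in list(
    list(ch = c(4, 8), st = 2, nru = 2),
    list(ch = c(8, 16, 32), st = c(2, 2), nru = 3),
    list(ch = c(16, 32, 64, 128), st = c(2, 2, 2), nru = 16)
  )) {
    mdl <- build_model(unet_config(channels = case$ch, strides = case$st,
                                   num_res_units = case$nru), seed = 2)
    expect_identical(mdl$n_parameters,
                     count_formula(case$ch, case$st, case$nru),
                     label = paste(case$ch, collapse = "-"))
  }
  # weight shapes define the divisibility constraint
  expect_identical(build_model(unet_config(), seed = 1)$size_divisor, 8L)
})

test_that("soft Dice loss matches hand arithmetic and stays in [0, 1]", {
  # perfect prediction: every included class ratio is exactly 1
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  oh <- tmjjsw:::one_hot_mask(lab)
  expect_equal(soft_dice_loss(oh, oh), 0, tolerance = 1e-12)
  expect_equal(soft_dice_loss(oh, oh, include_background = TRUE), 0,
               tolerance = 1e-12)

  # uniform 1/4 probabilities vs a 2x2 one-hot grid, by hand:
  # each class has one reference pixel; per class
  # (2*0.25 + eps) / (1 + 1 + eps) with eps = 1e-5
  unif <- array(0.25, c(2, 2, 4))
  eps <- 1e-5
  by_hand <- 1 - (2 * 0.25 + eps) / (2 + eps)
  expect_equal(soft_dice_loss(unif, oh), by_hand, tolerance = 1e-12)

  withr::with_seed(3, {
    for (i in 1:20) {
      z <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
      p <- tmjjsw:::softmax_probs(z)
      g <- tmjjsw:::one_hot_mask(matrix(sample(0:3, 16, TRUE), 4, 4))
      l <- soft_dice_loss(p, g)
      expect_true(l >= 0 && l <= 1)
    }
  })
  expect_error(soft_dice_loss(unif, array(0, c(2, 2, 3))), "shape")
})

test_that("backpropagation matches central finite differences", {
  cfg <- unet_config(channels = c(2L, 3L), strides = 2L,
                     num_res_units = 1L, dropout = 0)
  net <- build_model(cfg, seed = 5)$net
  withr::with_seed(9, {
    x <- array(runif(8 * 8), c(8, 8, 1))
    lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  })
  oh <- tmjjsw:::one_hot_mask(lab)
  loss_of <- function(n) {
    fw <- tmjjsw:::nn_forward(n, x, training = FALSE)
    tmjjsw:::dice_loss_grad(fw$y, oh)$loss
  }
  fw <- tmjjsw:::nn_forward(net, x, training = FALSE)
  lg <- tmjjsw:::dice_loss_grad(fw$y, oh)
  bw <- tmjjsw:::nn_backward(net, lg$dz, fw$cache)
  leaves <- tmjjsw:::nn_param_leaves(net)
  withr::with_seed(11, {
    for (rep in 1:30) {
      p <- leaves[[sample(length(leaves), 1)]]
      v <- tmjjsw:::tree_get(net, p)
      j <- sample(length(v), 1)
      h <- 1e-5
      v2 <- v; v2[j] <- v[j] + h
      lp <- loss_of(tmjjsw:::tree_set(net, p, v2))
      v2[j] <- v[j] - h
      lm <- loss_of(tmjjsw:::tree_set(net, p, v2))
      g_fd <- (lp - lm) / (2 * h)
      g_bp <- tmjjsw:::tree_get(bw$grads, tmjjsw:::grad_path(p))[j]
      expect_lt(abs(g_fd - g_bp) / max(1e-8, abs(g_fd) + abs(g_bp)), 1e-5)
    }
  })
})

test_that("probabilities normalize per pixel and survive ensembling", {
  cfg <- unet_config(channels = c(4L, 8L), strides = 2L, num_res_units = 1L,
                     dropout = 0.2)
  mdl <- build_model(cfg, seed = 21)
  img <- generate_phantom(phantom_spec(image_size = c(32, 32), jsw_px = 8,
                                       band_thickness_px = 3,
                                       condyle_curvature = 0.06,
                                       fossa_curvature = 0.03,
                                       seed = 1))$image
  probs <- predict_probs(mdl, img)
  expect_identical(dim(probs), c(32L, 32L, 4L))
  expect_true(all(probs >= 0))
  sums <- apply(probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))

  # odd-sized frames are padded internally and cropped back
  odd <- us_image(img$pixels[1:31, 1:29], spacing_mm = img$spacing_mm)
  expect_identical(dim(predict_probs(mdl, odd)), c(31L, 29L, 4L))

  # three copies of the same run: identical to the single prediction
  res3 <- ensemble_predict(list(mdl, mdl, mdl), img)
  expect_equal(res3$class_probabilities, probs, tolerance = 1e-12)
  expect_identical(res3$label_mask$labels,
                   ensemble_predict(list(mdl), img)$label_mask$labels)
  sums3 <- apply(res3$class_probabilities, c(1, 2), sum)
  expect_true(all(abs(sums3 - 1) < 1e-5))

  # the mean rule decides pixels where runs disagree
  other <- build_model(cfg, seed = 99)
  res_mix <- ensemble_predict(list(mdl, other), img)
  expect_equal(res_mix$class_probabilities,
               (probs + predict_probs(other, img)) / 2, tolerance = 1e-12)

  expect_error(ensemble_predict(list(), img), "at least one")
  mismatched <- build_model(unet_config(channels = c(4L, 8L, 16L),
                                        strides = c(2L, 2L),
                                        num_res_units = 1L), seed = 1)
  expect_error(ensemble_predict(list(mdl, mismatched), img), "mismatch")
})

test_that("training runs deterministically and logs one row per epoch", {
  co <- generate_cohort(6, jsw_range_mm = c(0.3, 0.7),
                        image_size = c(32, 32), seed = 50)
  cfg <- unet_config(channels = c(4L, 8L), strides = 2L, num_res_units = 1L,
                     dropout = 0.1)
  tc <- train_config(epochs = 1, seed = 7)
  run1 <- train_model(build_model(cfg, seed = 7), co[1:4], co[5:6], tc)
  expect_identical(nrow(run1$log), 1L)
  expect_true(all(c("epoch", "train_loss", "val_dice", "lr") %in%
                  names(run1$log)))
  run2 <- train_model(build_model(cfg, seed = 7), co[1:4], co[5:6], tc)
  expect_identical(run1$log$train_loss, run2$log$train_loss)
  expect_identical(run1$log$val_dice, run2$log$val_dice)

  expect_error(train_model(build_model(cfg, seed = 1), list(), co[5:6], tc),
               "non-empty")
})
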