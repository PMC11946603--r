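# Minimal dense 2D conv-net primitives used by the residual U-Net harness.
#
# Feature maps are numeric arrays [H, W, C] (one sample; batching is handled
# by gradient averaging in the training loop). Convolutions are computed by
# im2col gather + BLAS matrix multiply; the col2im scatter-add needed for
# gradients (and for transposed convolutions, which are the exact adjoint of
# a strided convolution) is a precomputed sparse matrix. Gather indices and
# scatter matrices depend only on (H, W, Cin, k, stride) and are cached.

.conv_cache <- new.env(parent = emptyenv())

conv_geometry <- function(H, W, Cin, k, stride) {
  key <- paste(H, W, Cin, k, stride, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (H + 2L * p - k) %/% stride + 1L
  Wout <- (W + 2L * p - k) %/% stride + 1L
  # base offset (0-based) of each output position's receptive-field origin
  pos_r <- rep((0:(Hout - 1L)) * stride, times = Wout)
  pos_c <- rep((0:(Wout - 1L)) * stride, each = Hout)
  base <- pos_c * Hp + pos_r
  # per-column offsets enumerating (ki fastest, then kj, then channel)
  ki <- rep(1:k, times = k * Cin)
  kj <- rep(rep(1:k, each = k), times = Cin)
  ch <- rep(1:Cin, each = k * k)
  off <- (ch - 1L) * Hp * Wp + (kj - 1L) * Hp + ki
  idx <- as.vector(outer(base, off, "+"))
  scatter <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                                  dims = c(Hp * Wp * Cin, length(idx)))
  geo <- list(p = p, Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout,
              npos = Hout * Wout, k2c = k * k * Cin,
              idx = idx, scatter = scatter)
  .conv_cache[[key]] <- geo
  geo
}

pad_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

crop_array <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

im2col <- function(x, geo) {
  xp <- pad_array(x, geo$p)
  matrix(xp[geo$idx], geo$npos, geo$k2c)
}

col2im <- function(dXcol, geo, H, W, Cin) {
  v <- as.vector(geo$scatter %*% as.vector(dXcol))
  crop_array(array(v, c(geo$Hp, geo$Wp, Cin)), geo$p, H, W)
}

# ---- layer constructors ----------------------------------------------------

uniform_init <- function(nrow, ncol, fan_in) {
  b <- sqrt(1 / fan_in)
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, transposed = FALSE) {
  fan_in <- k * k * in_ch
  if (transposed) {
    # weight parameterized as the adjoint convolution's matrix [k^2*out, in]
    W <- uniform_init(k * k * out_ch, in_ch, fan_in)
  } else {
    W <- uniform_init(k * k * in_ch, out_ch, fan_in)
  }
  b <- stats::runif(out_ch, -sqrt(1 / fan_in), sqrt(1 / fan_in))
  list(kind = "conv", k = as.integer(k), stride = as.integer(stride),
       transposed = isTRUE(transposed), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), params = list(W = W, b = b))
}

nn_instnorm <- function(eps = 1e-5) list(kind = "instnorm", eps = eps)
nn_prelu <- function(init = 0.25) list(kind = "prelu",
                                       params = list(a = init))
nn_dropout <- function(p) list(kind = "dropout", p = p)
nn_seq <- function(...) list(kind = "seq", layers = list(...))
nn_seq_list <- function(layers) list(kind = "seq", layers = layers)
nn_resunit <- function(main, residual = NULL) {
  list(kind = "resunit", main = main, residual = residual)
}
nn_skipcat <- function(sub) list(kind = "skipcat", sub = sub)

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$kind,
    conv = if (mod$transposed) convT_fwd(mod, x) else conv_fwd(mod, x),
    instnorm = instnorm_fwd(mod, x),
    prelu = {
      a <- mod$params$a
      y <- ifelse(x > 0, x, a * x)
      list(y = array(y, dim(x)), cache = x)
    },
    dropout = {
      if (training && mod$p > 0) {
        mask <- array(stats::rbinom(length(x), 1L, 1 - mod$p) / (1 - mod$p),
                      dim(x))
        list(y = x * mask, cache = mask)
      } else {
        list(y = x, cache = NULL)
      }
    },
    seq = {
      caches <- vector("list", length(mod$layers))
      for (i in seq_along(mod$layers)) {
        step <- nn_forward(mod$layers[[i]], x, training)
        x <- step$y
        caches[i] <- list(step$cache)  # keep NULL slots for cacheless layers
      }
      list(y = x, cache = caches)
    },
    resunit = {
      m <- nn_forward(mod$main, x, training)
      if (is.null(mod$residual)) {
        list(y = m$y + x, cache = list(main = m$cache, residual = NULL))
      } else {
        r <- nn_forward(mod$residual, x, training)
        list(y = m$y + r$y, cache = list(main = m$cache, residual = r$cache))
      }
    },
    skipcat = {
      s <- nn_forward(mod$sub, x, training)
      d <- dim(x); ds <- dim(s$y)
      y <- array(0, c(d[1], d[2], d[3] + ds[3]))
      y[, , seq_len(d[3])] <- x
      y[, , d[3] + seq_len(ds[3])] <- s$y
      list(y = y, cache = list(sub = s$cache, c1 = d[3]))
    },
    stop("unknown module kind: ", mod$kind)
  )
}

# Returns list(dx = ..., grads = ...) with grads mirroring the module tree.
nn_backward <- function(mod, dy, cache) {
  switch(mod$kind,
    conv = if (mod$transposed) convT_bwd(mod, dy, cache)
           else conv_bwd(mod, dy, cache),
    instnorm = instnorm_bwd(mod, dy, cache),
    prelu = {
      x <- cache
      a <- mod$params$a
      dx <- dy * ifelse(x > 0, 1, a)
      da <- sum(dy * x * (x <= 0))
      list(dx = array(dx, dim(x)), grads = list(a = da))
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    },
    seq = {
      grads <- vector("list", length(mod$layers))
      for (i in rev(seq_along(mod$layers))) {
        step <- nn_backward(mod$layers[[i]], dy, cache[[i]])
        dy <- step$dx
        grads[i] <- list(step$grads)  # keep NULL slots for param-free layers
      }
      list(dx = dy, grads = grads)
    },
    resunit = {
      m <- nn_backward(mod$main, dy, cache$main)
      if (is.null(mod$residual)) {
        list(dx = m$dx + dy, grads = list(main = m$grads, residual = NULL))
      } else {
        r <- nn_backward(mod$residual, dy, cache$residual)
        list(dx = m$dx + r$dx,
             grads = list(main = m$grads, residual = r$grads))
      }
    },
    skipcat = {
      c1 <- cache$c1
      d <- dim(dy)
      dy1 <- dy[, , seq_len(c1), drop = FALSE]
      dy2 <- dy[, , (c1 + 1L):d[3], drop = FALSE]
      s <- nn_backward(mod$sub, dy2, cache$sub)
      list(dx = dy1 + s$dx, grads = list(sub = s$grads))
    },
    stop("unknown module kind: ", mod$kind)
  )
}

conv_fwd <- function(mod, x) {
  d <- dim(x)
  geo <- conv_geometry(d[1], d[2], mod$in_ch, mod$k, mod$stride)
  Xcol <- im2col(x, geo)
  y <- Xcol %*% mod$params$W
  y <- y + rep(mod$params$b, each = geo$npos)
  list(y = array(y, c(geo$Hout, geo$Wout, mod$out_ch)),
       cache = list(Xcol = Xcol, H = d[1], W = d[2]))
}

conv_bwd <- function(mod, dy, cache) {
  geo <- conv_geometry(cache$H, cache$W, mod$in_ch, mod$k, mod$stride)
  dYm <- matrix(dy, geo$npos, mod$out_ch)
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(mod$params$W)
  dx <- col2im(dXcol, geo, cache$H, cache$W, mod$in_ch)
  list(dx = dx, grads = list(W = dW, b = db))
}

# Transposed conv doubling spatial size: exact adjoint of a stride-s conv
# mapping [s*H, s*W, out_ch] -> [H, W, in_ch].
convT_fwd <- function(mod, x) {
  d <- dim(x)
  s <- mod$stride
  Hb <- d[1] * s; Wb <- d[2] * s
  geo <- conv_geometry(Hb, Wb, mod$out_ch, mod$k, s)
  stopifnot(geo$Hout == d[1], geo$Wout == d[2])
  xm <- matrix(x, geo$npos, mod$in_ch)
  dXcol <- xm %*% t(mod$params$W)       # [npos, k^2*out_ch]
  y <- col2im(dXcol, geo, Hb, Wb, mod$out_ch)
  y <- y + rep(mod$params$b, each = Hb * Wb)
  list(y = y, cache = list(xm = xm, H = d[1], W = d[2]))
}

convT_bwd <- function(mod, dy, cache) {
  s <- mod$stride
  Hb <- cache$H * s; Wb <- cache$W * s
  geo <- conv_geometry(Hb, Wb, mod$out_ch, mod$k, s)
  dYcol <- im2col(dy, geo)              # [npos, k^2*out_ch]
  dx <- array(dYcol %*% mod$params$W, c(cache$H, cache$W, mod$in_ch))
  dW <- crossprod(dYcol, cache$xm)      # [k^2*out_ch, in_ch]
  db <- as.vector(colSums(matrix(dy, Hb * Wb, mod$out_ch)))
  list(dx = dx, grads = list(W = dW, b = db))
}

instnorm_fwd <- function(mod, x) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)                # biased variance, as in torch
  invstd <- 1 / sqrt(v + mod$eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  list(y = array(xhat, d), cache = list(xhat = xhat, invstd = invstd, d = d))
}

instnorm_bwd <- function(mod, dy, cache) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  xhat <- cache$xhat
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * xhat)
  dx <- sweep(sweep(dym, 2, m1) - sweep(xhat, 2, m2, `*`),
              2, cache$invstd, `*`)
  list(dx = array(dx, d), grads = NULL)
}

# ---- parameter-tree utilities ----------------------------------------------

nn_param_leaves <- function(mod) {
  out <- list()
  walk <- function(m, path) {
    if (!is.null(m$params)) {
      for (nm in names(m$params)) {
        out[[length(out) + 1L]] <<- c(path, list("params", nm))
      }
    }
    for (child in c("main", "residual", "sub")) {
      if (!is.null(m[[child]])) walk(m[[child]], c(path, list(child)))
    }
    if (!is.null(m$layers)) {
      for (i in seq_along(m$layers)) {
        walk(m$layers[[i]], c(path, list("layers", i)))
      }
    }
  }
  walk(mod, list())
  out
}

tree_get <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

tree_set <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- tree_set(x[[path[[1]]]], path[-1], value)
  x
}

# grads mirror the module tree but without the "params" level at leaves and
# with seq children as a plain list (no "layers" wrapper); nn_backward
# produces: conv -> list(W=..., b=...), prelu -> list(a=...), seq -> list of
# children, resunit -> list(main=, residual=), skipcat -> list(sub=).
grad_path <- function(param_path) {
  keep <- !vapply(param_path, function(p) {
    is.character(p) && p %in% c("params", "layers")
  }, logical(1))
  param_path[keep]
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(grads_add(a[[i]], b[[i]]))
    return(a)
  }
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) {
    for (i in seq_along(g)) g[i] <- list(grads_scale(g[[i]], s))
    return(g)
  }
  g * s
}
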