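# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own implementation paths.

# queue-based BFS connected-component labelling
bfs_label <- function(binary, connectivity = 8) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8) {
    nb <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (binary[i, j] != 0 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- nxt
      while (nrow(queue) > 0) {
        cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (q in seq_len(nrow(nb))) {
          r2 <- cur[1] + nb[q, 1]; c2 <- cur[2] + nb[q, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              binary[r2, c2] != 0 && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            queue <- rbind(queue, c(r2, c2))
          }
        }
      }
    }
  }
  lab
}

# all-pairs directed Hausdorff between full boundary point sets, point loops
brute_hausdorff_mm <- function(pred, ref, class_code) {
  bnd <- function(labels, code) {
    fg <- labels == code
    pts <- which(fg, arr.ind = TRUE)
    keep <- logical(nrow(pts))
    nr <- nrow(labels); nc <- ncol(labels)
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]
      nbv <- c(
        if (r > 1) fg[r - 1, c] else FALSE,
        if (r < nr) fg[r + 1, c] else FALSE,
        if (c > 1) fg[r, c - 1] else FALSE,
        if (c < nc) fg[r, c + 1] else FALSE
      )
      keep[i] <- length(nbv) < 4 || !all(nbv)
    }
    pts[keep, , drop = FALSE]
  }
  a <- bnd(pred$labels, class_code)
  b <- bnd(ref$labels, class_code)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  sp <- pred$spacing_mm
  directed <- function(from, to) {
    worst <- 0
    for (i in seq_len(nrow(from))) {
      best <- Inf
      for (j in seq_len(nrow(to))) {
        d <- sqrt(((from[i, 1] - to[j, 1]) * sp[1])^2 +
                  ((from[i, 2] - to[j, 2]) * sp[2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(a, b), directed(b, a))
}

# pixelwise-count oracle for the ratio metrics
brute_ratios <- function(pred, ref, class_code) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(pred$labels))) for (j in seq_len(ncol(pred$labels))) {
    p <- pred$labels[i, j] == class_code
    g <- ref$labels[i, j] == class_code
    if (p && g) tp <- tp + 1L
    if (p && !g) fp <- fp + 1L
    if (!p && g) fn <- fn + 1L
  }
  list(
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    precision = if (tp + fp == 0) {
      if (fn == 0) 1 else NA_real_
    } else tp / (tp + fp),
    recall = if (tp + fn == 0) {
      if (fp == 0) 1 else NA_real_
    } else tp / (tp + fn),
    vs = if (2 * tp + fp + fn == 0) {
      1
    } else 1 - abs(fp - fn) / (2 * tp + fp + fn)
  )
}

random_mask <- function(nr = 16, nc = 16, p_fg = 0.4,
                        spacing_mm = c(1, 1), id = "rand") {
  lab <- matrix(sample(0:3, nr * nc, replace = TRUE,
                       prob = c(1 - p_fg, rep(p_fg / 3, 3))), nr, nc)
  label_mask(lab, spacing_mm = spacing_mm, id = id)
}

# small mask with the given class at explicit (row, col) positions
mask_with <- function(nr, nc, ..., spacing_mm = c(1, 1)) {
  lab <- matrix(0L, nr, nc)
  pts <- list(...)
  for (cls_name in names(pts)) {
    code <- tmj_classes()[[cls_name]]
    lab[pts[[cls_name]]] <- code
  }
  label_mask(lab, spacing_mm = spacing_mm, id = "fixture")
}

shift_mask <- function(mask, dr, dc) {
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  out <- matrix(0L, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- lab[src_r[ok_r], src_c[ok_c]]
  label_mask(out, spacing_mm = mask$spacing_mm, id = mask$id)
}

small_cohort <- function(n, seed = 1, image_size = c(64, 64),
                         jsw_range_mm = c(0.8, 2.0)) {
  generate_cohort(n, jsw_range_mm = jsw_range_mm, image_size = image_size,
                  seed = seed)
}
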