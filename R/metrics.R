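#' One-vs-rest confusion counts for a class
#'
#' @param pred,ref [label_mask()] objects of identical shape.
#' @param class_code Class code in 1..3 (see [tmj_classes()]).
#' @return List `(tp, fp, fn)` of pixel counts.
#' @export
confusion_counts <- function(pred, ref, class_code) {
  stopifnot(inherits(pred, "label_mask"), inherits(ref, "label_mask"))
  stop_if_shape_mismatch(pred$labels, ref$labels)
  p <- pred$labels == class_code
  g <- ref$labels == class_code
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g))
}

#' Dice similarity coefficient from confusion counts
#'
#' `2*TP / (2*TP + FP + FN)`. When both masks are empty for the class the
#' agreement is vacuously perfect and 1 is returned; when exactly one is
#' empty the overlap is 0 and Dice is 0 (the convention under which a fully
#' missed structure scores 0.00).
#'
#' @param counts List `(tp, fp, fn)` from [confusion_counts()].
#' @return Dice in `[0, 1]`.
#' @export
dice_coefficient <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' Precision and recall from confusion counts
#'
#' `precision = TP/(TP+FP)` over predicted positives; `recall = TP/(TP+FN)`
#' over reference positives. An empty denominator yields `NA` (undefined,
#' excluded from summaries) unless both masks are empty for the class, in
#' which case agreement is vacuously perfect and 1 is returned.
#'
#' @param counts List `(tp, fp, fn)` from [confusion_counts()].
#' @return A ratio in `[0, 1]` or `NA`.
#' @export
precision_metric <- function(counts) {
  if (counts$tp + counts$fp == 0) {
    return(if (counts$fn == 0) 1 else NA_real_)
  }
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname precision_metric
#' @export
recall_metric <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    return(if (counts$fp == 0) 1 else NA_real_)
  }
  counts$tp / (counts$tp + counts$fn)
}

#' Volume similarity
#'
#' `VS = 1 - |V_P - V_G| / (V_P + V_G)`, i.e. `2*min(V_P, V_G)/(V_P + V_G)`:
#' size agreement irrespective of overlap location. Both volumes zero is a
#' perfect (vacuous) match and returns 1. For 2D masks the "volumes" are
#' pixel counts (areas).
#'
#' @param pred_count,ref_count Non-negative pixel counts.
#' @return VS in `[0, 1]`.
#' @export
volume_similarity <- function(pred_count, ref_count) {
  if (pred_count + ref_count == 0) return(1)
  1 - abs(pred_count - ref_count) / (pred_count + ref_count)
}

#' Boundary pixels of a class region
#'
#' A boundary pixel is a foreground pixel with at least one 4-neighbour that
#' is not foreground; pixels on the image border count as boundary on that
#' side.
#'
#' @param labels Integer label matrix.
#' @param class_code Class code.
#' @return Two-column matrix of (row, col) indices (possibly 0 rows).
#' @export
boundary_points <- function(labels, class_code) {
  fg <- labels == class_code
  nr <- nrow(fg); nc <- ncol(fg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  interior <- core &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(core & !interior, arr.ind = TRUE)
}

#' Symmetric Hausdorff distance between two class regions, in mm
#'
#' The Hausdorff distance is the larger of the two directed maximum
#' nearest-neighbour distances between the boundary point sets of the class
#' in the predicted and reference masks, using Euclidean distance with
#' per-axis physical spacing. The directed maxima of region-to-region
#' distances are attained on boundaries, so boundary pixels are used as the
#' point sets.
#'
#' @param pred,ref [label_mask()] objects with identical shape and spacing.
#' @param class_code Class code.
#' @return Distance in mm; 0 if the class is empty in both masks; `NA` if it
#'   is empty in exactly one (undefined, excluded from summaries).
#' @export
hausdorff_mm <- function(pred, ref, class_code) {
  stopifnot(inherits(pred, "label_mask"), inherits(ref, "label_mask"))
  stop_if_shape_mismatch(pred$labels, ref$labels)
  if (any(abs(pred$spacing_mm - ref$spacing_mm) > 1e-12)) {
    stop("spacing mismatch between masks")
  }
  a <- boundary_points(pred$labels, class_code)
  b <- boundary_points(ref$labels, class_code)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  sp <- pred$spacing_mm
  dr <- outer(a[, 1] * sp[1], b[, 1] * sp[1], "-")
  dc <- outer(a[, 2] * sp[2], b[, 2] * sp[2], "-")
  d2 <- dr * dr + dc * dc
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' Evaluate one predicted mask against its reference
#'
#' Computes Dice, precision, recall, volume similarity and Hausdorff distance
#' for each of the three anatomical classes (MC, JS, GF).
#'
#' @param pred,ref Paired [label_mask()] objects.
#' @param id Case id; defaults to the reference mask's id.
#' @return A data.frame with one row per class and columns `id, class, dice,
#'   precision, recall, vs, hd_mm`.
#' @export
evaluate_case <- function(pred, ref, id = ref$id) {
  classes <- tmj_classes()
  rows <- lapply(names(classes), function(nm) {
    cc <- confusion_counts(pred, ref, classes[[nm]])
    data.frame(
      id = id,
      class = nm,
      dice = dice_coefficient(cc),
      precision = precision_metric(cc),
      recall = recall_metric(cc),
      vs = volume_similarity(cc$tp + cc$fp, cc$tp + cc$fn),
      hd_mm = hausdorff_mm(pred, ref, classes[[nm]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Aggregate per-case metric reports over a test set
#'
#' Mean and sample standard deviation (n-1 denominator) of every metric for
#' every class, with undefined (`NA`) per-case values excluded and their
#' exclusion count reported.
#'
#' @param reports A data.frame of stacked [evaluate_case()] outputs.
#' @return A data.frame with columns `class, metric, mean, sd, n,
#'   n_excluded`.
#' @export
summarize_metrics <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0) stop("empty report list")
  metrics <- c("dice", "precision", "recall", "vs", "hd_mm")
  out <- list()
  for (cls in unique(reports$class)) {
    sub <- reports[reports$class == cls, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        class = cls, metric = m,
        mean = if (any(ok)) mean(v[ok]) else NA_real_,
        sd = if (sum(ok) > 1) stats::sd(v[ok]) else NA_real_,
        n = sum(ok), n_excluded = sum(!ok),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Overall mean Dice across classes
#'
#' A single-number model summary: the unweighted mean over the three classes
#' of the per-class test-set mean Dice (mean of per-class means, in that
#' order).
#'
#' @param reports Stacked [evaluate_case()] outputs.
#' @return A single number in `[0, 1]`.
#' @export
overall_dice <- function(reports) {
  s <- summarize_metrics(reports)
  mean(s$mean[s$metric == "dice"])
}
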