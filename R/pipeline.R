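#' Full evaluation pipeline: metrics, JSW measurement and agreement
#'
#' Runs the complete evaluation protocol on paired predicted/reference masks:
#' connected-component postprocessing of the predictions, per-case per-class
#' segmentation metrics, JSW measurement on both the postprocessed
#' predictions and the reference masks (the same landmark algorithm on both
#' sides, so differences isolate segmentation error rather than
#' measurement-rule differences), and paired agreement statistics over all
#' cases where both sides yield an `ok` measurement. Cases excluded from the
#' agreement analysis are listed with the failing side's status.
#'
#' @param pred_masks,ref_masks Named lists of [label_mask()] objects (names
#'   are case ids) or lists whose masks carry ids; every reference id must
#'   have a prediction.
#' @param threshold_fraction,connectivity Passed to [filter_components()].
#' @param postprocess Apply [filter_components()] to predictions first?
#' @param allow_inferior_fossa Passed to [measure_jsw()].
#' @return A list of class `full_eval` with elements `metrics` (per-case
#'   per-class data.frame), `metrics_summary`, `jsw_pred`, `jsw_ref`
#'   (measurement data.frames), `pairs` (paired mm values used for
#'   agreement), `excluded` (data.frame of case id and reason), and
#'   `agreement` (an `agreement_report`, or `NULL` if fewer than two pairs
#'   remain).
#' @export
full_eval <- function(pred_masks, ref_masks, threshold_fraction = 0.6,
                      connectivity = 8, postprocess = TRUE,
                      allow_inferior_fossa = FALSE) {
  pred_ids <- mask_ids(pred_masks)
  ref_ids <- mask_ids(ref_masks)
  missing_ids <- setdiff(ref_ids, pred_ids)
  if (length(missing_ids) > 0) {
    stop("missing prediction for id(s): ", paste(missing_ids, collapse = ", "))
  }
  pred_masks <- stats::setNames(pred_masks, pred_ids)[ref_ids]
  ref_masks <- stats::setNames(ref_masks, ref_ids)

  if (isTRUE(postprocess)) {
    pred_masks <- lapply(pred_masks, filter_components,
                         threshold_fraction = threshold_fraction,
                         connectivity = connectivity)
  }

  metrics <- do.call(rbind, lapply(ref_ids, function(id) {
    evaluate_case(pred_masks[[id]], ref_masks[[id]], id = id)
  }))

  jsw_pred <- measure_jsw_batch(pred_masks,
                                allow_inferior_fossa = allow_inferior_fossa)
  jsw_ref <- measure_jsw_batch(ref_masks,
                               allow_inferior_fossa = allow_inferior_fossa)
  jsw_pred$id <- ref_ids
  jsw_ref$id <- ref_ids

  ok <- jsw_pred$status == "ok" & jsw_ref$status == "ok"
  excluded <- data.frame(
    id = ref_ids[!ok],
    pred_status = jsw_pred$status[!ok],
    ref_status = jsw_ref$status[!ok],
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    id = ref_ids[ok],
    ai_mm = jsw_pred$jsw_mm[ok],
    ref_mm = jsw_ref$jsw_mm[ok],
    stringsAsFactors = FALSE
  )
  agreement <- if (nrow(pairs) >= 2) agreement_stats(pairs) else NULL

  structure(
    list(metrics = metrics, metrics_summary = summarize_metrics(metrics),
         jsw_pred = jsw_pred, jsw_ref = jsw_ref, pairs = pairs,
         excluded = excluded, agreement = agreement),
    class = "full_eval"
  )
}

mask_ids <- function(masks) {
  if (!is.null(names(masks)) && all(nzchar(names(masks)))) return(names(masks))
  ids <- vapply(masks, function(m) m$id, character(1))
  if (anyDuplicated(ids) || any(is.na(ids))) {
    stop("masks must carry unique ids (names or $id)")
  }
  ids
}

#' @export
print.full_eval <- function(x, ...) {
  cat(sprintf("<full_eval> %d cases; %d excluded from agreement\n",
              length(unique(x$metrics$id)), nrow(x$excluded)))
  s <- x$metrics_summary
  d <- s[s$metric == "dice", ]
  cat(sprintf("  mean Dice  MC %.3f  JS %.3f  GF %.3f\n",
              d$mean[d$class == "MC"], d$mean[d$class == "JS"],
              d$mean[d$class == "GF"]))
  if (!is.null(x$agreement)) {
    cat(sprintf("  JSW bias %.3f mm, LoA [%.3f, %.3f] mm (n = %d)\n",
                x$agreement$bias, x$agreement$loa_low, x$agreement$loa_high,
                x$agreement$n))
  }
  invisible(x)
}

#' Load masks listed in a manifest
#'
#' @param manifest A data.frame from [read_manifest()].
#' @param column `"mask"` (default) or `"image"`-style column holding mask
#'   paths.
#' @param class_map Passed to [read_label_mask()].
#' @return Named list of [label_mask()] objects keyed by case id.
#' @export
load_masks <- function(manifest, column = "mask",
                       class_map = identity_class_map()) {
  masks <- lapply(seq_len(nrow(manifest)), function(i) {
    read_label_mask(manifest[[column]][i], class_map = class_map,
                    spacing_mm = c(manifest$row_spacing_mm[i],
                                   manifest$col_spacing_mm[i]),
                    id = manifest$id[i])
  })
  stats::setNames(masks, manifest$id)
}
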