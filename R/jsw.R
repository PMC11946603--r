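#' Locate the superior-most point of the mandibular condyle
#'
#' The condyle apex is the MC pixel with the highest vertical position, i.e.
#' the smallest row index under the screen convention (row 1 = top of frame =
#' anatomically superior). If several MC pixels share that row, the median
#' pixel along the horizontal axis is taken; for an even number of tied
#' columns the lower of the two middle columns is used.
#'
#' @param mask A [label_mask()].
#' @return A list `(row, col)` of class `pixel_point`, or `NULL` if the mask
#'   contains no MC pixels.
#' @export
find_condyle_apex <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  idx <- which(mask$labels == tmj_classes()[["MC"]], arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  rmin <- min(idx[, 1])
  cols <- sort(idx[idx[, 1] == rmin, 2])
  k <- length(cols)
  pixel_point(rmin, cols[(k + 1L) %/% 2L])  # lower middle when k is even
}

pixel_point <- function(row, col) {
  structure(list(row = as.integer(row), col = as.integer(col)),
            class = "pixel_point")
}

#' @export
print.pixel_point <- function(x, ...) {
  cat(sprintf("<pixel_point> row %d, col %d\n", x$row, x$col))
  invisible(x)
}

#' Find the glenoid fossa point vertically aligned with the condyle apex
#'
#' Searches the apex column for the closest GF pixel superior to (strictly
#' above) the apex, i.e. the GF pixel with the largest row index smaller than
#' the apex row.
#'
#' @param mask A [label_mask()].
#' @param apex A `pixel_point` from [find_condyle_apex()].
#' @param allow_inferior_fossa If `TRUE`, fall back to the nearest GF pixel
#'   in the column regardless of side when none lies above the apex (useful
#'   for pathological predicted masks). Default `FALSE`.
#' @return A `pixel_point`, or a character status: `"no_fossa_in_column"` if
#'   the apex column holds no GF pixel, `"fossa_not_superior"` if GF pixels
#'   exist in the column but only below the apex (and `allow_inferior_fossa`
#'   is `FALSE`).
#' @export
find_fossa_match <- function(mask, apex, allow_inferior_fossa = FALSE) {
  stopifnot(inherits(mask, "label_mask"), inherits(apex, "pixel_point"))
  gf_rows <- which(mask$labels[, apex$col] == tmj_classes()[["GF"]])
  if (length(gf_rows) == 0) return("no_fossa_in_column")
  above <- gf_rows[gf_rows < apex$row]
  if (length(above) > 0) return(pixel_point(max(above), apex$col))
  if (isTRUE(allow_inferior_fossa)) {
    nearest <- gf_rows[which.min(abs(gf_rows - apex$row))]
    return(pixel_point(nearest, apex$col))
  }
  "fossa_not_superior"
}

#' Measure the TMJ joint space width from a label mask
#'
#' Implements the landmark-based measurement: locate the superior-most MC
#' pixel (condyle apex), find the nearest GF pixel directly above it in the
#' same column, and report the vertical distance between the two points.
#' Distance is the raw row-index difference (`apex_row - fossa_row`), in
#' pixels, converted to mm with the row spacing.
#'
#' Anatomical absence is reported through `status`, never as an error:
#' `"ok"`, `"no_condyle"`, `"no_fossa_in_column"`, or `"fossa_not_superior"`.
#'
#' @param mask A [label_mask()].
#' @param allow_inferior_fossa Passed to [find_fossa_match()].
#' @return An object of class `jsw_measurement`: list with `id`, `apex`,
#'   `fossa_point`, `jsw_px`, `jsw_mm`, `status`. Measurement fields are `NA`
#'   unless `status == "ok"`.
#' @export
measure_jsw <- function(mask, allow_inferior_fossa = FALSE) {
  stopifnot(inherits(mask, "label_mask"))
  res <- list(id = mask$id, apex = NULL, fossa_point = NULL,
              jsw_px = NA_real_, jsw_mm = NA_real_, status = "ok")
  apex <- find_condyle_apex(mask)
  if (is.null(apex)) {
    res$status <- "no_condyle"
    return(structure(res, class = "jsw_measurement"))
  }
  res$apex <- apex
  fossa <- find_fossa_match(mask, apex,
                            allow_inferior_fossa = allow_inferior_fossa)
  if (is.character(fossa)) {
    res$status <- fossa
    return(structure(res, class = "jsw_measurement"))
  }
  res$fossa_point <- fossa
  res$jsw_px <- abs(apex$row - fossa$row)
  res$jsw_mm <- res$jsw_px * mask$spacing_mm[1]
  structure(res, class = "jsw_measurement")
}

#' @export
print.jsw_measurement <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "<jsw_measurement> %s: %.0f px = %.3f mm (apex r%d c%d, fossa r%d c%d)\n",
      x$id, x$jsw_px, x$jsw_mm, x$apex$row, x$apex$col,
      x$fossa_point$row, x$fossa_point$col))
  } else {
    cat(sprintf("<jsw_measurement> %s: status %s\n", x$id, x$status))
  }
  invisible(x)
}

#' @export
as.data.frame.jsw_measurement <- function(x, ...) {
  data.frame(
    id = x$id,
    apex_row = if (is.null(x$apex)) NA_integer_ else x$apex$row,
    apex_col = if (is.null(x$apex)) NA_integer_ else x$apex$col,
    fossa_row = if (is.null(x$fossa_point)) NA_integer_ else x$fossa_point$row,
    fossa_col = if (is.null(x$fossa_point)) NA_integer_ else x$fossa_point$col,
    jsw_px = x$jsw_px,
    jsw_mm = x$jsw_mm,
    status = x$status,
    stringsAsFactors = FALSE
  )
}

#' Measure JSW for a list of masks
#'
#' @param masks List of [label_mask()] objects.
#' @param allow_inferior_fossa Passed to [measure_jsw()].
#' @return A data.frame, one row per mask (see
#'   [as.data.frame.jsw_measurement()]).
#' @export
measure_jsw_batch <- function(masks, allow_inferior_fossa = FALSE) {
  rows <- lapply(masks, function(m) {
    as.data.frame(measure_jsw(m, allow_inferior_fossa = allow_inferior_fossa))
  })
  do.call(rbind, rows)
}
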