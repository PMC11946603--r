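#' Class codes for TMJ segmentation masks
#'
#' Fixed mapping between anatomical structure abbreviations and the integer
#' codes used in label masks: background = 0, mandibular condyle (MC) = 1,
#' joint space (JS) = 2, glenoid fossa (GF) = 3.
#'
#' @return Named integer vector `c(MC = 1, JS = 2, GF = 3)`.
#' @export
tmj_classes <- function() {
  c(MC = 1L, JS = 2L, GF = 3L)
}

#' Construct an 8-bit grayscale ultrasound image
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`. Row 1 is the
#'   top of the image (anatomically superior for TMJ scans acquired with the
#'   standard screen convention), column 1 the left edge.
#' @param spacing_mm Numeric length-2 vector `(row_spacing, col_spacing)` in
#'   mm per pixel; both strictly positive.
#' @param id Case identifier string.
#'
#' @return An object of class `us_image` (a list with elements `pixels`,
#'   `spacing_mm`, `id`).
#' @export
us_image <- function(pixels, spacing_mm = c(1, 1), id = NA_character_) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px) || any(px < 0L) || any(px > 255L)) {
    stop("pixel intensities must be integers in [0, 255]")
  }
  spacing_mm <- check_spacing(spacing_mm)
  structure(
    list(pixels = px, spacing_mm = spacing_mm, id = as.character(id)),
    class = "us_image"
  )
}

#' Construct a multi-class TMJ label mask
#'
#' @param labels Integer matrix of class codes in `{0, 1, 2, 3}` (see
#'   [tmj_classes()]); same orientation convention as [us_image()].
#' @param spacing_mm Numeric `(row_spacing, col_spacing)` in mm per pixel.
#' @param id Case identifier string.
#'
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing_mm = c(1, 1), id = NA_character_) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  lab <- labels
  storage.mode(lab) <- "integer"
  if (anyNA(lab) || any(!(lab %in% 0:3))) {
    bad <- unique(lab[!(lab %in% 0:3)])
    stop("mask values must be in {0,1,2,3}; found: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  spacing_mm <- check_spacing(spacing_mm)
  structure(
    list(labels = lab, spacing_mm = spacing_mm, id = as.character(id),
         class_names = tmj_classes()),
    class = "label_mask"
  )
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(spacing_mm) != 2 || anyNA(spacing_mm) || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be two strictly positive numbers (row, col)")
  }
  spacing_mm
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %s: %d x %d px, spacing %.4g x %.4g mm/px\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2]))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  counts <- vapply(0:3, function(k) sum(x$labels == k), integer(1))
  cat(sprintf("<label_mask> %s: %d x %d px, spacing %.4g x %.4g mm/px\n",
              x$id, nrow(x$labels), ncol(x$labels),
              x$spacing_mm[1], x$spacing_mm[2]))
  cat(sprintf("  background: %d  MC: %d  JS: %d  GF: %d\n",
              counts[1], counts[2], counts[3], counts[4]))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

#' @export
dim.label_mask <- function(x) dim(x$labels)

stop_if_shape_mismatch <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
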