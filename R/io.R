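#' Read an 8-bit grayscale ultrasound image (PNG or TIFF)
#'
#' Reads a single-channel 8-bit image. Multi-channel files are accepted only
#' when all colour channels are identical (a grayscale image stored as RGB),
#' in which case the first channel is used. Pixel spacing is taken, in order
#' of precedence, from the `spacing_mm` argument, a JSON sidecar
#' `<stem>.json` with a `spacing_mm` field, or defaults to `(1, 1)` with a
#' warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param spacing_mm Optional `(row, col)` spacing override in mm/pixel.
#' @param id Case id; defaults to the file stem.
#' @return A [us_image()].
#' @export
read_us_image <- function(path, spacing_mm = NULL, id = NULL) {
  arr <- read_gray_array(path)
  px <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  if (is.null(id)) id <- file_stem(path)
  if (is.null(spacing_mm)) spacing_mm <- sidecar_spacing(path)
  us_image(px, spacing_mm = spacing_mm, id = id)
}

#' Read a multi-class label mask
#'
#' Reads an indexed/grayscale label image and remaps stored pixel values to
#' the class codes 0..3. Any stored value missing from `class_map` is an
#' error naming the offending value.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` label image.
#' @param class_map Named integer vector mapping stored 8-bit values to class
#'   codes, e.g. `c("0" = 0, "50" = 1, "100" = 2, "150" = 3)`. Default is the
#'   identity map on 0..3.
#' @param spacing_mm Optional `(row, col)` spacing override in mm/pixel.
#' @param id Case id; defaults to the file stem.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, class_map = identity_class_map(),
                            spacing_mm = NULL, id = NULL) {
  arr <- read_gray_array(path)
  stored <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  keys <- as.integer(names(class_map))
  if (anyNA(keys)) stop("'class_map' must have integer-valued names")
  unknown <- setdiff(unique(as.vector(stored)), keys)
  if (length(unknown) > 0) {
    stop("mask '", path, "' contains value(s) not in class_map: ",
         paste(sort(unknown), collapse = ", "))
  }
  lab <- matrix(as.integer(class_map[match(stored, keys)]),
                nrow = nrow(stored), ncol = ncol(stored))
  if (is.null(id)) id <- file_stem(path)
  if (is.null(spacing_mm)) spacing_mm <- sidecar_spacing(path)
  label_mask(lab, spacing_mm = spacing_mm, id = id)
}

#' @rdname read_label_mask
#' @export
identity_class_map <- function() {
  stats::setNames(0:3, 0:3)
}

#' Write an image or mask as an 8-bit grayscale PNG
#'
#' Masks are written with their class codes as raw pixel values (0..3), so a
#' read/write round trip through [read_label_mask()] with the identity class
#' map is lossless.
#'
#' @param x A [us_image()] or [label_mask()].
#' @param path Output `.png` path.
#' @param sidecar Write a `<stem>.json` sidecar carrying `spacing_mm`?
#' @return `path`, invisibly.
#' @export
write_png8 <- function(x, path, sidecar = TRUE) {
  vals <- if (inherits(x, "label_mask")) x$labels else x$pixels
  png::writePNG(vals / 255, target = path)
  if (isTRUE(sidecar)) {
    jsonlite::write_json(list(spacing_mm = x$spacing_mm, id = x$id),
                         sidecar_path(path), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

read_gray_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      stop("unsupported bit depth (", info$bit.depth, ") in ", path,
           "; 8-bit input required")
    }
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits > 8) {
      stop("unsupported bit depth (", bits, ") in ", path,
           "; 8-bit input required")
    }
  } else {
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)")
  }
  collapse_channels(arr, path)
}

collapse_channels <- function(arr, path) {
  if (length(dim(arr)) == 2) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    ch <- min(nc, 3)  # ignore an alpha channel if fully opaque colour data
    for (k in seq_len(ch)[-1]) {
      if (!isTRUE(all.equal(arr[, , 1], arr[, , k], tolerance = 1e-12))) {
        stop("multi-channel image with non-identical channels: ", path)
      }
    }
    return(arr[, , 1])
  }
  stop("unsupported image array in ", path)
}

sidecar_path <- function(path) {
  file.path(dirname(path), paste0(file_stem(path), ".json"))
}

file_stem <- function(path) {
  sub("\\.[^.]*$", "", basename(path))
}

sidecar_spacing <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) return(as.numeric(meta$spacing_mm))
  }
  warning("no pixel spacing found for '", basename(path),
          "'; defaulting to 1 mm/pixel", call. = FALSE)
  c(1, 1)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `id, image, mask, row_spacing_mm,
#' col_spacing_mm`; `image` and `mask` paths are resolved relative to the
#' manifest's directory when not absolute.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "image", "mask", "row_spacing_mm", "col_spacing_mm")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image <- resolve(man$image)
  man$mask <- resolve(man$mask)
  man
}

#' Split case ids into train / validation / test sets
#'
#' Holdout split with a random, seed-reproducible assignment. Validation and
#' test set sizes are `fraction * n` rounded half-down; the remainder goes to
#' the training set (the largest bucket), so 142 ids under the default
#' fractions give 86 / 21 / 35.
#'
#' @param ids Character or integer vector of unique case ids.
#' @param fractions Numeric length-3 `(train, val, test)` summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @return A list of class `dataset_split` with elements `train_ids`,
#'   `val_ids`, `test_ids`, `seed`.
#' @export
make_split <- function(ids, fractions = c(0.60, 0.15, 0.25), seed = 1L) {
  if (length(ids) < 3) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("duplicate ids in 'ids'")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must be 3 non-negative numbers summing to 1")
  }
  n <- length(ids)
  round_half_down <- function(x) as.integer(ceiling(x - 0.5))
  n_val <- round_half_down(fractions[2] * n)
  n_test <- round_half_down(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("split leaves no training cases")
  perm <- withr::with_seed(seed, sample(ids))
  structure(
    list(train_ids = perm[seq_len(n_train)],
         val_ids = perm[n_train + seq_len(n_val)],
         test_ids = perm[n_train + n_val + seq_len(n_test)],
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Write JSW measurements to CSV
#'
#' One row per case with columns `id, apex_row, apex_col, fossa_row,
#' fossa_col, jsw_px, jsw_mm, status`. mm values are written with
#' `digits` decimal places (>= 3).
#'
#' @param measurements List of `jsw_measurement` objects (see
#'   [measure_jsw()]) or a data.frame with the columns above.
#' @param path Output CSV path.
#' @param digits Decimal places for `jsw_mm` (minimum 3).
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path, digits = 6) {
  digits <- max(3L, as.integer(digits))
  df <- if (is.data.frame(measurements)) measurements else
    do.call(rbind, lapply(measurements, as.data.frame))
  cols <- c("id", "apex_row", "apex_col", "fossa_row", "fossa_col",
            "jsw_px", "jsw_mm", "status")
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  }
  df <- df[, cols, drop = FALSE]
  if (nrow(df) > 0) {
    df$jsw_mm <- ifelse(is.na(df$jsw_mm), "",
                        sprintf(paste0("%.", digits, "f"), df$jsw_mm))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a JSW measurements CSV written by [write_measurements_csv()]
#'
#' @param path CSV path.
#' @return A data.frame with numeric measurement columns.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  for (col in c("apex_row", "apex_col", "fossa_row", "fossa_col",
                "jsw_px", "jsw_mm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
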