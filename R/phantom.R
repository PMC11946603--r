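#' Specification of a synthetic TMJ ultrasound phantom
#'
#' The phantom emulates the appearance a TMJ scan presents to a segmentation
#' model: two hyperechoic (bright) curved bone-surface bands -- a convex
#' mandibular condyle below and a concave glenoid fossa above -- separated by
#' a darker joint-space band of known vertical width, with multiplicative
#' speckle noise and 8-bit quantization in the image channel. The paired
#' ground-truth mask is noise-free and fully determined by the geometry, so
#' the true JSW at the condyle apex is known exactly by construction.
#'
#' Geometry: in the apex column, the condyle surface sits at `apex_row` and
#' the lowest fossa pixel at `apex_row - jsw_px`; band surfaces follow
#' parabolas (`row = apex_row + curvature * d^2`, `d` = column offset), so
#' the condyle has a unique, column-symmetric superior apex.
#'
#' @param image_size `(rows, cols)`, default `(128, 128)`.
#' @param spacing_mm `(row, col)` mm per pixel, default `(0.05, 0.05)`.
#' @param jsw_px True vertical gap at the condyle apex in pixels (integer,
#'   >= 2).
#' @param condyle_curvature,fossa_curvature Parabola coefficients (1/px).
#' @param band_thickness_px Bone-band thickness in pixels.
#' @param halfwidth_px Lateral half-extent of the bands around the apex
#'   column; `NULL` = as wide as fits symmetrically (capped at 45% of the
#'   image width).
#' @param apex_col,apex_row Apex position; `NULL` = image centre column and
#'   the shallowest feasible apex row.
#' @param speckle_scale Multiplicative speckle amplitude in `[0, 1)`.
#' @param fossa_dropout_prob Probability of erasing the fossa band from a
#'   random lateral position out to one edge (simulating a weakly echogenic
#'   fossa); the eroded band stays a single connected component.
#' @param seed Integer seed; image noise and dropout are fully determined by
#'   `spec + seed`.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(128, 128),
                         spacing_mm = c(0.05, 0.05),
                         jsw_px = 30L,
                         condyle_curvature = 0.02,
                         fossa_curvature = 0.012,
                         band_thickness_px = 6L,
                         halfwidth_px = NULL,
                         apex_col = NULL,
                         apex_row = NULL,
                         speckle_scale = 0.25,
                         fossa_dropout_prob = 0,
                         seed = 1L) {
  rows <- as.integer(image_size[1]); cols <- as.integer(image_size[2])
  jsw_px <- as.integer(jsw_px)
  band <- as.integer(band_thickness_px)
  if (jsw_px < 2) stop("jsw_px must be an integer >= 2")
  if (jsw_px + 2L * band >= rows) {
    stop("infeasible geometry: jsw_px + 2*band_thickness_px must be < rows")
  }
  if (condyle_curvature <= 0 || fossa_curvature <= 0) {
    stop("curvatures must be positive")
  }
  if (speckle_scale < 0 || speckle_scale >= 1) {
    stop("speckle_scale must be in [0, 1)")
  }
  if (is.null(apex_col)) apex_col <- (cols + 1L) %/% 2L
  apex_col <- as.integer(apex_col)
  if (is.null(halfwidth_px)) {
    halfwidth_px <- min(apex_col - 1L, cols - apex_col,
                        as.integer(round(0.45 * cols)))
  }
  halfwidth_px <- as.integer(halfwidth_px)
  if (apex_col - halfwidth_px < 1L || apex_col + halfwidth_px > cols) {
    stop("infeasible geometry: bands must fit symmetrically around apex_col")
  }
  # flat tie region of the condyle surface must lie inside the bands so the
  # apex column is recovered exactly by the median-of-ties rule
  tie <- apex_tie_halfwidth(condyle_curvature)
  if (tie >= halfwidth_px) {
    stop("infeasible geometry: condyle too flat for the lateral extent")
  }
  min_apex_row <- jsw_px + band + 2L
  if (is.null(apex_row)) apex_row <- min_apex_row
  apex_row <- as.integer(apex_row)
  if (apex_row < min_apex_row || apex_row + 1L > rows) {
    stop("infeasible geometry: apex_row out of range")
  }
  structure(
    list(image_size = c(rows, cols), spacing_mm = check_spacing(spacing_mm),
         jsw_px = jsw_px, condyle_curvature = condyle_curvature,
         fossa_curvature = fossa_curvature, band_thickness_px = band,
         halfwidth_px = halfwidth_px, apex_col = apex_col,
         apex_row = apex_row, speckle_scale = speckle_scale,
         fossa_dropout_prob = fossa_dropout_prob, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# widest |d| whose parabolic drop rounds to 0 rows
apex_tie_halfwidth <- function(curvature) {
  d <- 0L
  while (round(curvature * (d + 1L)^2) < 1) d <- d + 1L
  d
}

#' Generate a synthetic TMJ phantom
#'
#' @param spec A [phantom_spec()].
#' @param id Case id for the generated image/mask.
#' @return A list of class `phantom_sample`: `image` ([us_image()]), `mask`
#'   ([label_mask()]), `true_jsw_px`, `true_jsw_mm`, `true_apex`
#'   (`pixel_point`). Bit-identical for a fixed spec (including seed).
#' @export
generate_phantom <- function(spec, id = sprintf("phantom_%06d", spec$seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- spec$image_size[1]; cols <- spec$image_size[2]
  cls <- tmj_classes()
  lab <- matrix(0L, rows, cols)

  c0 <- spec$apex_col; r_a <- spec$apex_row
  r_f <- r_a - spec$jsw_px
  band <- spec$band_thickness_px
  dcols <- (c0 - spec$halfwidth_px):(c0 + spec$halfwidth_px)

  withr::with_seed(spec$seed, {
    drop_cols <- integer(0)
    if (spec$fossa_dropout_prob > 0 &&
        stats::runif(1) < spec$fossa_dropout_prob) {
      side <- sample(c(-1L, 1L), 1L)
      tie <- apex_tie_halfwidth(spec$condyle_curvature)
      lo <- min(tie + 2L, spec$halfwidth_px - 1L)
      start <- sample(lo:(spec$halfwidth_px - 1L), 1L)
      drop_cols <- c0 + side * (start:spec$halfwidth_px)
    }
    for (j in dcols) {
      d <- j - c0
      cond_top <- r_a + as.integer(round(spec$condyle_curvature * d^2))
      gf_low <- r_f - as.integer(round(spec$fossa_curvature * d^2))
      # mandibular condyle band (below the gap)
      mc_rows <- cond_top:min(cond_top + band - 1L, rows)
      mc_rows <- mc_rows[mc_rows >= 1L & mc_rows <= rows]
      lab[mc_rows, j] <- cls[["MC"]]
      # glenoid fossa band (above the gap), optionally eroded laterally
      if (!(j %in% drop_cols)) {
        gf_rows <- max(gf_low - band + 1L, 1L):gf_low
        gf_rows <- gf_rows[gf_rows >= 1L & gf_rows <= rows]
        lab[gf_rows, j] <- cls[["GF"]]
      }
      # joint space between the two bands
      if (gf_low + 1L <= cond_top - 1L) {
        js_rows <- (gf_low + 1L):(cond_top - 1L)
        js_rows <- js_rows[js_rows >= 1L & js_rows <= rows]
        lab[js_rows, j] <- cls[["JS"]]
      }
    }
    base <- matrix(40, rows, cols)
    base[lab == cls[["MC"]] | lab == cls[["GF"]]] <- 200
    base[lab == cls[["JS"]]] <- 15
    if (spec$speckle_scale > 0) {
      rayleigh <- sqrt(-2 * log(stats::runif(rows * cols)))  # mode 1
      base <- base * (1 + spec$speckle_scale * (rayleigh - 1))
    }
    px <- matrix(as.integer(pmin(pmax(round(base), 0), 255)), rows, cols)
  })

  structure(
    list(
      image = us_image(px, spacing_mm = spec$spacing_mm, id = id),
      mask = label_mask(lab, spacing_mm = spec$spacing_mm, id = id),
      true_jsw_px = spec$jsw_px,
      true_jsw_mm = spec$jsw_px * spec$spacing_mm[1],
      true_apex = pixel_point(r_a, c0),
      spec = spec
    ),
    class = "phantom_sample"
  )
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s: %d x %d px, true JSW %d px = %.3f mm\n",
              x$image$id, nrow(x$image$pixels), ncol(x$image$pixels),
              x$true_jsw_px, x$true_jsw_mm))
  invisible(x)
}

#' Generate a cohort of phantoms with randomized geometry
#'
#' True JSW is drawn uniformly from `jsw_range_mm`; apex position, band
#' thickness and curvatures are jittered per sample within feasible ranges.
#' Per-sample seeds are derived from the master seed, so two calls with the
#' same arguments produce identical cohorts.
#'
#' @param n Number of phantoms (>= 1).
#' @param jsw_range_mm True JSW range in mm, default `c(0.8, 4.0)`.
#' @param image_size,spacing_mm,speckle_scale,fossa_dropout_prob Passed to
#'   [phantom_spec()].
#' @param seed Master seed.
#' @return List of `phantom_sample` objects.
#' @export
generate_cohort <- function(n, jsw_range_mm = c(0.8, 4.0),
                            image_size = c(128, 128),
                            spacing_mm = c(0.05, 0.05),
                            speckle_scale = 0.25,
                            fossa_dropout_prob = 0,
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  rows <- image_size[1]; cols <- image_size[2]
  jsw_px_max <- as.integer(floor(jsw_range_mm[2] / spacing_mm[1]))
  if (jsw_px_max + 2L * 8L >= rows) {
    stop("infeasible jsw_range_mm for this image size")
  }
  params <- withr::with_seed(seed, {
    data.frame(
      seed = sample.int(.Machine$integer.max - 1L, n),
      jsw_mm = stats::runif(n, jsw_range_mm[1], jsw_range_mm[2]),
      curv_c = stats::runif(n, 0.02, 0.06),
      curv_f = stats::runif(n, 0.012, 0.03),
      band = sample(5:8, n, replace = TRUE),
      col_jitter = sample(-6:6, n, replace = TRUE),
      row_slack = stats::runif(n)
    )
  })
  lapply(seq_len(n), function(i) {
    p <- params[i, ]
    jsw_px <- max(2L, as.integer(round(p$jsw_mm / spacing_mm[1])))
    min_r <- jsw_px + p$band + 2L
    max_r <- rows - p$band - 2L
    apex_row <- min_r + as.integer(floor(p$row_slack * max(0L, max_r - min_r)))
    spec <- phantom_spec(
      image_size = image_size, spacing_mm = spacing_mm, jsw_px = jsw_px,
      condyle_curvature = p$curv_c, fossa_curvature = p$curv_f,
      band_thickness_px = p$band,
      apex_col = (cols + 1L) %/% 2L + p$col_jitter,
      apex_row = apex_row, speckle_scale = speckle_scale,
      fossa_dropout_prob = fossa_dropout_prob, seed = p$seed
    )
    generate_phantom(spec, id = sprintf("phantom_%03d", i))
  })
}

#' Add spurious components to a mask
#'
#' Adds `n_spurious` small connected blobs (discs) per non-background class,
#' each strictly smaller than `max_spurious_frac` times the largest component
#' of that class, placed on background pixels with one pixel of clearance
#' from every existing structure and away from specified columns. With
#' `max_spurious_frac < 0.6`, [filter_components()] at the default threshold
#' removes every added blob and recovers the input mask exactly.
#'
#' @param mask A [label_mask()].
#' @param n_spurious Blobs per class (0 = identity).
#' @param max_spurious_frac Upper bound on blob size relative to the largest
#'   component of its class; must be < 0.6.
#' @param seed Integer seed (deterministic placement).
#' @param avoid_cols Columns where blob pixels may not be placed (e.g. the
#'   apex column neighbourhood).
#' @return A degraded [label_mask()].
#' @export
degrade_mask <- function(mask, n_spurious = 2L, max_spurious_frac = 0.4,
                         seed = 1L, avoid_cols = integer(0)) {
  stopifnot(inherits(mask, "label_mask"))
  if (max_spurious_frac >= 0.6) stop("max_spurious_frac must be < 0.6")
  if (n_spurious == 0) return(mask)
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  withr::with_seed(seed, {
    for (cls in tmj_classes()) {
      sizes <- component_sizes(label_components(lab == cls))
      if (length(sizes) == 0) next
      cap <- max_spurious_frac * max(sizes)
      for (b in seq_len(n_spurious)) {
        placed <- FALSE
        for (try in 1:500) {
          r <- sample(1:3, 1L)
          ctr <- c(sample(seq_len(nr), 1L), sample(seq_len(nc), 1L))
          blob <- disc_offsets(r)
          blob[, 1] <- blob[, 1] + ctr[1]; blob[, 2] <- blob[, 2] + ctr[2]
          if (nrow(blob) >= cap) next
          halo <- disc_offsets(r + 1.5)
          halo[, 1] <- halo[, 1] + ctr[1]; halo[, 2] <- halo[, 2] + ctr[2]
          if (any(halo[, 1] < 1 | halo[, 1] > nr |
                  halo[, 2] < 1 | halo[, 2] > nc)) next
          if (any(blob[, 2] %in% avoid_cols)) next
          if (any(lab[halo] != 0L)) next
          lab[blob] <- cls
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("cannot place spurious blobs without touching existing components")
        }
      }
    }
  })
  label_mask(lab, spacing_mm = mask$spacing_mm, id = mask$id)
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  cbind(g$dr, g$dc)
}

#' Write a phantom cohort to disk
#'
#' Emits `images/<id>.png`, `masks/<id>.png`, `manifest.csv` and `truth.csv`
#' under `dir`.
#'
#' @param samples List of `phantom_sample` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(samples, function(s) {
    img_rel <- file.path("images", paste0(s$image$id, ".png"))
    msk_rel <- file.path("masks", paste0(s$mask$id, ".png"))
    write_png8(s$image, file.path(dir, img_rel), sidecar = FALSE)
    write_png8(s$mask, file.path(dir, msk_rel), sidecar = FALSE)
    data.frame(id = s$image$id, image = img_rel, mask = msk_rel,
               row_spacing_mm = s$image$spacing_mm[1],
               col_spacing_mm = s$image$spacing_mm[2],
               stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(samples, function(s) {
    data.frame(id = s$image$id, true_jsw_px = s$true_jsw_px,
               true_jsw_mm = s$true_jsw_mm,
               apex_row = s$true_apex$row, apex_col = s$true_apex$col,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
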