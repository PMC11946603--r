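test_that("phantom generation is bit-identical for a fixed spec and seed", {
  spec <- phantom_spec(jsw_px = 24, speckle_scale = 0.3,
                       fossa_dropout_prob = 0.5, seed = 77)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$labels, b$mask$labels)

  c2 <- generate_phantom(phantom_spec(jsw_px = 24, speckle_scale = 0.3,
                                      seed = 78))
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("zero speckle and dropout give the deterministic template", {
  a <- generate_phantom(phantom_spec(speckle_scale = 0, seed = 1))
  b <- generate_phantom(phantom_spec(speckle_scale = 0, seed = 999))
  expect_identical(a$image$pixels, b$image$pixels)  # no randomness left
  # bright bone bands, dark joint space
  cls <- tmj_classes()
  px <- a$image$pixels; lab <- a$mask$labels
  expect_true(all(px[lab == cls[["MC"]]] == 200))
  expect_true(all(px[lab == cls[["GF"]]] == 200))
  expect_true(all(px[lab == cls[["JS"]]] == 15))
  expect_true(all(px[lab == 0] == 40))
})

test_that("the clean mask reproduces the constructed gap exactly", {
  for (jsw in c(2, 10, 30, 55)) {
    s <- generate_phantom(phantom_spec(jsw_px = jsw, seed = jsw))
    got <- measure_jsw(s$mask)
    expect_identical(got$status, "ok")
    expect_equal(got$jsw_px, jsw)
    expect_identical(got$apex$row, s$true_apex$row)
    expect_identical(got$apex$col, s$true_apex$col)
  }
  s30 <- generate_phantom(phantom_spec(jsw_px = 30,
                                       spacing_mm = c(0.05, 0.05), seed = 2))
  expect_equal(measure_jsw(s30$mask)$jsw_mm, 1.50)
})

test_that("infeasible geometry is rejected", {
  expect_error(phantom_spec(jsw_px = 1), ">= 2")
  expect_error(phantom_spec(jsw_px = 120, image_size = c(128, 128)),
               "infeasible")
  expect_error(phantom_spec(condyle_curvature = 1e-6), "infeasible")
  expect_error(phantom_spec(speckle_scale = 1), "speckle")
  expect_error(generate_cohort(10, jsw_range_mm = c(0.8, 8)), "infeasible")
})

test_that("cohorts are reproducible and cover the requested JSW range", {
  a <- generate_cohort(30, seed = 9)
  b <- generate_cohort(30, seed = 9)
  expect_identical(lapply(a, function(s) s$mask$labels),
                   lapply(b, function(s) s$mask$labels))
  expect_identical(length(generate_cohort(1, seed = 2)), 1L)

  mm <- vapply(a, function(s) s$true_jsw_mm, numeric(1))
  expect_true(all(mm >= 0.8 - 0.025 & mm <= 4.0 + 0.025))  # rounding to px
  expect_gt(stats::sd(mm), 0.2)  # genuinely spread across the range
})

test_that("degradation adds only sub-threshold clutter and is reversible", {
  s <- generate_phantom(phantom_spec(jsw_px = 26, seed = 14))
  avoid <- (s$true_apex$col - 3):(s$true_apex$col + 3)
  d <- degrade_mask(s$mask, n_spurious = 3, max_spurious_frac = 0.4,
                    seed = 5, avoid_cols = avoid)
  expect_false(identical(d$labels, s$mask$labels))
  # every class gained components, all below 60% of its largest
  for (cls in tmj_classes()) {
    sizes <- sort(component_sizes(label_components(d$labels == cls)),
                  decreasing = TRUE)
    expect_gte(length(sizes), 4)  # original + 3 blobs
    expect_true(all(sizes[-1] < 0.6 * sizes[1]))
  }
  restored <- filter_components(d)
  expect_identical(restored$labels, s$mask$labels)

  expect_identical(degrade_mask(s$mask, n_spurious = 0)$labels, s$mask$labels)
  d2 <- degrade_mask(s$mask, n_spurious = 3, max_spurious_frac = 0.4,
                     seed = 5, avoid_cols = avoid)
  expect_identical(d2$labels, d$labels)  # deterministic placement
  expect_error(degrade_mask(s$mask, max_spurious_frac = 0.7), "0.6")
})

test_that("cohorts written to disk round-trip through the manifest", {
  dir <- withr::local_tempdir()
  co <- small_cohort(4, seed = 44)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  masks <- load_masks(man)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  for (i in seq_along(co)) {
    expect_identical(masks[[co[[i]]$mask$id]]$labels, co[[i]]$mask$labels)
    expect_equal(measure_jsw(masks[[i]])$jsw_px, truth$true_jsw_px[i])
  }
  img <- read_us_image(man$image[1], spacing_mm = c(man$row_spacing_mm[1],
                                                    man$col_spacing_mm[1]))
  expect_identical(img$pixels, co[[1]]$image$pixels)
})
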