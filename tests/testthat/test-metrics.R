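# pred MC occupies 4 px, ref MC 6 px, overlapping in 3 -> (tp, fp, fn) = (3, 1, 3)
overlap_pair <- function() {
  pred <- mask_with(6, 6, MC = cbind(1, 1:4))
  ref <- mask_with(6, 6, MC = cbind(1, 2:6), GF = cbind(4, 1))
  ref$labels[2, 2] <- tmj_classes()[["MC"]]  # ref has 6 MC px total
  list(pred = pred, ref = ref)
}

test_that("confusion counts, Dice, precision, recall and VS match hand values", {
  pr <- overlap_pair()
  cc <- confusion_counts(pr$pred, pr$ref, 1)
  expect_identical(cc, list(tp = 3L, fp = 1L, fn = 3L))
  expect_equal(dice_coefficient(cc), 0.6)
  expect_equal(precision_metric(cc), 0.75)
  expect_equal(recall_metric(cc), 0.5)
  expect_equal(volume_similarity(4, 6), 0.8)
  expect_equal(volume_similarity(5, 5), 1)
  expect_equal(volume_similarity(0, 7), 0)

  # identity: no false positives or negatives anywhere
  m <- random_mask(12, 12)
  for (cls in tmj_classes()) {
    cci <- confusion_counts(m, m, cls)
    expect_identical(cci$fp + cci$fn, 0L)
    expect_equal(dice_coefficient(cci), 1)
  }

  # empty prediction against a populated reference scores 0, not NA
  empty <- label_mask(matrix(0L, 6, 6))
  ref <- mask_with(6, 6, GF = cbind(2, 2:4))
  cc0 <- confusion_counts(empty, ref, 3)
  expect_identical(cc0, list(tp = 0L, fp = 0L, fn = 3L))
  expect_equal(dice_coefficient(cc0), 0)
  expect_true(is.na(precision_metric(cc0)))  # no predicted positives
  expect_equal(recall_metric(cc0), 0)

  # both empty: vacuous perfect agreement
  cc1 <- confusion_counts(empty, empty, 2)
  expect_equal(dice_coefficient(cc1), 1)
  expect_equal(precision_metric(cc1), 1)

  expect_error(confusion_counts(empty, mask_with(4, 4, MC = cbind(1, 1)), 1),
               "shape")
})

test_that("Hausdorff distance uses physical spacing and both directions", {
  a <- mask_with(8, 8, MC = cbind(1, 1))
  b <- mask_with(8, 8, MC = cbind(4, 5))
  expect_equal(hausdorff_mm(a, b, 1), 5)  # 3-4-5 triangle at 1 mm/px
  expect_equal(hausdorff_mm(b, a, 1), 5)  # symmetric

  a2 <- mask_with(8, 8, MC = cbind(1, 1), spacing_mm = c(0.05, 0.1))
  b2 <- mask_with(8, 8, MC = cbind(4, 5), spacing_mm = c(0.05, 0.1))
  expect_equal(hausdorff_mm(a2, b2, 1), sqrt((3 * 0.05)^2 + (4 * 0.1)^2))

  m <- random_mask(12, 12)
  expect_equal(hausdorff_mm(m, m, 1), 0)
  empty <- label_mask(matrix(0L, 12, 12))
  expect_true(is.na(hausdorff_mm(empty, m, 1)))
  expect_equal(hausdorff_mm(empty, empty, 1), 0)
})

test_that("Hausdorff matches the all-pairs brute-force oracle", {
  for (seed in 1:15) {
    pred <- withr::with_seed(seed, random_mask(16, 16, spacing_mm = c(0.05, 0.08)))
    ref <- withr::with_seed(seed + 500, random_mask(16, 16, spacing_mm = c(0.05, 0.08)))
    for (cls in tmj_classes()) {
      expect_equal(hausdorff_mm(pred, ref, cls),
                   brute_hausdorff_mm(pred, ref, cls),
                   tolerance = 1e-12,
                   label = sprintf("seed %d class %d", seed, cls))
    }
  }
})

test_that("Hausdorff agrees with pracma on raw boundary point sets", {
  skip_if_not_installed("pracma")
  pred <- withr::with_seed(42, random_mask(20, 20))
  ref <- withr::with_seed(43, random_mask(20, 20))
  a <- boundary_points(pred$labels, 1)
  b <- boundary_points(ref$labels, 1)
  expect_equal(hausdorff_mm(pred, ref, 1),
               pracma::hausdorff_dist(a, b), tolerance = 1e-12)
})

test_that("Dice is the harmonic mean of precision and recall", {
  withr::with_seed(7, {
    for (i in 1:200) {
      cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
                 fn = sample(0:50, 1))
      p <- precision_metric(cc)
      r <- recall_metric(cc)
      d <- dice_coefficient(cc)
      if (!is.na(p) && !is.na(r) && p + r > 0) {
        expect_equal(d, 2 * p * r / (p + r), tolerance = 1e-12)
      }
      vs <- volume_similarity(cc$tp + cc$fp, cc$tp + cc$fn)
      expect_gte(vs + 1e-15, d)
      expect_true(d >= 0 && d <= 1 && vs >= 0 && vs <= 1)
    }
  })
})

test_that("per-case evaluation and test-set summaries behave like a report", {
  m <- withr::with_seed(12, random_mask(20, 20))
  rep0 <- evaluate_case(m, m, id = "self")
  expect_identical(nrow(rep0), 3L)
  expect_true(all(rep0$dice == 1 & rep0$precision == 1 & rep0$recall == 1 &
                  rep0$vs == 1 & rep0$hd_mm == 0))

  # two synthetic cases with known Dice 0.6 and 0.8 for MC
  pr <- overlap_pair()
  rep1 <- evaluate_case(pr$pred, pr$ref, id = "a")       # MC Dice 0.6
  pred2 <- mask_with(6, 6, MC = cbind(1, 1:4))
  ref2 <- mask_with(6, 6, MC = cbind(1, 1:6))            # (4,0,2): Dice 0.8
  rep2 <- evaluate_case(pred2, ref2, id = "b")
  s <- summarize_metrics(rbind(rep1, rep2))
  mc_dice <- s[s$class == "MC" & s$metric == "dice", ]
  expect_equal(mc_dice$mean, 0.7)
  expect_equal(mc_dice$sd, sqrt(((0.6 - 0.7)^2 + (0.8 - 0.7)^2) / 1),
               tolerance = 1e-12)
  expect_identical(mc_dice$n, 2L)

  # undefined values are excluded and counted: GF absent from both pred2/ref2
  # masks gives HD 0 there, but rep1's GF exists only in the reference
  gf_hd <- s[s$class == "GF" & s$metric == "hd_mm", ]
  expect_identical(gf_hd$n_excluded, 1L)
  expect_identical(gf_hd$n, 1L)

  expect_error(summarize_metrics(rep1[0, ]), "empty")
  expect_equal(overall_dice(rbind(rep0, rep0)), 1)
})
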