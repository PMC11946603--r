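#' Paired AI-vs-reference agreement statistics for JSW measurements
#'
#' Computes the method-comparison summary for paired joint-space-width
#' measurements: per-method mean and median, bias (mean difference, signed,
#' with the convention `reference - AI`), standard deviation of the
#' differences (sample, n-1), Bland-Altman 95% limits of agreement
#' (`bias +/- 1.96 * sd`), mean absolute error, mean percentage error
#' (mean over cases of `|ai - ref| / ref * 100`), and root mean square error.
#'
#' @param pairs A data.frame with columns `ai_mm`, `ref_mm` (both positive)
#'   and optionally `id`.
#' @return An object of class `agreement_report` (a list of the statistics
#'   plus `n`).
#' @export
agreement_stats <- function(pairs) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) < 2) stop("need at least 2 paired measurements")
  ai <- pairs$ai_mm
  ref <- pairs$ref_mm
  d <- ref - ai
  n <- length(d)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(
      n = n,
      ai_mean = mean(ai), ai_median = stats::median(ai),
      ref_mean = mean(ref), ref_median = stats::median(ref),
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      mae = mean(abs(d)),
      mpe = mean(abs(ai - ref) / ref) * 100,
      rmse = sqrt(mean(d^2))
    ),
    class = "agreement_report"
  )
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("ai_mm", "ref_mm") %in% names(pairs))) {
    stop("'pairs' must be a data.frame with columns ai_mm and ref_mm")
  }
  if (anyNA(pairs$ai_mm) || anyNA(pairs$ref_mm)) {
    stop("paired measurements must not contain NA; exclude non-ok cases first")
  }
  if (any(pairs$ai_mm <= 0) || any(pairs$ref_mm <= 0)) {
    stop("measurements must be positive")
  }
  pairs
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement of paired JSW measurements (difference = reference - AI)\n")
  cat(sprintf("  n cases                     %d\n", x$n))
  cat(sprintf("  AI mean / median (mm)       %.3f / %.3f\n", x$ai_mean, x$ai_median))
  cat(sprintf("  Reference mean / median (mm) %.3f / %.3f\n", x$ref_mean, x$ref_median))
  cat(sprintf("  Mean difference (mm)        %.3f\n", x$bias))
  cat(sprintf("  SD of differences (mm)      %.3f\n", x$sd_diff))
  cat(sprintf("  95%% limits of agreement (mm) [%.3f, %.3f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  Mean percentage error (%%)   %.2f\n", x$mpe))
  cat(sprintf("  Mean absolute error (mm)    %.3f\n", x$mae))
  cat(sprintf("  Root mean square error (mm) %.3f\n", x$rmse))
  invisible(x)
}

#' Bland-Altman plot data
#'
#' Per-case points `((ai + ref)/2, ref - ai)` plus the bias line and the 95%
#' limits of agreement.
#'
#' @param pairs A data.frame with columns `ai_mm`, `ref_mm`, optional `id`.
#' @return A data.frame of columns `id, mean_mm, diff_mm`, with attributes
#'   `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman_points <- function(pairs) {
  rep <- agreement_stats(pairs)
  pairs <- check_pairs(pairs)
  pts <- data.frame(
    id = if ("id" %in% names(pairs)) pairs$id else seq_len(nrow(pairs)),
    mean_mm = (pairs$ai_mm + pairs$ref_mm) / 2,
    diff_mm = pairs$ref_mm - pairs$ai_mm,
    stringsAsFactors = FALSE
  )
  attr(pts, "bias") <- rep$bias
  attr(pts, "loa_low") <- rep$loa_low
  attr(pts, "loa_high") <- rep$loa_high
  pts
}

#' Concordance plot data
#'
#' Per-case `(reference, AI)` scatter points; perfect agreement lies on the
#' identity line.
#'
#' @param pairs A data.frame with columns `ai_mm`, `ref_mm`, optional `id`.
#' @return A data.frame of columns `id, ref_mm, ai_mm` (0 rows for empty
#'   input).
#' @export
concordance_points <- function(pairs) {
  if (is.data.frame(pairs) && nrow(pairs) == 0) {
    return(data.frame(id = character(0), ref_mm = numeric(0),
                      ai_mm = numeric(0), stringsAsFactors = FALSE))
  }
  pairs <- check_pairs(pairs)
  data.frame(
    id = if ("id" %in% names(pairs)) pairs$id else seq_len(nrow(pairs)),
    ref_mm = pairs$ref_mm,
    ai_mm = pairs$ai_mm,
    stringsAsFactors = FALSE
  )
}

#' Draw a Bland-Altman plot
#'
#' @param pairs A data.frame with columns `ai_mm`, `ref_mm`.
#' @param ... Passed to [graphics::plot()].
#' @return The plot data, invisibly.
#' @export
plot_bland_altman <- function(pairs, ...) {
  pts <- bland_altman_points(pairs)
  ylim <- range(c(pts$diff_mm, attr(pts, "loa_low"), attr(pts, "loa_high")))
  graphics::plot(pts$mean_mm, pts$diff_mm, col = "blue", pch = 16,
                 xlab = "Mean of AI and reference JSW (mm)",
                 ylab = "Reference - AI (mm)", ylim = ylim, ...)
  graphics::abline(h = attr(pts, "bias"), col = "red", lty = 2)
  graphics::abline(h = c(attr(pts, "loa_low"), attr(pts, "loa_high")),
                   col = "darkgreen", lty = 2)
  invisible(pts)
}

#' Draw a concordance plot
#'
#' @param pairs A data.frame with columns `ai_mm`, `ref_mm`.
#' @param ... Passed to [graphics::plot()].
#' @return The plot data, invisibly.
#' @export
plot_concordance <- function(pairs, ...) {
  pts <- concordance_points(pairs)
  lim <- range(c(pts$ref_mm, pts$ai_mm))
  graphics::plot(pts$ref_mm, pts$ai_mm, col = "blue", pch = 16,
                 xlab = "Reference JSW (mm)", ylab = "AI JSW (mm)",
                 xlim = lim, ylim = lim, ...)
  graphics::abline(a = 0, b = 1, col = "red", lty = 2)
  invisible(pts)
}
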