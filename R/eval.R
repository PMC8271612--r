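#' Mean absolute error between predicted and reference rates
#'
#' @param pred predicted rates, bpm.
#' @param truth reference rates, bpm; same length as `pred`.
#' @return MAE in bpm.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L)
    stop("'pred' and 'truth' must have equal length >= 1")
  mean(abs(pred - truth))
}

#' Bland-Altman agreement statistics
#'
#' Differences are `pred - truth`; bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * SD` with the sample (n-1 denominator)
#' standard deviation.
#'
#' @param pred predicted rates, bpm.
#' @param truth reference rates, bpm; same length, at least 2 pairs.
#' @return A list of class `agreement_stats`: `mae`, `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2L)
    stop("'pred' and 'truth' must have equal length >= 2")
  d <- pred - truth
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(mae = mean(abs(d)), bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 sd_diff = s, n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement (n = %d): MAE %.3f bpm, bias %.3f bpm, 95%% LoA [%.3f, %.3f] bpm\n",
    x$n, x$mae, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x an `agreement_stats` object; pass the paired values to draw the
#'   points.
#' @param pred,truth the paired rates used to compute `x`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.agreement_stats <- function(x, pred, truth, ...) {
  m <- (pred + truth) / 2
  d <- pred - truth
  graphics::plot(m, d, xlab = "mean of estimates (bpm)",
                 ylab = "difference pred - truth (bpm)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Run the estimator over a benchmark suite
#'
#' Generates each scene of a [generate_benchmark_suite()] sweep, runs the
#' full pipeline on it, and pairs the estimate with the ground truth.
#'
#' @param suite a `benchmark_suite`.
#' @param ... passed to [estimate_rr()] (window placement, `n_fft`,
#'   [rqi_params()], ...).
#' @return A list with `results` (data frame: `scene_id`, `rr_true_bpm`,
#'   `rr_pred_bpm`, `selected_roi`, `selected_ok`, `snr_db`) and `stats`
#'   (an `agreement_stats` over the scenes with a defined estimate).
#' @export
evaluate_suite <- function(suite, ...) {
  stopifnot(inherits(suite, "benchmark_suite"))
  n <- length(suite$configs)
  res <- suite$manifest
  res$rr_pred_bpm <- NA_real_
  res$selected_roi <- NA_integer_
  res$selected_ok <- FALSE
  for (i in seq_len(n)) {
    sc <- generate_scene(suite$configs[[i]])
    fit <- estimate_rr(sc$seq, sc$box, ...)
    w1 <- fit$windows[[1L]]
    res$rr_pred_bpm[i] <- w1$rr_bpm
    res$selected_roi[i] <- w1$selected_roi
    res$selected_ok[i] <- !is.na(w1$selected_roi) &&
      w1$selected_roi %in% sc$truth$breathing_cells
  }
  ok <- !is.na(res$rr_pred_bpm)
  stats <- if (sum(ok) >= 2L)
    bland_altman(res$rr_pred_bpm[ok], res$rr_true_bpm[ok]) else NULL
  list(results = res, stats = stats)
}
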