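#' Parameters of the Respiratory Quality Index
#'
#' @param a sigmoid shift in bpm: the RQI's logistic agreement term is
#'   `G(a - |RRt - RRf|)`, so `a` is the disagreement (in bpm) at which the
#'   term crosses 0.5. Default 5, reflecting that clean respiratory signals
#'   keep the two estimators within about 5 bpm of each other.
#' @param bf_threshold fraction of the breathing-band peak above which a BF
#'   bin counts as "large" (default 0.25).
#' @param hf_threshold fraction of the breathing-band peak above which an HF
#'   bin counts as "large" (default 0.10).
#' @return A list of class `rqi_params`.
#' @export
rqi_params <- function(a = 5, bf_threshold = 0.25, hf_threshold = 0.10) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            bf_threshold > 0, bf_threshold < 1,
            hf_threshold > 0, hf_threshold < 1)
  structure(list(a = a, bf_threshold = bf_threshold,
                 hf_threshold = hf_threshold),
            class = "rqi_params")
}

#' Frequency-domain respiratory rate
#'
#' The respiratory frequency is the grid frequency maximising the
#' periodogram over the breathing band (0.1-2 Hz, closed interval; ties
#' break to the lowest frequency), and `rr_f = 60 * f_peak` breaths/min.
#' Restricting the argmax to the band bounds the estimate to 6-120 bpm.
#'
#' @param spec a [power_spectrum()].
#' @param bands band edges from [band_edges()]; default derived from the
#'   spectrum's sampling rate.
#' @return A list with `f_peak` (Hz) and `rr_f` (bpm).
#' @export
rr_from_spectrum <- function(spec, bands = band_edges(spec$fps)) {
  stopifnot(inherits(spec, "power_spectrum"))
  bf <- which(band_masks(spec, bands)$bf)
  if (length(bf) == 0L)
    stop("window too short for band: no spectral bin inside the breathing band")
  pk <- bf[which.max(spec$values[bf])]  # which.max takes the first maximum
  list(f_peak = spec$freqs[pk], rr_f = 60 * spec$freqs[pk])
}

#' Zero-crossing times of a detrended window
#'
#' Finds the times where the signal changes sign, with sub-sample precision
#' by linear interpolation between the bracketing samples. Samples exactly
#' at zero are treated as belonging to the following sign, so a crossing
#' through a zero sample is located at that sample. In the default
#' convention both directions (+ to - and - to +) are returned in time
#' order; `direction = "pos-neg"` keeps only positive-to-negative
#' crossings.
#'
#' @param win an `analysis_window` (detrended) or numeric vector.
#' @param fps sampling rate, required when `win` is a bare vector.
#' @param direction `"both"` (default) or `"pos-neg"`.
#' @return Numeric vector of crossing times in seconds (possibly empty),
#'   relative to the window start.
#' @export
zero_crossings <- function(win, fps = NULL, direction = c("both", "pos-neg")) {
  direction <- match.arg(direction)
  if (inherits(win, "analysis_window")) {
    x <- win$samples; fps <- win$fps
  } else {
    x <- win
    if (is.null(fps)) stop("'fps' is required for a bare sample vector")
  }
  n <- length(x)
  if (n < 2L) return(numeric(0))
  s <- sign(x)
  # zeros adopt the following sign; trailing zeros adopt the preceding one
  for (i in (n - 1L):1L) if (s[i] == 0) s[i] <- s[i + 1L]
  for (i in 2L:n) if (s[i] == 0) s[i] <- s[i - 1L]
  if (all(s == 0)) return(numeric(0))
  idx <- which(s[-n] != s[-1L])
  if (direction == "pos-neg") idx <- idx[s[idx] > 0]
  if (length(idx) == 0L) return(numeric(0))
  a <- x[idx]; b <- x[idx + 1L]
  ((idx - 1L) + a / (a - b)) / fps
}

#' Time-domain respiratory rate from zero crossings
#'
#' Each consecutive crossing spacing yields one fundamental-frequency
#' estimate; the rate is 60 times their median (an even count averages the
#' two central values). In the default convention the crossings include both
#' sign-change directions, so each spacing is a half-period and
#' `f_i = 1/(2 * delta_i)`. The `"literal"` mode instead uses
#' `f_i = 2/delta_i`, intended for one-directional (positive-to-negative)
#' crossings; on such crossings each spacing is a full period, so this mode
#' reports twice the fundamental and exists for comparison only (see the
#' methods vignette). Fewer than 2 crossings leave the rate undefined
#' (`NA`), which downstream forces the region's RQI to 0.
#'
#' @param crossings crossing times in seconds, from [zero_crossings()].
#' @param mode `"half-period"` (default) or `"literal"`.
#' @return `rr_t` in bpm, or `NA_real_` when undefined.
#' @export
rr_from_time <- function(crossings, mode = c("half-period", "literal")) {
  mode <- match.arg(mode)
  if (length(crossings) < 2L) return(NA_real_)
  delta <- diff(crossings)
  f <- if (mode == "half-period") 1 / (2 * delta) else 2 / delta
  60 * stats::median(f)
}

#' Spectral-shape features of a region
#'
#' From the periodogram, computes the breathing-band peak `p_bf_max` and the
#' two power-weighted indicator fractions behind the Spectrum Index:
#' `f_bf`, the fraction of breathing-band power in bins at or above
#' `bf_threshold * p_bf_max`, and `f_hf`, the fraction of high-frequency
#' power in bins at or above `hf_threshold * p_bf_max` (the unbounded upper
#' integration limit is truncated at Nyquist). Integrals are realised as
#' Riemann sums over the spectrum's grid bins; threshold comparisons use
#' `>=` so boundary bins count deterministically.
#'
#' Degenerate cases: an all-zero spectrum (`p_bf_max = 0`) is maximally
#' noise-like, `f_bf = f_hf = 1`, flagged `degenerate`; zero total HF power
#' with a nonzero peak means no high-frequency noise at all, `f_hf = 0`.
#'
#' @param spec a [power_spectrum()].
#' @param bands band edges, see [band_edges()].
#' @param params an [rqi_params()] object (thresholds).
#' @return A list with `p_bf_max`, `f_bf`, `f_hf`, `degenerate`.
#' @export
spectrum_features <- function(spec, bands = band_edges(spec$fps),
                              params = rqi_params()) {
  stopifnot(inherits(spec, "power_spectrum"))
  m <- band_masks(spec, bands)
  if (!any(m$bf) || !any(m$hf))
    stop("spectrum grid has no bins in the BF or HF band")
  p_bf <- spec$values[m$bf]
  p_hf <- spec$values[m$hf]
  p_bf_max <- max(p_bf)
  if (p_bf_max == 0)
    return(list(p_bf_max = 0, f_bf = 1, f_hf = 1, degenerate = TRUE))
  f_bf <- sum(p_bf[p_bf >= params$bf_threshold * p_bf_max]) / sum(p_bf)
  hf_total <- sum(p_hf)
  f_hf <- if (hf_total == 0) 0 else
    sum(p_hf[p_hf >= params$hf_threshold * p_bf_max]) / hf_total
  list(p_bf_max = p_bf_max, f_bf = f_bf, f_hf = f_hf, degenerate = FALSE)
}

#' Spectrum Index
#'
#' `SI = 1 - (f_bf + f_hf)/2`, in `[0, 1]`. High SI means the breathing
#' band holds one dominant narrow peak (low `f_bf` mass spread) and the
#' high-frequency band holds no comparable power (low `f_hf`).
#'
#' @param f_bf,f_hf indicator fractions in `[0, 1]`, from
#'   [spectrum_features()].
#' @return SI in `[0, 1]`.
#' @export
spectrum_index <- function(f_bf, f_hf) {
  if (!is.numeric(f_bf) || !is.numeric(f_hf) ||
      any(f_bf < 0 | f_bf > 1) || any(f_hf < 0 | f_hf > 1))
    stop("'f_bf' and 'f_hf' must lie in [0, 1]")
  1 - (f_bf + f_hf) / 2
}

#' Logistic sigmoid
#'
#' `G(x) = 1 / (1 + exp(-x))`; monotone increasing, saturating to 0 and 1
#' without overflow.
#'
#' @param x numeric.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(x) stats::plogis(x)

#' Respiratory Quality Index
#'
#' `RQI = SI * G(a - |rr_t - rr_f|)`: the spectral-shape score damped by a
#' logistic penalty on disagreement between the time- and frequency-domain
#' rate estimates. Bounded in `[0, 1]`, and never exceeds SI. An undefined
#' `rr_t` (fewer than 2 zero crossings) yields RQI 0 — such a region carries
#' no usable periodicity.
#'
#' @param si Spectrum Index in `[0, 1]`.
#' @param rr_t time-domain rate in bpm, or `NA`.
#' @param rr_f frequency-domain rate in bpm.
#' @param params an [rqi_params()] object.
#' @return RQI in `[0, 1]`.
#' @export
rqi <- function(si, rr_t, rr_f, params = rqi_params()) {
  stopifnot(is.numeric(si), all(si >= 0 & si <= 1))
  if (length(rr_t) == 1L && is.na(rr_t)) return(0)
  si * sigmoid(params$a - abs(rr_t - rr_f))
}

#' Assess every grid region and select the respiratory one
#'
#' Runs the full per-region chain — rectangular window, linear detrend,
#' periodogram, dual-domain rate estimates, spectral features, SI, RQI — for
#' all grid cells of one analysis window, then selects the region with the
#' maximum RQI (ties break to the lowest index). The selected region's
#' frequency-domain rate is the subject's RR. When every region's RQI is 0
#' or degenerate, no respiratory region is found and the RR is `NA` (a
#' result, not an error).
#'
#' @param signals a `roi_signals` object from [extract_grid_signals()].
#' @param start,duration analysis window placement in seconds (default the
#'   first 15 s).
#' @param n_fft periodogram transform length (default 8192).
#' @param params an [rqi_params()] object.
#' @param bands band edges; default from the sampling rate.
#' @param crossing_mode zero-crossing convention, `"half-period"` (both
#'   sign changes, `f = 1/(2*delta)`) or `"literal"` (positive-to-negative
#'   only, `f = 2/delta`).
#' @return An object of class `rr_result`: `selected_roi` (0-based index or
#'   `NA`), `rr_bpm`, `assessments` (data frame with one row per region:
#'   `roi`, `rr_f`, `rr_t`, `p_bf_max`, `f_bf`, `f_hf`, `si`, `rqi`,
#'   `degenerate`, `selected`), and window metadata.
#' @export
assess_regions <- function(signals, start = 0, duration = 15, n_fft = 8192L,
                           params = rqi_params(), bands = NULL,
                           crossing_mode = c("half-period", "literal")) {
  stopifnot(inherits(signals, "roi_signals"))
  crossing_mode <- match.arg(crossing_mode)
  if (is.null(bands)) bands <- band_edges(signals$fps)
  n_cells <- signals$n_cells
  out <- data.frame(roi = seq_len(n_cells) - 1L, rr_f = NA_real_,
                    rr_t = NA_real_, p_bf_max = NA_real_, f_bf = NA_real_,
                    f_hf = NA_real_, si = NA_real_, rqi = NA_real_,
                    degenerate = FALSE, selected = FALSE)
  direction <- if (crossing_mode == "literal") "pos-neg" else "both"
  for (k in seq_len(n_cells)) {
    win <- detrend_linear(window_signal(trace_of(signals, k - 1L),
                                        start = start, duration = duration))
    spec <- periodogram(win, n_fft = max(n_fft, length(win$samples)))
    feats <- spectrum_features(spec, bands, params)
    out$p_bf_max[k] <- feats$p_bf_max
    out$f_bf[k] <- feats$f_bf
    out$f_hf[k] <- feats$f_hf
    out$si[k] <- spectrum_index(feats$f_bf, feats$f_hf)
    out$degenerate[k] <- feats$degenerate
    if (feats$degenerate) {
      out$rqi[k] <- 0
      next
    }
    out$rr_f[k] <- rr_from_spectrum(spec, bands)$rr_f
    cr <- zero_crossings(win, direction = direction)
    out$rr_t[k] <- rr_from_time(cr, mode = crossing_mode)
    out$rqi[k] <- rqi(out$si[k], out$rr_t[k], out$rr_f[k], params)
  }
  if (all(out$rqi <= 0)) {
    selected <- NA_integer_
    rr_bpm <- NA_real_
  } else {
    selected <- which.max(out$rqi)  # first maximum -> lowest index on ties
    rr_bpm <- out$rr_f[selected]
    out$selected[selected] <- TRUE
    selected <- selected - 1L       # 0-based roi index
  }
  structure(list(selected_roi = selected, rr_bpm = rr_bpm,
                 assessments = out,
                 window = list(start = start, duration = duration,
                               fps = signals$fps, n_fft = n_fft,
                               crossing_mode = crossing_mode),
                 params = params),
            class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  if (is.na(x$selected_roi)) {
    cat("rr_result: no respiratory region found\n")
  } else {
    cat(sprintf("rr_result: RR %.2f bpm from roi %d (RQI %.3f)\n",
                x$rr_bpm, x$selected_roi,
                max(x$assessments$rqi)))
  }
  invisible(x)
}

#' Write a per-region assessment table to CSV
#'
#' @param result an `rr_result` from [assess_regions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments_csv <- function(result, path) {
  stopifnot(inherits(result, "rr_result"))
  utils::write.csv(result$assessments, path, row.names = FALSE)
  invisible(path)
}
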