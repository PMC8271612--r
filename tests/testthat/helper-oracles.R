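# Independent oracles and small fixtures, deliberately naive.

# direct O(N^2) one-sided periodogram: P(f_k) = |sum_t x_t e^{-i 2 pi k t / n}|^2 / (N fs)
# with N the native sample count (x may be zero-padded to length n already)
dft_psd_oracle <- function(x, fs, native_n = length(x)) {
  n <- length(x)
  n_keep <- n %/% 2 + 1
  vals <- numeric(n_keep)
  for (k in seq_len(n_keep) - 1) {
    acc <- 0 + 0i
    for (t in seq_len(n) - 1)
      acc <- acc + x[t + 1] * exp(-2i * pi * k * t / n)
    vals[k + 1] <- Mod(acc)^2 / (native_n * fs)
  }
  list(freqs = (seq_len(n_keep) - 1) * fs / n, values = vals)
}

# per-bin enumeration of the indicator-sum features of a spectrum
features_oracle <- function(freqs, values, fps, bf_threshold = 0.25,
                            hf_threshold = 0.10) {
  bf <- which(freqs >= 0.1 & freqs <= 2.0)
  hf <- which(freqs > 2.0 & freqs <= fps / 2)
  p_bf_max <- max(values[bf])
  if (p_bf_max == 0) return(list(p_bf_max = 0, f_bf = 1, f_hf = 1))
  num_bf <- 0; den_bf <- 0
  for (i in bf) {
    den_bf <- den_bf + values[i]
    if (values[i] >= bf_threshold * p_bf_max) num_bf <- num_bf + values[i]
  }
  num_hf <- 0; den_hf <- 0
  for (i in hf) {
    den_hf <- den_hf + values[i]
    if (values[i] >= hf_threshold * p_bf_max) num_hf <- num_hf + values[i]
  }
  list(p_bf_max = p_bf_max, f_bf = num_bf / den_bf,
       f_hf = if (den_hf == 0) 0 else num_hf / den_hf)
}

# 15 s sinusoidal trace at frequency f_hz, default reference rate 8.6 fps
sine_trace <- function(f_hz, fps = 8.6, duration = 15, amp = 1, offset = 0,
                       phase = 0) {
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  signal_trace(offset + amp * sin(2 * pi * f_hz * t + phase), fps = fps)
}

# windowed + detrended spectrum of a trace, the standard per-region chain
chain_spectrum <- function(trace, n_fft = 8192) {
  periodogram(detrend_linear(window_signal(trace, 0, length(trace$values) /
                                             trace$fps)), n_fft = n_fft)
}

# cell k (0-based) of a roi_signals object as a standalone trace
trace_of_cell <- function(sig, k) {
  signal_trace(sig$values[, k + 1], fps = sig$fps, roi_index = k)
}

# tiny deterministic sequence: n frames of h x w filled from a function f(i,j,t)
tiny_sequence <- function(h, w, n, fps, fill) {
  frames <- lapply(seq_len(n), function(t)
    outer(seq_len(h), seq_len(w),
          function(i, j) mapply(fill, i, j, MoreArgs = list(t = t))))
  thermal_sequence(frames, fps = fps)
}
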