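#' Configure a synthetic thermal breathing scene
#'
#' Defines a face-sized region inside a thermal frame in which a chosen
#' subset of grid cells carries a quasi-sinusoidal temperature oscillation at
#' a known breathing frequency, on top of per-cell linear drift and
#' broadband pixel noise; all other cells carry drift and noise only. The
#' defaults emulate the reference measurement conditions: 15 s of frames at
#' 8.6 fps, a face box with 1:2 aspect split into the 4x6 grid, and
#' breathing confined to two mid-face cells. Breathing in the 15-30 bpm
#' instructed-rate range is the benchmark regime.
#'
#' @param frame_height,frame_width frame size in pixels.
#' @param face a [face_box()] placed inside the frame.
#' @param breathing_cells 0-based grid indices carrying the oscillation.
#' @param rr_true true breathing rate, bpm, in `[6, 120]`.
#' @param amplitude oscillation amplitude in sensor counts (> 0).
#' @param baseline mean intensity in counts.
#' @param drift_slope per-cell linear drift is drawn uniformly from
#'   `[-drift_slope, drift_slope]` counts/second.
#' @param noise_sigma per-pixel Gaussian noise SD in counts (>= 0).
#' @param distortion second-harmonic fraction in `[0, 1)`; exhalation and
#'   inhalation phases are not mirror images, so real traces are not pure
#'   sinusoids.
#' @param duration scene length in seconds.
#' @param fps frame rate, frames/second.
#' @param seed integer RNG seed; scenes are bit-reproducible under it.
#' @param n_cols,n_rows grid shape used to place the breathing cells.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(frame_height = 64L, frame_width = 64L,
                         face = face_box(12, 2, 40, 60),
                         breathing_cells = c(9L, 10L),
                         rr_true = 15, amplitude = 150, baseline = 30000,
                         drift_slope = 20, noise_sigma = 75,
                         distortion = 0.2, duration = 15, fps = 8.6,
                         seed = 1L, n_cols = 4L, n_rows = 6L) {
  cfg <- list(frame_height = as.integer(frame_height),
              frame_width = as.integer(frame_width), face = face,
              breathing_cells = as.integer(breathing_cells),
              rr_true = rr_true, amplitude = amplitude, baseline = baseline,
              drift_slope = drift_slope, noise_sigma = noise_sigma,
              distortion = distortion, duration = duration, fps = fps,
              seed = as.integer(seed), n_cols = as.integer(n_cols),
              n_rows = as.integer(n_rows))
  stopifnot(inherits(face, "face_box"),
            face$x + face$w <= cfg$frame_width,
            face$y + face$h <= cfg$frame_height,
            rr_true >= 6, rr_true <= 120,
            amplitude > 0 || length(breathing_cells) == 0L,
            noise_sigma >= 0, distortion >= 0, distortion < 1,
            duration > 0, fps > 0,
            all(cfg$breathing_cells >= 0),
            all(cfg$breathing_cells < cfg$n_cols * cfg$n_rows))
  structure(cfg, class = "scene_config")
}

# round half-up to uint16 with clipping; returns matrix + clip count
quantize_u16 <- function(m) {
  q <- floor(m + 0.5)
  clipped <- sum(q < 0 | q > 65535)
  q <- pmin(pmax(q, 0), 65535)
  storage.mode(q) <- "integer"
  list(frame = q, clipped = clipped)
}

#' Generate a synthetic thermal scene
#'
#' Breathing cells follow
#' `baseline + drift*t + amplitude*(sin(2*pi*f*t) + distortion*sin(4*pi*f*t))`
#' plus per-pixel Gaussian noise; non-breathing cells omit the oscillation;
#' pixels outside the face box carry baseline plus noise. Frames are
#' quantised to uint16 (round half-up, clipped to `[0, 65535]`, clips
#' counted). Deterministic under the config seed; the caller's RNG state is
#' left untouched.
#'
#' @param cfg a [scene_config()].
#' @return A list with `seq` (a [thermal_sequence()]), `box` (the face
#'   box) and `truth` (ground-truth record: `rr_true_bpm`, `f_true_hz`,
#'   `breathing_cells`, `snr_db`, `n_clipped`, `seed`). `snr_db` is the
#'   per-pixel oscillation SNR `10*log10(amplitude^2 / (2*noise_sigma^2))`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(cfg$seed)

  n <- as.integer(round(cfg$duration * cfg$fps))
  t <- (seq_len(n) - 1) / cfg$fps
  f <- cfg$rr_true / 60
  grid <- split_grid(cfg$face, cfg$n_cols, cfg$n_rows)
  n_cells <- length(grid$cells)
  slopes <- stats::runif(n_cells, -cfg$drift_slope, cfg$drift_slope)
  osc <- cfg$amplitude * (sin(2 * pi * f * t) +
                            cfg$distortion * sin(4 * pi * f * t))

  h <- cfg$frame_height; w <- cfg$frame_width
  scene <- array(cfg$baseline, dim = c(h, w, n))
  for (k in seq_len(n_cells)) {
    cell <- grid$cells[[k]]
    s_k <- slopes[k] * t
    if ((k - 1L) %in% cfg$breathing_cells) s_k <- s_k + osc
    rows <- (cell$y + 1L):(cell$y + cell$h)
    cols <- (cell$x + 1L):(cell$x + cell$w)
    scene[rows, cols, ] <- scene[rows, cols, ] +
      rep(s_k, each = length(rows) * length(cols))
  }
  if (cfg$noise_sigma > 0)
    scene <- scene + cfg$noise_sigma * array(stats::rnorm(h * w * n),
                                             dim = c(h, w, n))
  n_clipped <- 0L
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    q <- quantize_u16(scene[, , i])
    frames[[i]] <- q$frame
    n_clipped <- n_clipped + q$clipped
  }
  snr_db <- if (cfg$noise_sigma > 0)
    10 * log10(cfg$amplitude^2 / (2 * cfg$noise_sigma^2)) else Inf
  list(seq = thermal_sequence(frames, fps = cfg$fps),
       box = cfg$face,
       truth = list(rr_true_bpm = cfg$rr_true, f_true_hz = f,
                    breathing_cells = cfg$breathing_cells, snr_db = snr_db,
                    n_clipped = n_clipped, seed = cfg$seed))
}

# amplitude/sigma pairing for a requested per-pixel SNR (dB):
# snr_db = 10*log10(A^2 / (2*sigma^2))  =>  sigma = A / sqrt(2*10^(snr/10))
sigma_for_snr <- function(amplitude, snr_db) {
  amplitude / sqrt(2 * 10^(snr_db / 10))
}

#' Generate a factorial benchmark suite of scenes
#'
#' Sweeps breathing rate x per-pixel SNR x replicate, deriving each scene's
#' seed reproducibly from the master seed. Scene pixel data are not
#' materialised here: each entry is a [scene_config()] to be passed to
#' [generate_scene()] (scenes of this size are cheap to regenerate, and a
#' large suite held as frames would be needlessly heavy).
#'
#' @param rrs breathing rates in bpm (default the instructed rates 15, 20,
#'   25, 30).
#' @param snrs per-pixel SNRs in dB (default ~3 dB, the amplitude/noise
#'   pairing of [scene_config()] defaults).
#' @param n_reps replicates per combination.
#' @param seed master seed.
#' @param base_cfg template config; rate, noise and seed fields are
#'   overridden per scene.
#' @return A list of class `benchmark_suite` with `configs` (list of
#'   scene_configs) and `manifest` (data frame: `scene_id`, `rr_true_bpm`,
#'   `snr_db`, `seed`, `breathing_cells`).
#' @export
generate_benchmark_suite <- function(rrs = c(15, 20, 25, 30),
                                     snrs = round(10 * log10(2), 2),
                                     n_reps = 5L, seed = 1L,
                                     base_cfg = scene_config()) {
  stopifnot(n_reps >= 0L)
  combos <- expand.grid(rep = seq_len(n_reps), snr_db = snrs, rr = rrs,
                        KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  configs <- vector("list", n)
  manifest <- data.frame(scene_id = character(0), rr_true_bpm = numeric(0),
                         snr_db = numeric(0), seed = integer(0),
                         breathing_cells = character(0))
  if (n > 0L) {
    seeds <- (as.integer(seed) + 9973L * seq_len(n)) %% 2147483647L
    for (i in seq_len(n)) {
      cfg <- base_cfg
      cfg$rr_true <- combos$rr[i]
      cfg$noise_sigma <- sigma_for_snr(cfg$amplitude, combos$snr_db[i])
      cfg$seed <- seeds[i]
      configs[[i]] <- cfg
    }
    manifest <- data.frame(
      scene_id = sprintf("scene_%04d", seq_len(n)),
      rr_true_bpm = combos$rr,
      snr_db = combos$snr_db,
      seed = seeds,
      breathing_cells = paste(base_cfg$breathing_cells, collapse = ";"))
  }
  structure(list(configs = configs, manifest = manifest),
            class = "benchmark_suite")
}

#' @export
print.benchmark_suite <- function(x, ...) {
  cat(sprintf("benchmark_suite: %d scenes (%s bpm x %s dB)\n",
              nrow(x$manifest),
              paste(unique(x$manifest$rr_true_bpm), collapse = "/"),
              paste(unique(x$manifest$snr_db), collapse = "/")))
  invisible(x)
}
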