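#' Accelerometer synthesis / classification configuration
#'
#' Defaults for the 12 Hz neck-collar signal model and its windowed
#' features. Rumination carries a rhythmic chew component (~1.1 Hz, inside
#' the 0.5-2 Hz chew band) on top of the noise floor; feeding carries
#' higher-variance broadband content (2-6 Hz dominated); other behaviour is
#' the noise floor alone. `snr` scales both activity signatures relative to
#' the floor; 1 is the default operating point.
#'
#' @param fs sampling rate, Hz.
#' @param window_s feature window length, seconds.
#' @param bands named list of frequency bands (Hz, `(lo, hi]`); the first
#'   band is treated as the chew band, the last as the broadband reference.
#' @param chew_freq chew-cycle frequency, Hz.
#' @param rum_amp chew-component amplitude at `snr = 1` (g).
#' @param feed_sd extra broadband SD during feeding at `snr = 1` (g).
#' @param base_sd noise-floor SD (g).
#' @param snr signal-to-noise scaling of the activity signatures.
#' @return list of class `accel_config`.
#' @export
accel_config <- function(fs = 12, window_s = 30,
                         bands = list(chew = c(0.5, 2), broad = c(2, 6)),
                         chew_freq = 1.1, rum_amp = 0.5, feed_sd = 0.5,
                         base_sd = 0.15, snr = 1) {
  stopifnot(fs > 0, window_s * fs >= 8, snr >= 0, base_sd > 0)
  structure(list(fs = fs, window_s = window_s, bands = bands,
                 chew_freq = chew_freq, rum_amp = rum_amp,
                 feed_sd = feed_sd, base_sd = base_sd, snr = snr),
            class = "accel_config")
}

#' Synthesize a tri-axial accelerometer trace from an activity schedule
#'
#' @param schedule data.frame with `start_s`, `end_s`, `activity` in
#'   `{"rumination", "feeding", "other"}`; intervals must not overlap.
#'   Time not covered by any interval behaves as `"other"`.
#' @param config an [accel_config()].
#' @param seed optional RNG seed (fixed seed gives a byte-identical trace).
#' @param duration_s trace length; default the schedule's last end time.
#' @param cow_id,t0 carried into the signal object.
#' @return list of class `accel_signal`: `cow_id`, `fs`, `t0`, `samples`
#'   (n x 3 matrix).
#' @export
synthesize_accel <- function(schedule, config = accel_config(), seed = NULL,
                             duration_s = NULL, cow_id = NA, t0 = 0) {
  if (nrow(schedule)) {
    sc <- schedule[order(schedule$start_s), , drop = FALSE]
    if (any(sc$end_s <= sc$start_s)) stop("schedule has empty/negative intervals")
    if (nrow(sc) > 1 && any(sc$start_s[-1] < sc$end_s[-nrow(sc)] - 1e-9))
      stop("schedule intervals overlap")
    if (!all(sc$activity %in% c("rumination", "feeding", "other")))
      stop("activity must be rumination/feeding/other")
  } else sc <- schedule
  if (is.null(duration_s))
    duration_s <- if (nrow(sc)) max(sc$end_s) else stop("empty schedule needs duration_s")
  fs <- config$fs
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * 3, 0, config$base_sd), ncol = 3)
    x[, 3] <- x[, 3] + 1                      # gravity on the vertical axis
    tt <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(sc))) {
      idx <- which(tt >= sc$start_s[i] & tt < sc$end_s[i])
      if (!length(idx)) next
      if (sc$activity[i] == "rumination") {
        phase <- stats::runif(1, 0, 2 * pi)
        chew <- config$snr * config$rum_amp *
          sin(2 * pi * config$chew_freq * tt[idx] + phase)
        chew <- chew + 0.3 * config$snr * config$rum_amp *
          sin(2 * pi * 2 * config$chew_freq * tt[idx] + 2 * phase)
        # mostly along the gravity axis so the chew rhythm survives in the
        # resultant magnitude linearly (off-axis motion only enters squared)
        x[idx, 3] <- x[idx, 3] + 0.8 * chew
        x[idx, 2] <- x[idx, 2] + 0.5 * chew
      } else if (sc$activity[i] == "feeding") {
        x[idx, 2:3] <- x[idx, 2:3] +
          stats::rnorm(2 * length(idx), 0, config$snr * config$feed_sd)
      }
    }
    structure(list(cow_id = cow_id, fs = fs, t0 = t0, samples = x),
              class = "accel_signal")
  })
}

#' Windowed variance and Fourier band-power features
#'
#' Tiles the 3-axis resultant magnitude into non-overlapping windows and
#' computes, per window, the sample variance (signal-energy proxy) and the
#' power in each configured frequency band from the discrete Fourier
#' transform, normalised by window length (`sum |X_k|^2 / N^2` over band
#' bins, both spectrum halves, DC excluded). Band powers over a full
#' partition of (0, Nyquist] sum to the (population) window variance.
#'
#' @param signal an [synthesize_accel()] object.
#' @param window_s window length in seconds; `window_s * fs` must be >= 8
#'   samples and no longer than the signal.
#' @param bands named list of `(lo, hi]` bands in Hz.
#' @return data.frame of class `accel_features`: `window_start`,
#'   `variance`, one column per band; attributes `fs`, `window_s`, `bands`.
#' @export
window_features <- function(signal, window_s = 30,
                            bands = list(chew = c(0.5, 2), broad = c(2, 6))) {
  fs <- signal$fs
  N <- round(window_s * fs)
  if (N < 8) stop("window must contain at least 8 samples")
  res <- sqrt(rowSums(signal$samples^2))
  K <- floor(length(res) / N)
  if (K < 1) stop("window longer than signal")
  M <- matrix(res[seq_len(K * N)], nrow = N)
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  v <- colSums(Mc^2) / (N - 1)
  P <- Mod(stats::mvfft(Mc))^2 / N^2              # rows = bins 0..N-1
  freq <- (seq_len(N) - 1) * fs / N
  half <- 2:(floor(N / 2) + 1)                    # bins 1..N/2
  out <- data.frame(window_start = signal$t0 + (seq_len(K) - 1) * window_s,
                    variance = v)
  for (bn in names(bands)) {
    lo <- bands[[bn]][1]; hi <- bands[[bn]][2]
    ks <- half[freq[half] > lo & freq[half] <= hi]
    bp <- numeric(K)
    for (k in ks) {
      bp <- bp + P[k, ]
      mirror <- N - (k - 1) + 1                   # conjugate bin, 1-based
      if (mirror != k && mirror <= N) bp <- bp + P[mirror, ]
    }
    out[[bn]] <- bp
  }
  structure(out, fs = fs, window_s = window_s, bands = bands,
            class = c("accel_features", "data.frame"))
}

#' Write / read a signal as a plain-text array with a JSON sidecar
#'
#' @param signal an `accel_signal`.
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return the prefix (write) or an `accel_signal` (read).
#' @export
write_signal <- function(signal, prefix) {
  utils::write.csv(as.data.frame(signal$samples), paste0(prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(cow_id = signal$cow_id, fs = signal$fs,
                            t0 = signal$t0),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_signal
#' @export
read_signal <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  samples <- as.matrix(utils::read.csv(paste0(prefix, ".csv")))
  dimnames(samples) <- NULL
  structure(list(cow_id = meta$cow_id, fs = meta$fs, t0 = meta$t0,
                 samples = samples), class = "accel_signal")
}
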