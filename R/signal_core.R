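# EMG containers, sliding-window segmentation, and the Hudgins + AR feature set.

#' Default electrode montage
#'
#' Twelve surface-EMG sites: the three deltoid heads, upper trapezius,
#' pectoralis major, supraspinatus, infraspinatus, biceps brachii, and two
#' pairs each over the wrist/finger extensors and flexors.
#'
#' @return Character vector of 12 channel names.
#' @export
default_channel_names <- function() {
  c("ant_delt", "mid_delt", "post_delt", "up_trap",
    "pect_major", "supraspin", "infraspin", "biceps",
    "wrist_ext1", "wrist_ext2", "wrist_flex1", "wrist_flex2")
}

#' Multi-channel surface EMG recording
#'
#' @param samples Numeric matrix, `n_samples x n_channels`; no missing values.
#' @param fs Sampling rate in Hz (> 0); the study hardware samples at 1 kHz.
#' @param channel_names Ordered channel labels; defaults to
#'   [default_channel_names()] when 12 channels are supplied.
#' @param label Movement class or condition tag.
#' @param posture Horizontal-adduction angle tag in degrees.
#' @param trial_id,session_id Identifiers.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_names = NULL, label = NA_character_,
                          posture = NA_real_, trial_id = NA_character_,
                          session_id = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop("EMG samples must be a numeric matrix with no missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names)) {
    channel_names <- if (ncol(samples) == 12L) default_channel_names()
                     else sprintf("ch%02d", seq_len(ncol(samples)))
  }
  if (length(channel_names) != ncol(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", ncol(samples), ")")
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 label = label, posture = posture, trial_id = trial_id,
                 session_id = session_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("emg_recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  label: %s  posture: %s  trial: %s\n",
              x$label, format(x$posture), x$trial_id))
  invisible(x)
}

#' Segment a recording into overlapping analysis windows
#'
#' Windows are causal: a window starting at sample `s` covers the `window_ms`
#' of signal preceding its decision time `s + window_ms`. The default 200 ms
#' windows with 25 ms steps overlap by 175 ms.
#'
#' @param recording An [emg_recording()].
#' @param window_ms Window length in ms.
#' @param step_ms Step between consecutive windows in ms.
#' @return List of windows, each `list(samples, start_ms)`; attribute
#'   `overlap_ms` records the window overlap. A recording shorter than one
#'   window yields an empty list with a warning.
#' @export
segment_windows <- function(recording, window_ms = 200, step_ms = 25) {
  stopifnot(inherits(recording, "emg_recording"), window_ms > 0,
            step_ms > 0, window_ms > step_ms)
  w <- round(window_ms * recording$fs / 1000)
  s <- round(step_ms * recording$fs / 1000)
  n <- nrow(recording$samples)
  if (n < w) {
    warning("recording (", n, " samples) is shorter than one window (",
            w, " samples); returning no windows")
    return(structure(list(), overlap_ms = window_ms - step_ms))
  }
  starts <- seq(1L, n - w + 1L, by = s)
  out <- lapply(starts, function(i)
    list(samples = recording$samples[i:(i + w - 1L), , drop = FALSE],
         start_ms = (i - 1L) * 1000 / recording$fs))
  structure(out, overlap_ms = window_ms - step_ms)
}

#' Mean absolute value of a signal window
#' @param x Numeric vector (non-empty).
#' @return Arithmetic mean of `abs(x)`.
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop("mav: empty window")
  mean(abs(x))
}

#' Amplitude-gated zero-crossing count
#'
#' Counts consecutive-sample pairs with strictly opposite signs where both
#' samples exceed the amplitude threshold (Hudgins noise gate).
#'
#' @param x Numeric vector.
#' @param threshold Non-negative amplitude gate.
#' @return Integer count.
#' @export
zero_crossings <- function(x, threshold = 0) {
  stopifnot(threshold >= 0)
  n <- length(x)
  if (n < 2L) return(0L)
  a <- x[-n]; b <- x[-1]
  sum(a * b < 0 & abs(a) >= threshold & abs(b) >= threshold)
}

#' Amplitude-gated slope-sign-change count
#'
#' Counts interior samples `i` where
#' `(x[i] - x[i-1]) * (x[i] - x[i+1]) >= max(threshold, tiny)`, i.e. local
#' slope reversals exceeding the gate.
#'
#' @inheritParams zero_crossings
#' @return Integer count; a window shorter than 3 samples gives 0 with a warning.
#' @export
slope_sign_changes <- function(x, threshold = 0) {
  stopifnot(threshold >= 0)
  n <- length(x)
  if (n < 3L) {
    warning("slope_sign_changes: window shorter than 3 samples")
    return(0L)
  }
  d1 <- x[2:(n - 1L)] - x[1:(n - 2L)]
  d2 <- x[2:(n - 1L)] - x[3:n]
  sum(d1 * d2 >= max(threshold, .Machine$double.eps))
}

#' Waveform length of a signal window
#' @param x Numeric vector.
#' @return Sum of absolute successive differences; a window shorter than 2
#'   samples gives 0 with a warning.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) {
    warning("waveform_length: window shorter than 2 samples")
    return(0)
  }
  sum(abs(diff(x)))
}

#' Autoregressive coefficients of a signal window (Burg method)
#'
#' Fits `x_t = a_1 x_(t-1) + ... + a_p x_(t-p) + e_t` by Burg's method, which
#' is stable on short (200-sample) EMG windows. Degenerate windows
#' (constant/zero, or a failed fit) fall back to all-zero coefficients with a
#' warning rather than raising, so the real-time loop never aborts.
#'
#' @param x Numeric vector, length > `order`.
#' @param order Model order (default 6).
#' @return Numeric vector of `order` coefficients.
#' @export
ar_coefficients <- function(x, order = 6L) {
  if (length(x) <= order)
    stop("window length (", length(x), ") must exceed AR order (", order, ")")
  if (stats::sd(x) == 0) {
    warning("ar_coefficients: constant window, returning zero coefficients")
    return(numeric(order))
  }
  a <- tryCatch(
    stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)$ar,
    error = function(e) NULL)
  if (is.null(a) || length(a) != order || any(!is.finite(a))) {
    warning("ar_coefficients: Burg fit degenerate, returning zero coefficients")
    return(numeric(order))
  }
  as.numeric(a)
}

#' Per-channel feature names in extraction order
#' @param channel_names Channel labels.
#' @param order AR model order.
#' @return Character vector, channel-major:
#'   `ch1_mav, ch1_zc, ch1_ssc, ch1_wl, ch1_ar1..ar6, ch2_mav, ...`.
#' @export
feature_names <- function(channel_names, order = 6L) {
  per <- c("mav", "zc", "ssc", "wl", paste0("ar", seq_len(order)))
  as.vector(t(outer(channel_names, per, paste, sep = "_")))
}

#' Extract the 10-feature-per-channel descriptor of an analysis window
#'
#' For each channel: mean absolute value, zero crossings, slope sign changes,
#' waveform length, and 6th-order AR coefficients, in fixed channel-major
#' order. A 12-channel window yields 120 features.
#'
#' @param window Numeric matrix (`samples x channels`) or a window from
#'   [segment_windows()].
#' @param thresholds Per-channel amplitude gate for ZC/SSC (scalar recycled);
#'   default 0.
#' @param order AR model order.
#' @return Named numeric vector of length `10 * n_channels`, with the
#'   per-channel MAV sub-vector in attribute `"mav"`.
#' @export
extract_features <- function(window, thresholds = 0, order = 6L) {
  m <- if (is.list(window)) window$samples else window
  m <- as.matrix(m)
  nch <- ncol(m)
  thresholds <- rep_len(thresholds, nch)
  ch <- colnames(m)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(nch))
  vals <- lapply(seq_len(nch), function(j) {
    x <- m[, j]
    c(mav(x), zero_crossings(x, thresholds[j]),
      slope_sign_changes(x, thresholds[j]), waveform_length(x),
      ar_coefficients(x, order))
  })
  out <- unlist(vals, use.names = FALSE)
  names(out) <- feature_names(ch, order)
  attr(out, "mav") <- stats::setNames(
    vapply(vals, `[`, numeric(1), 1L), ch)
  out
}

#' Windowed feature extraction over a whole recording
#'
#' @param recording An [emg_recording()] (already conditioned).
#' @inheritParams segment_windows
#' @inheritParams extract_features
#' @return List with `features` (matrix `n_windows x 10*n_channels`),
#'   `mav` (matrix `n_windows x n_channels`), and `start_ms`.
#' @export
extract_features_recording <- function(recording, window_ms = 200, step_ms = 25,
                                       thresholds = 0, order = 6L) {
  wins <- segment_windows(recording, window_ms, step_ms)
  nch <- ncol(recording$samples)
  feats <- matrix(NA_real_, length(wins), 10L * nch)
  mavs <- matrix(NA_real_, length(wins), nch)
  for (i in seq_along(wins)) {
    fv <- extract_features(wins[[i]], thresholds, order)
    feats[i, ] <- fv
    mavs[i, ] <- attr(fv, "mav")
  }
  if (length(wins)) {
    colnames(feats) <- feature_names(recording$channel_names, order)
    colnames(mavs) <- recording$channel_names
  }
  list(features = feats, mav = mavs,
       start_ms = vapply(wins, `[[`, numeric(1), "start_ms"))
}
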