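# IIR filter design and application for EMG conditioning.
#
# No DSP package ships with the target environment, so the digital Butterworth
# design (analog prototype -> band transform -> bilinear transform) is done
# here directly. Coefficients agree with standard references to full double
# precision.

# polynomial coefficients (descending powers) from a set of complex roots
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * ri)
  p
}

#' Digital Butterworth band-pass / band-stop design
#'
#' Designs a digital Butterworth filter of final order `2 * n` via the analog
#' low-pass prototype, low-pass-to-band transform and bilinear transform.
#'
#' @param n Prototype (half) order; the returned transfer function has order
#'   `2 * n`. `n = 2` gives the 4th-order stages used for EMG conditioning.
#' @param wc_hz Two corner frequencies in Hz, increasing.
#' @param fs Sampling rate in Hz.
#' @param type `"bandpass"` or `"bandstop"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (descending powers of z, `a[1] = 1`).
#' @export
butter_design <- function(n, wc_hz, fs, type = c("bandpass", "bandstop")) {
  type <- match.arg(type)
  stopifnot(length(wc_hz) == 2L, wc_hz[1] < wc_hz[2], fs > 0)
  if (wc_hz[2] >= fs / 2)
    stop("upper corner frequency (", wc_hz[2], " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  wn <- wc_hz / (fs / 2)
  fs2 <- 2                       # internal bilinear sampling rate
  warped <- 2 * fs2 * tan(pi * wn / 2)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # left-half-plane prototype poles
  z <- complex(0)
  gain <- 1
  bw <- warped[2] - warped[1]
  w0 <- sqrt(warped[1] * warped[2])
  if (type == "bandpass") {
    ps <- p * bw / 2
    p <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
    z <- rep(0 + 0i, n)
    gain <- gain * bw^n
  } else {
    pinv <- (bw / 2) / p
    p <- c(pinv + sqrt(pinv^2 - w0^2), pinv - sqrt(pinv^2 - w0^2))
    z <- rep(c(1i * w0, -1i * w0), n)
    gain <- gain * Re(prod(-z) / prod(-p))
  }
  zd <- (2 * fs2 + z) / (2 * fs2 - z)
  pd <- (2 * fs2 + p) / (2 * fs2 - p)
  gd <- gain * Re(prod(2 * fs2 - z) / prod(2 * fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(b = Re(.poly_from_roots(zd)) * gd, a = Re(.poly_from_roots(pd)))
}

# single-pass (causal) direct-form IIR filter, zero initial state
.iir_filter <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), filter = b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, filter = -a[-1], method = "recursive"))
  v
}

# zero-phase forward-backward filtering with odd-reflection edge padding
.filtfilt <- function(x, b, a) {
  n <- length(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- .iir_filter(c(pre, x, post), b, a)
  y <- rev(.iir_filter(rev(y), b, a))
  y[pad + seq_len(n)]
}

# cached per-fs conditioning cascade: 20-350 Hz pass, 50-70 Hz stop
.filter_cache <- new.env(parent = emptyenv())

#' EMG conditioning filter cascade for a sampling rate
#'
#' 4th-order Butterworth band-pass 20--350 Hz cascaded with a 4th-order
#' Butterworth band-stop 50--70 Hz (mains avoidance).
#'
#' @param fs Sampling rate in Hz; must be at least 700 so the 350 Hz band edge
#'   stays below Nyquist.
#' @return List of two `list(b, a)` stages, `bp` then `bs`.
#' @export
emg_filters <- function(fs) {
  if (fs < 700)
    stop("sampling rate ", fs, " Hz is too low: the 350 Hz passband edge ",
         "requires fs >= 700 Hz")
  key <- format(fs, digits = 12)
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- list(
      bp = butter_design(2, c(20, 350), fs, "bandpass"),
      bs = butter_design(2, c(50, 70), fs, "bandstop"))
  }
  .filter_cache[[key]]
}

# apply the conditioning cascade to one numeric vector
.condition_channel <- function(x, filt, mode) {
  if (mode == "offline") {
    x <- .filtfilt(x, filt$bp$b, filt$bp$a)
    .filtfilt(x, filt$bs$b, filt$bs$a)
  } else {
    x <- .iir_filter(x, filt$bp$b, filt$bp$a)
    .iir_filter(x, filt$bs$b, filt$bs$a)
  }
}

#' Condition a multi-channel EMG recording
#'
#' Band-pass filters each channel to 20--350 Hz with a 50--70 Hz stop band.
#' Offline mode applies the cascade forward and backward (zero phase); causal
#' mode applies a single forward pass as in the real-time loop, introducing
#' only the filter group delay.
#'
#' @param recording An [emg_recording()].
#' @param mode `"offline"` (zero-phase) or `"causal"` (single pass).
#' @return The recording with filtered samples; metadata unchanged.
#' @export
condition_signal <- function(recording, mode = c("offline", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "emg_recording"))
  filt <- emg_filters(recording$fs)
  out <- recording
  out$samples <- apply(recording$samples, 2, .condition_channel,
                       filt = filt, mode = mode)
  dimnames(out$samples) <- dimnames(recording$samples)
  out$conditioned <- mode
  out
}
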