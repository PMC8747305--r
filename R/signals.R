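# Signal conditioning: Butterworth filtering, the EMG linear-envelope chain,
# MVC normalization, anti-aliased resampling to the 50 Hz analysis rate, and
# cross-correlation delay estimation for exoskeleton synchronization.

#' Construct a filter specification
#'
#' @param kind One of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param order Filter order (of the underlying one-pass Butterworth
#'   design).
#' @param cutoff_hz One cutoff frequency (low/highpass) or two (bandpass),
#'   strictly inside (0, fs/2).
#' @param zero_phase Apply forward-backward (zero-phase) filtering; this
#'   doubles the effective order.  Offline processing default.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass"),
                        order = 2L, cutoff_hz, zero_phase = TRUE) {
  kind <- match.arg(kind)
  stopifnot(order >= 1L, all(cutoff_hz > 0))
  if (kind == "bandpass" && length(cutoff_hz) != 2L)
    stop("bandpass needs two cutoff frequencies")
  if (kind != "bandpass" && length(cutoff_hz) != 1L)
    stop(kind, " needs one cutoff frequency")
  structure(list(kind = kind, order = as.integer(order),
                 cutoff_hz = sort(cutoff_hz), zero_phase = zero_phase),
            class = "filter_spec")
}

#' Apply a Butterworth filter
#'
#' Designs a Butterworth filter from `spec` and applies it to `x`.
#' Zero-phase (forward-backward) application is the default, preserving
#' signal timing at the cost of doubling the effective order.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
butterworth <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (any(spec$cutoff_hz >= fs / 2))
    stop("cutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  if (length(x) <= 3L * spec$order)
    stop("signal too short for filter order ", spec$order)
  w <- spec$cutoff_hz / (fs / 2)
  type <- switch(spec$kind, lowpass = "low", highpass = "high",
                 bandpass = "pass")
  bf <- signal::butter(spec$order, w, type = type)
  if (spec$zero_phase) {
    filtfilt_ss(bf$b, bf$a, x)
  } else {
    filter_ss(bf$b, bf$a, x)
  }
}

# One-pass IIR filtering started from the steady state for the signal's
# first value, so constant inputs pass through exactly and startup
# transients are minimal.
filter_ss <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(dc * x[1], length(a) - 1L)))
}

# Zero-phase (forward-backward) filtering with odd-symmetric end padding
# and steady-state initial conditions, so edges carry no spurious
# transients (the usual offline filtfilt convention).
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  nf <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  pre <- 2 * x[1] - x[seq(nf + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - nf)]
  xx <- c(pre, x, post)
  y <- filter_ss(b, a, xx)
  y <- rev(filter_ss(b, a, rev(y)))
  y[(nf + 1L):(nf + n)]
}

#' Compute the EMG linear envelope
#'
#' Conditioning chain for raw surface EMG sampled at 2000 Hz: band-pass
#' 10-400 Hz (2nd order Butterworth), high-pass 30 Hz to suppress ECG
#' artifacts, full-wave rectification, and low-pass at 2.5 Hz; the result is
#' clipped at zero to remove small negative filter ripple.  An optional
#' mains notch is available for recorded data.
#'
#' @param raw Raw EMG samples.
#' @param fs Sampling frequency in Hz (2000 for the standard chain).
#' @param notch_hz Optional mains frequency to notch out (e.g. 50); `NULL`
#'   (default) disables the notch.
#' @return Non-negative envelope at the input rate.
#' @export
emg_envelope <- function(raw, fs = 2000, notch_hz = NULL) {
  if (length(raw) < fs)
    stop("signal shorter than filter warm-up (< 1 s)")
  x <- butterworth(raw, fs, filter_spec("bandpass", 2L, c(10, 400)))
  if (!is.null(notch_hz)) {
    x <- x - butterworth(x, fs, filter_spec("bandpass", 2L,
                                            notch_hz + c(-1, 1)))
  }
  x <- butterworth(x, fs, filter_spec("highpass", 2L, 30))
  x <- abs(x)
  env <- butterworth(x, fs, filter_spec("lowpass", 2L, 2.5))
  pmax(env, 0)
}

#' Normalize an envelope to its maximal voluntary contraction
#'
#' @param envelope EMG envelope.
#' @param mvc_peak Positive per-channel MVC envelope peak.
#' @return `envelope / mvc_peak`.
#' @export
normalize_mvc <- function(envelope, mvc_peak) {
  if (!is.numeric(mvc_peak) || length(mvc_peak) != 1L || mvc_peak <= 0)
    stop("mvc_peak must be a single positive number")
  envelope / mvc_peak
}

#' Resample a signal to 50 Hz
#'
#' Anti-aliased integer decimation: a zero-phase 4th-order Butterworth
#' low-pass at 20 Hz removes content above the target Nyquist band, then
#' every k-th sample is kept.  Zero-phase filtering leaves no net group
#' delay, so resampled channels stay synchronized with the 50 Hz kinematics.
#'
#' @param x Input signal.
#' @param fs_in Input sampling frequency; must be an integer multiple of 50
#'   (e.g. 200 for force plates, 2000 for EMG).
#' @return Signal at 50 Hz.
#' @export
resample_to_50hz <- function(x, fs_in) {
  k <- fs_in / TRIAL_FS
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("fs_in must be an integer multiple of 50 Hz")
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  y <- butterworth(x, fs_in, filter_spec("lowpass", 4L, 20))
  y[seq(1L, length(y), by = k)]
}

#' Estimate the delay between two signals by cross-correlation
#'
#' Returns the integer lag (in samples) that maximizes the normalized
#' cross-correlation between the two demeaned signals.  A positive lag
#' means `sig_b` lags (is delayed with respect to) `sig_a`.  Used to
#' synchronize exoskeleton torque logs with marker-derived trunk kinematics
#' via their shared inclination-angle content.
#'
#' @param sig_a,sig_b Signals at a common sampling rate.
#' @param max_lag Maximum |lag| searched, in samples (default half the
#'   signal length).
#' @return Integer lag in samples.
#' @export
estimate_delay_xcorr <- function(sig_a, sig_b,
                                 max_lag = floor(length(sig_a) / 2)) {
  if (length(sig_a) != length(sig_b))
    stop("signals must have equal length")
  a <- sig_a - mean(sig_a)
  b <- sig_b - mean(sig_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate input: constant signal has no cross-correlation peak")
  n <- length(a)
  lags <- seq.int(-max_lag, max_lag)
  # Pearson correlation over the overlapping window at each lag; the
  # biased FFT estimator would favour lag 0 on ramp-dominated signals.
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      bb <- b[(1 + k):n]; aa <- a[1:(n - k)]
    } else {
      bb <- b[1:(n + k)]; aa <- a[(1 - k):n]
    }
    if (stats::sd(bb) == 0 || stats::sd(aa) == 0) return(-1)
    stats::cor(bb, aa)
  }, numeric(1))
  as.integer(lags[which.max(r)])
}
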