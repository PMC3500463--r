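#' Filter cascade specification
#'
#' The analysis cascade: 0.5 Hz high-pass, 30 Hz low-pass and a 50 Hz
#' notch, all recursive (IIR) filters of limited kernel length applied
#' zero-phase by mirror filtering. The acquisition-stage 100 Hz low-pass
#' is carried as metadata only. The high-pass is a 2nd-order Butterworth
#' (its normalized cutoff at 1048 Hz is ~1e-3, where higher orders are
#' numerically fragile in transfer-function form); the low-pass is a
#' 4th-order Butterworth and the notch a 2nd-order biquad.
#'
#' @param highpass,lowpass,notch cutoff / center frequencies in Hz; any of
#'   them may be `NULL` to drop that stage.
#' @param hp_order,lp_order Butterworth orders.
#' @param notch_bw notch -3 dB bandwidth in Hz.
#' @param acq_lowpass acquisition anti-alias low-pass (metadata).
#' @return object of class `fg_filter_spec`.
#' @export
filter_spec <- function(highpass = 0.5, lowpass = 30, notch = 50,
                        hp_order = 2, lp_order = 4, notch_bw = 2,
                        acq_lowpass = 100) {
  if (!is.null(highpass) && !is.null(lowpass)) {
    fg_assert(highpass > 0 && highpass < lowpass, "input",
              "need 0 < highpass < lowpass")
  }
  structure(list(highpass = highpass, lowpass = lowpass, notch = notch,
                 hp_order = hp_order, lp_order = lp_order,
                 notch_bw = notch_bw, acq_lowpass = acq_lowpass),
            class = "fg_filter_spec")
}

notch_biquad <- function(f0, fs, bw) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - pi * bw / fs # pole radius for the requested bandwidth
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  k <- sum(a) / sum(b) # unit gain at DC
  list(b = k * b, a = a)
}

filter_cascade <- function(spec, fs) {
  nyq <- fs / 2
  stages <- list()
  if (!is.null(spec$highpass)) {
    bt <- signal::butter(spec$hp_order, spec$highpass / nyq, type = "high")
    stages <- c(stages, list(list(b = bt$b, a = bt$a)))
  }
  if (!is.null(spec$lowpass)) {
    fg_assert(spec$lowpass < nyq, "input",
              "lowpass %.1f Hz not below Nyquist %.1f Hz", spec$lowpass, nyq)
    bt <- signal::butter(spec$lp_order, spec$lowpass / nyq, type = "low")
    stages <- c(stages, list(list(b = bt$b, a = bt$a)))
  }
  if (!is.null(spec$notch)) {
    fg_assert(spec$notch < nyq, "input", "notch above Nyquist")
    stages <- c(stages, list(notch_biquad(spec$notch, fs, spec$notch_bw)))
  }
  stages
}

# shortest stage cutoff period, in samples: used as the settling scale
settle_samples <- function(spec, fs) {
  f_min <- min(c(spec$highpass, spec$lowpass, spec$notch), na.rm = TRUE)
  ceiling(fs / f_min)
}

zero_phase_1d <- function(x, stages, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  # odd (point-mirrored) reflection padding at both ends
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- c(left, x, right)
  for (st in stages) {
    y <- signal::filter(st$b, st$a, y)
    y <- rev(signal::filter(st$b, st$a, rev(y)))
  }
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase mirror filtering
#'
#' Filters the signal and its time-mirrored extension and combines the
#' forward- and backward-filtered passes (forward-backward recursive
#' filtering over an odd-reflection padded signal), giving zero phase
#' shift and suppressing the ringing a causal recursive filter produces
#' at sharp discontinuities such as excision-window boundaries.
#'
#' @param x numeric vector, or matrix channels x samples (filtered
#'   row-wise).
#' @param fs sampling rate in Hz.
#' @param spec [filter_spec()].
#' @param pad_sec reflection padding per end in seconds.
#' @return filtered object of the same shape.
#' @export
mirror_filter <- function(x, fs, spec = filter_spec(), pad_sec = 2) {
  stages <- filter_cascade(spec, fs)
  if (length(stages) == 0) return(x)
  st <- settle_samples(spec, fs)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  fg_assert(n > 3 * st, "input",
            "signal too short for the cascade: %d samples, need > %d",
            n, 3 * st)
  pad <- as.integer(round(pad_sec * fs))
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- zero_phase_1d(x[i, ], stages, pad)
    return(out)
  }
  zero_phase_1d(x, stages, pad)
}

#' Single-pass causal filtering (for edge-ringing comparisons)
#'
#' @inheritParams mirror_filter
#' @return causally filtered signal (nonzero phase, with onset ringing).
#' @export
causal_filter <- function(x, fs, spec = filter_spec()) {
  stages <- filter_cascade(spec, fs)
  y <- x
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) {
      for (st in stages) y[i, ] <- signal::filter(st$b, st$a, y[i, ])
    }
  } else {
    for (st in stages) y <- signal::filter(st$b, st$a, y)
  }
  y
}

#' Resample a signal to a new rate by spline interpolation
#'
#' Used for the 1048 Hz -> 256 Hz downsampling step. The cascade's 30 Hz
#' low-pass (well below the 128 Hz target Nyquist) serves as the
#' anti-alias filter, so plain cubic interpolation onto the new grid is
#' sufficient.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs_from,fs_to source and target sampling rates (Hz).
#' @return list with `data` (same shape, new length), `fs`, and `t0 = 0`
#'   time alignment (sample k is at time `(k-1)/fs_to`).
#' @export
resample_to <- function(x, fs_from, fs_to) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  t_old <- (seq_len(n) - 1) / fs_from
  t_new <- seq(0, t_old[n], by = 1 / fs_to)
  interp <- function(v) spline(t_old, v, xout = t_new, method = "fmm")$y
  data <- if (is.matrix(x)) {
    out <- matrix(0, nrow(x), length(t_new), dimnames = list(rownames(x), NULL))
    for (i in seq_len(nrow(x))) out[i, ] <- interp(x[i, ])
    out
  } else interp(x)
  list(data = data, fs = fs_to)
}

# map a per-sample logical mask through resampling: a target sample is
# masked if any source sample within half a target period was masked
resample_mask <- function(mask, fs_from, fs_to) {
  n <- length(mask)
  t_old <- (seq_len(n) - 1) / fs_from
  t_new <- seq(0, t_old[n], by = 1 / fs_to)
  half <- 0.5 / fs_to
  lo <- findInterval(t_new - half, t_old, left.open = TRUE) + 1L
  hi <- findInterval(t_new + half, t_old)
  cs <- c(0, cumsum(as.integer(mask)))
  ok <- hi >= lo
  out <- logical(length(t_new))
  out[ok] <- (cs[hi[ok] + 1L] - cs[lo[ok]]) > 0
  out
}
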