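#' TMS artifact excision window specification
#'
#' Samples from 2 ms before to 65 ms after each TMS pulse-pair onset (a
#' 67 ms window covering both pulses of the 45 Hz double pulse) are
#' replaced by a cubic-spline fit through 250 ms of context on each side
#' of the window.
#'
#' @param window_ms `c(start, end)` of the excised window relative to the
#'   pulse-pair onset, in ms.
#' @param context_ms length of the spline-fitting context on each side, ms.
#' @return object of class `fg_excision_spec`.
#' @export
excision_spec <- function(window_ms = c(-2, 65), context_ms = 250) {
  fg_assert(diff(window_ms) > 0, "input", "window must have positive length")
  fg_assert(context_ms > diff(window_ms), "input",
            "context (%g ms) must exceed the excised window (%g ms)",
            context_ms, diff(window_ms))
  structure(list(window_ms = window_ms, context_ms = context_ms,
                 window_length_ms = diff(window_ms)),
            class = "fg_excision_spec")
}

#' Excise TMS pulse artifacts and interpolate across the gap
#'
#' For every pulse-pair onset, the samples inside the excision window are
#' replaced, per channel, by a natural cubic spline fitted to the clean
#' context (250 ms by default) on each side of the window. Samples outside
#' the window are left bit-identical to the input. A logical per-sample
#' mask of interpolated data is attached; interpolated samples are later
#' excluded from statistical testing.
#'
#' @param x channels x samples matrix (micro-V).
#' @param fs sampling rate (Hz).
#' @param pulse_onsets sample indices of pulse-pair onsets (1-based).
#' @param spec [excision_spec()].
#' @return list with `data` (same shape), `mask` (logical per sample,
#'   `TRUE` = interpolated), `windows` (matrix of sample ranges).
#' @export
excise_and_interpolate <- function(x, fs, pulse_onsets,
                                   spec = excision_spec()) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  mask <- logical(n)
  if (length(pulse_onsets) == 0) {
    return(list(data = x, mask = mask,
                windows = matrix(integer(0), ncol = 2)))
  }
  w0 <- round(spec$window_ms[1] / 1000 * fs)
  w1 <- round(spec$window_ms[2] / 1000 * fs)
  ctx <- round(spec$context_ms / 1000 * fs)
  windows <- matrix(0L, length(pulse_onsets), 2)
  for (k in seq_along(pulse_onsets)) {
    p <- pulse_onsets[k]
    a <- p + w0; b <- p + w1
    if (a - ctx < 1 || b + ctx > n) {
      fg_stop("boundary",
              "pulse at sample %d: interpolation context [%d, %d] outside recording (1..%d)",
              p, a - ctx, b + ctx, n)
    }
    idx_fit <- c(seq(a - ctx, a - 1L), seq(b + 1L, b + ctx))
    idx_gap <- seq(a, b)
    for (ch in seq_len(nrow(x))) {
      x[ch, idx_gap] <- fit_gap_spline(idx_fit, x[ch, idx_fit], idx_gap)
    }
    mask[idx_gap] <- TRUE
    windows[k, ] <- c(a, b)
  }
  list(data = x, mask = mask, windows = windows)
}

# Cubic-spline fit of the context, evaluated inside the gap. A smoothing
# spline is used rather than an interpolating one: a spline forced through
# every noisy context sample acquires noise-scale edge derivatives that
# blow up when continued across a 67 ms gap, whereas the smoothing spline
# continues the low-frequency trend. Falls back to a natural interpolating
# spline for tiny or degenerate contexts.
fit_gap_spline <- function(idx_fit, y_fit, idx_gap) {
  fit <- tryCatch(
    stats::smooth.spline(idx_fit, y_fit, keep.data = FALSE),
    error = function(e) NULL)
  if (!is.null(fit)) {
    return(stats::predict(fit, idx_gap)$y)
  }
  splinefun(idx_fit, y_fit, method = "natural")(idx_gap)
}
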