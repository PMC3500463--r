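#' Derive a per-unit RNG seed from a master seed
#'
#' Deterministic counter scheme used everywhere a master seed has to be
#' fanned out over subjects, trials or replicates: the i-th derived seed is
#' `(seed + 104729 * i) mod (2^31 - 1)` (104729 is the 10000th prime, used
#' only to decorrelate neighbouring counters). Results stay inside the
#' positive 32-bit integer range accepted by [set.seed()].
#'
#' @param seed master seed (integer-like scalar).
#' @param index counter, any non-negative integer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 104729 * as.numeric(index)
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("figseg_", class, "_error"), "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

fg_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) fg_stop(class, msg, ...)
  invisible(TRUE)
}

#' Convert a logical significance vector into contiguous intervals
#'
#' @param sig logical vector over samples (in temporal order).
#' @param times_ms sample times in milliseconds, same length.
#' @return data.frame with columns `start_ms`, `end_ms`, `n_samples`,
#'   `single_sample` (flagging one-sample runs).
#' @keywords internal
runs_to_intervals <- function(sig, times_ms) {
  stopifnot(length(sig) == length(times_ms))
  if (!any(sig, na.rm = TRUE)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      n_samples = integer(0), single_sample = logical(0)))
  }
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_ms = times_ms[starts[keep]],
    end_ms = times_ms[ends[keep]],
    n_samples = r$lengths[keep],
    single_sample = r$lengths[keep] == 1L
  )
}

#' Jaccard overlap between a set of intervals and a reference window
#'
#' Computed on the discrete sample grid: the significant sample set vs the
#' set of samples inside the reference window.
#'
#' @param sig logical significance per sample.
#' @param times_ms sample times (ms).
#' @param window reference window `c(start, end)` in ms.
#' @return scalar in `[0, 1]`.
#' @export
interval_jaccard <- function(sig, times_ms, window) {
  sig[is.na(sig)] <- FALSE
  ref <- times_ms >= window[1] & times_ms <= window[2]
  u <- sum(sig | ref)
  if (u == 0) return(0)
  sum(sig & ref) / u
}

# md5 of an arbitrary R object via its serialization (used in manifests)
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
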