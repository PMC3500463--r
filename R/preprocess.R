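#' Regression-based ocular correction
#'
#' Estimates per-channel EOG propagation coefficients on blink-rich
#' segments (samples where the vertical EOG deviates by more than 4
#' robust SDs, dilated by 150 ms; the full recording is used when too few
#' blink samples exist) and regresses the EOG channels out of every scalp
#' channel.
#'
#' @param data channels x samples matrix.
#' @param labels channel labels (rownames of `data`).
#' @param eog_labels labels of the EOG channels.
#' @param fs sampling rate (Hz).
#' @return list with `data` (corrected), `coefficients` (EOG x scalp
#'   matrix), `n_blink_samples`.
#' @export
ocular_correct <- function(data, labels = rownames(data),
                           eog_labels = c("VEOG1", "VEOG2", "HEOG1", "HEOG2"),
                           fs) {
  eog_idx <- which(labels %in% eog_labels)
  if (length(eog_idx) == 0) {
    warning("no EOG channels present; ocular correction skipped")
    return(list(data = data, coefficients = NULL, n_blink_samples = 0L))
  }
  E <- data[eog_idx, , drop = FALSE]
  if (all(apply(E, 1, sd) < 1e-9)) {
    warning("EOG channels are flat; ocular correction skipped")
    return(list(data = data, coefficients = NULL, n_blink_samples = 0L))
  }
  v <- E[1, ]
  dev <- abs(v - median(v)) > 4 * mad(v)
  if (any(dev)) { # dilate by 150 ms
    k <- as.integer(round(0.15 * fs))
    idx <- which(dev)
    sel <- unique(unlist(lapply(idx, function(i) {
      seq(max(1, i - k), min(length(v), i + k))
    })))
  } else sel <- integer(0)
  if (length(sel) < fs) sel <- seq_len(ncol(data)) # too few blink samples
  scalp_idx <- setdiff(seq_len(nrow(data)), eog_idx)
  X <- t(E[, sel, drop = FALSE])
  X <- cbind(1, X)
  Y <- t(data[scalp_idx, sel, drop = FALSE])
  beta <- qr.solve(X, Y) # (1 + n_eog) x n_scalp
  pred <- t(cbind(1, t(E)) %*% beta)
  out <- data
  out[scalp_idx, ] <- data[scalp_idx, ] - pred
  list(data = out,
       coefficients = beta[-1, , drop = FALSE],
       n_blink_samples = if (length(sel) == ncol(data)) 0L else length(sel))
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' @param data channels x samples matrix (already at the analysis rate).
#' @param fs sampling rate of `data`.
#' @param event_times_s stimulus onset times in seconds.
#' @param meta per-trial metadata data.frame (kind, tms, correct, ...).
#' @param mask per-sample logical interpolation mask for `data`
#'   (`NULL` = none).
#' @param window epoch window `c(start, end)` in seconds relative to
#'   stimulus onset.
#' @return object of class `fg_epochs`: list with `data` (array trials x
#'   channels x samples), `mask` (trials x samples), `meta`, `times_ms`,
#'   `fs`, `labels`.
#' @export
epoch_recording <- function(data, fs, event_times_s, meta, mask = NULL,
                            window = c(-0.2, 0.5)) {
  fg_assert(length(event_times_s) > 0, "input", "no events to epoch")
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  times_ms <- rel / fs * 1000
  n_tr <- length(event_times_s)
  ep <- array(0, dim = c(n_tr, nrow(data), length(rel)),
              dimnames = list(NULL, rownames(data), NULL))
  epm <- matrix(FALSE, n_tr, length(rel))
  for (i in seq_len(n_tr)) {
    s0 <- as.integer(round(event_times_s[i] * fs)) + 1L
    idx <- s0 + rel
    fg_assert(idx[1] >= 1 && idx[length(idx)] <= ncol(data), "boundary",
              "epoch %d extends outside the recording", i)
    ep[i, , ] <- data[, idx]
    if (!is.null(mask)) epm[i, ] <- mask[idx]
  }
  structure(list(data = ep, mask = epm, meta = meta, times_ms = times_ms,
                 fs = fs, labels = rownames(data)),
            class = "fg_epochs")
}

#' Threshold-based artifact rejection
#'
#' Drops every trial containing any scalp-channel sample outside
#' +/-`amp_uv` micro-V or any single-sample voltage step exceeding
#' `step_uv` micro-V. Applied to potential (micro-V) data before the
#' surface Laplacian, whose units the thresholds are not defined in.
#' Interpolated TMS segments are exempt from the step criterion (their
#' spline edges are not physiological steps).
#'
#' @param epochs `fg_epochs` in micro-V.
#' @param amp_uv amplitude bound.
#' @param step_uv per-sampling-point step bound.
#' @param scalp_labels channels the criteria apply to (default: all
#'   non-EOG channels).
#' @return list with `epochs` (retained trials) and `report` (data.frame
#'   `trial`, `reason`, `channel`, `value`).
#' @export
reject_artifacts <- function(epochs, amp_uv = 75, step_uv = 50,
                             scalp_labels = NULL) {
  labs <- epochs$labels
  if (is.null(scalp_labels)) {
    scalp_labels <- labs[!grepl("EOG", labs)]
  }
  ch_idx <- which(labs %in% scalp_labels)
  n_tr <- dim(epochs$data)[1]
  report <- data.frame(trial = integer(0), reason = character(0),
                       channel = character(0), value = numeric(0))
  drop <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    x <- epochs$data[i, ch_idx, , drop = TRUE]
    mx <- max(abs(x))
    if (mx > amp_uv) {
      w <- which(abs(x) == mx, arr.ind = TRUE)[1, ]
      report <- rbind(report, data.frame(
        trial = i, reason = "amplitude", channel = labs[ch_idx[w[1]]],
        value = mx))
      drop[i] <- TRUE
      next
    }
    st <- abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
    interp <- epochs$mask[i, ]
    step_ok <- !(interp[-length(interp)] | interp[-1]) # exempt interpolated
    st <- st[, step_ok, drop = FALSE]
    if (length(st) && max(st) > step_uv) {
      w <- which(st == max(st), arr.ind = TRUE)[1, ]
      report <- rbind(report, data.frame(
        trial = i, reason = "step", channel = labs[ch_idx[w[1]]],
        value = max(st)))
      drop[i] <- TRUE
    }
  }
  if (all(drop)) {
    fg_stop("empty", "all %d trials rejected (%d amplitude, %d step)",
            n_tr, sum(report$reason == "amplitude"),
            sum(report$reason == "step"))
  }
  keep <- !drop
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$mask <- epochs$mask[keep, , drop = FALSE]
  epochs$meta <- epochs$meta[keep, , drop = FALSE]
  list(epochs = epochs, report = report)
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the baseline window
#' (the 100 ms before stimulus onset by default).
#'
#' @param epochs `fg_epochs`.
#' @param window baseline window in ms.
#' @return corrected `fg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  sel <- epochs$times_ms >= window[1] & epochs$times_ms <= window[2]
  fg_assert(any(sel), "input", "baseline window outside the epoch")
  for (i in seq_len(dim(epochs$data)[1])) {
    bl <- rowMeans(epochs$data[i, , sel, drop = TRUE])
    epochs$data[i, , ] <- epochs$data[i, , ] - bl
  }
  epochs
}

#' Average epochs into per-condition ERPs with a pooled trace
#'
#' @param epochs `fg_epochs`.
#' @param pool channel labels averaged into the pooled trace.
#' @return named list (`kind.condition`) of ERP objects: `data`
#'   (channels x samples), `pooled`, `mask` (union over trials),
#'   `n_trials`, `times_ms`, `kind`, `tms`, `valid`.
#' @export
average_erps <- function(epochs, pool = pool_channels()) {
  cells <- expand.grid(kind = kinds_3, tms = tms_conditions_4,
                       stringsAsFactors = FALSE)
  pool_idx <- which(epochs$labels %in% pool)
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- which(epochs$meta$kind == cells$kind[r] &
                   epochs$meta$tms == cells$tms[r])
    nm <- paste(cells$kind[r], cells$tms[r], sep = ".")
    if (length(sel) == 0) {
      out[[nm]] <- list(data = NULL, pooled = NULL, mask = NULL,
                        n_trials = 0L, times_ms = epochs$times_ms,
                        kind = cells$kind[r], tms = cells$tms[r],
                        valid = FALSE)
      next
    }
    avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    rownames(avg) <- epochs$labels
    out[[nm]] <- list(
      data = avg,
      pooled = colMeans(avg[pool_idx, , drop = FALSE]),
      mask = apply(epochs$mask[sel, , drop = FALSE], 2, any),
      n_trials = length(sel), times_ms = epochs$times_ms,
      kind = cells$kind[r], tms = cells$tms[r], valid = TRUE)
  }
  out
}

#' Preprocessing configuration
#'
#' @param excision enable TMS artifact excision/interpolation.
#' @param excision_spec [excision_spec()].
#' @param filter [filter_spec()].
#' @param fs_target analysis sampling rate after downsampling (Hz).
#' @param reference reference channel label (subtracted from all scalp
#'   channels).
#' @param ocular enable regression ocular correction.
#' @param reject enable threshold artifact rejection.
#' @param amp_uv,step_uv rejection thresholds (micro-V).
#' @param laplacian enable the spherical-spline surface Laplacian.
#' @param laplacian_m,laplacian_lambda,laplacian_terms spline parameters.
#' @param epoch_s epoch window (s).
#' @param baseline_ms baseline window (ms).
#' @param pool pooled channel labels.
#' @param trials trial subset entering the ERPs: `"all"` or
#'   `"correct"`.
#' @return list of class `fg_preproc_config`.
#' @export
preproc_config <- function(excision = TRUE, excision_spec = figseg::excision_spec(),
                           filter = filter_spec(), fs_target = 256,
                           reference = "Cz", ocular = TRUE, reject = TRUE,
                           amp_uv = 75, step_uv = 50, laplacian = TRUE,
                           laplacian_m = 4, laplacian_lambda = 1e-5,
                           laplacian_terms = 50,
                           epoch_s = c(-0.2, 0.5), baseline_ms = c(-100, 0),
                           pool = pool_channels(), trials = "all") {
  structure(list(excision = excision, excision_spec = excision_spec,
                 filter = filter, fs_target = fs_target,
                 reference = reference, ocular = ocular, reject = reject,
                 amp_uv = amp_uv, step_uv = step_uv, laplacian = laplacian,
                 laplacian_m = laplacian_m,
                 laplacian_lambda = laplacian_lambda,
                 laplacian_terms = laplacian_terms,
                 epoch_s = epoch_s, baseline_ms = baseline_ms, pool = pool,
                 trials = trials),
            class = "fg_preproc_config")
}

#' Run the full preprocessing chain on one recording
#'
#' Stage order: TMS artifact excision and spline interpolation ->
#' zero-phase mirror filtering (0.5 / 30 / 50 Hz cascade) -> downsampling
#' to 256 Hz -> re-referencing to Cz -> regression ocular correction ->
#' threshold artifact rejection -> spherical-spline surface Laplacian ->
#' epoching -> baseline correction -> per-condition averaging ->
#' peri-occipital pooling. Rejection operates on micro-V data because its
#' thresholds are potentials; the Laplacian is applied to the retained
#' epochs.
#'
#' @param recording `fg_recording`.
#' @param config [preproc_config()].
#' @return list with `erps` (12 per-condition ERP objects), `epochs`
#'   (post-Laplacian), `rejection` report, `ocular` coefficients, `mask`
#'   (continuous-time interpolation mask at `fs_target`), `config`.
#' @export
run_preprocessing <- function(recording, config = preproc_config()) {
  fg_assert(nrow(recording$events) > 0, "input", "recording has no events")
  x <- recording$data
  fs <- recording$fs
  mask <- logical(ncol(x))
  if (config$excision && nrow(recording$pulses) > 0) {
    exc <- excise_and_interpolate(x, fs, recording$pulses$sample,
                                  config$excision_spec)
    x <- exc$data
    mask <- exc$mask
  }
  x <- mirror_filter(x, fs, config$filter)
  rs <- resample_to(x, fs, config$fs_target)
  x <- rs$data
  fs2 <- rs$fs
  mask2 <- resample_mask(mask, fs, config$fs_target)
  if (!is.null(config$reference) &&
      config$reference %in% rownames(x)) {
    scalp <- !grepl("EOG", rownames(x))
    x[scalp, ] <- sweep(x[scalp, , drop = FALSE], 2,
                        x[config$reference, ])
  }
  oc <- NULL
  if (config$ocular) {
    occ <- ocular_correct(x, rownames(x), fs = fs2)
    x <- occ$data
    oc <- occ$coefficients
  }
  meta <- recording$events
  if (identical(config$trials, "correct")) {
    keep <- which(meta$correct)
    fg_assert(length(keep) > 0, "input", "no correct trials to analyze")
    meta <- meta[keep, , drop = FALSE]
  }
  epochs <- epoch_recording(x, fs2, meta$time_s, meta, mask = mask2,
                            window = config$epoch_s)
  rejection <- NULL
  if (config$reject) {
    rj <- reject_artifacts(epochs, config$amp_uv, config$step_uv)
    epochs <- rj$epochs
    rejection <- rj$report
  }
  if (config$laplacian) {
    lt <- laplacian_transform(recording$montage, m = config$laplacian_m,
                              lambda = config$laplacian_lambda,
                              n_terms = config$laplacian_terms)
    sc_idx <- match(lt$labels, epochs$labels)
    epochs$data[, sc_idx, ] <- spline_laplacian(
      epochs$data[, sc_idx, , drop = FALSE], lt)
  }
  epochs <- baseline_correct(epochs, config$baseline_ms)
  erps <- average_erps(epochs, pool = config$pool)
  invalid <- names(erps)[!vapply(erps, `[[`, logical(1), "valid")]
  if (length(invalid)) {
    warning("conditions with no surviving trials: ",
            paste(invalid, collapse = ", "))
  }
  list(erps = erps, epochs = epochs, rejection = rejection, ocular = oc,
       mask = mask2, fs = fs2, config = config)
}
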