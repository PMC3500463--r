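#' ERP component templates with condition-dependent gains
#'
#' Two compactly supported raised-cosine (Hann) components carry the
#' condition structure of the design:
#'
#' * `figural`: a negative deflection common to both figure stimuli
#'   (stack and frame) over 137-211 ms -- the figure-border-detection
#'   correlate isolated by the figure minus homogenous difference wave.
#' * `surface`: a positive deflection carried by stack stimuli only over
#'   227-313 ms -- the surface-segregation correlate isolated by the
#'   stack minus frame difference wave.
#'
#' Per-component gain factors encode the simulated TMS disruption: early
#' stimulation attenuates both components (gain 0.2), intermediate
#' stimulation leaves both intact (gain 1), late stimulation attenuates
#' only the surface component (gain 0.5), mirroring the behavioral
#' finding that late disruption selectively degrades stack detection.
#' Amplitudes are stated at the peri-occipital pool peak; no reference
#' effect sizes in micro-V exist, so these are calibration choices.
#'
#' @param figural_amp,surface_amp pool-peak amplitudes in micro-V.
#' @param figural_window,surface_window component support in ms.
#' @param figural_gains,surface_gains named gain vectors over TMS
#'   conditions, each in `[0, 1]`.
#' @return object of class `fg_templates`.
#' @export
erp_templates <- function(figural_amp = -1.5,
                          figural_window = c(137, 211),
                          figural_gains = c(none = 1, early = 0.2,
                                            intermediate = 1, late = 1),
                          surface_amp = 1.0,
                          surface_window = c(227, 313),
                          surface_gains = c(none = 1, early = 0.2,
                                            intermediate = 1, late = 0.5)) {
  chk <- function(g) {
    fg_assert(all(g >= 0 & g <= 1), "input", "gains must lie in [0, 1]")
    fg_assert(all(tms_conditions_4 %in% names(g)), "input",
              "gains must name all four TMS conditions")
  }
  chk(figural_gains); chk(surface_gains)
  structure(list(
    figural = list(window_ms = figural_window, amplitude = figural_amp,
                   kinds = c("stack", "frame"), gains = figural_gains),
    surface = list(window_ms = surface_window, amplitude = surface_amp,
                   kinds = "stack", gains = surface_gains)
  ), class = "fg_templates")
}

hann_bump <- function(t_ms, window_ms) {
  u <- (t_ms - window_ms[1]) / diff(window_ms)
  ifelse(u >= 0 & u <= 1, sin(pi * u)^2, 0)
}

#' Spatial weight map peaked over the peri-occipital pool
#'
#' Gaussian falloff in great-circle angle from the centroid of the pooled
#' electrodes, normalized so the mean weight over the pool is 1 (a
#' component of amplitude A then averages to A across the pool).
#'
#' @param montage `fg_montage`.
#' @param fwhm_deg full width at half maximum of the falloff, degrees of
#'   arc on the scalp sphere.
#' @return named numeric weight per scalp channel.
#' @export
occipital_weights <- function(montage, fwhm_deg = 70) {
  sc <- montage[montage$type == "scalp", ]
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  pool <- pool_channels()
  ctr <- colMeans(xyz[sc$label %in% pool, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(1, pmax(-1, xyz %*% ctr))) * 180 / pi
  sig <- fwhm_deg / (2 * sqrt(2 * log(2)))
  w <- exp(-ang^2 / (2 * sig^2))
  w <- w / mean(w[sc$label %in% pool])
  stats::setNames(as.numeric(w), sc$label)
}

#' Noiseless pooled-channel ERP implied by the templates
#'
#' The exact injected waveform after peri-occipital pooling; the recovery
#' oracle for all downstream stages.
#'
#' @param kind stimulus kind.
#' @param condition TMS condition.
#' @param templates [erp_templates()].
#' @param times_ms sample times relative to stimulus onset (ms).
#' @return numeric vector over `times_ms` (micro-V at the pool).
#' @export
ground_truth_erp <- function(kind, condition, templates = erp_templates(),
                             times_ms) {
  fg_assert(kind %in% kinds_3, "input", "unknown kind '%s'", kind)
  fg_assert(condition %in% tms_conditions_4, "input",
            "unknown condition '%s'", condition)
  out <- numeric(length(times_ms))
  for (comp in templates) {
    if (!kind %in% comp$kinds) next
    out <- out + comp$amplitude * comp$gains[[condition]] *
      hann_bump(times_ms, comp$window_ms)
  }
  out
}

#' TMS artifact model
#'
#' Each pulse of the 45 Hz double pulse injects a large (mV-scale)
#' transient: a biexponentially enveloped damped oscillation, clipped at
#' the amplifier range, with an occipitally weighted topography. Peak
#' amplitude is far above EEG scale (>= 10x any ERP component).
#'
#' @param peak_uv artifact peak in micro-V.
#' @param decay_ms slow envelope time constant (ms).
#' @param rise_ms fast envelope time constant (ms).
#' @param ring_hz damped oscillation frequency (Hz).
#' @param clip_uv clipping range (+/-).
#' @param duration_ms support of the artifact after each pulse.
#' @return object of class `fg_artifact_model` including the pulse-pair
#'   onsets per TMS condition from [tms_windows_ms()].
#' @export
tms_artifact_model <- function(peak_uv = 5000, decay_ms = 6, rise_ms = 0.8,
                               ring_hz = 180, clip_uv = 5000,
                               duration_ms = 45) {
  structure(list(onsets_ms = tms_windows_ms(), pulse_gap_ms = 23,
                 peak_uv = peak_uv, decay_ms = decay_ms, rise_ms = rise_ms,
                 ring_hz = ring_hz, clip_uv = clip_uv,
                 duration_ms = duration_ms),
            class = "fg_artifact_model")
}

artifact_waveform <- function(model, fs) {
  t_ms <- seq(0, model$duration_ms, by = 1000 / fs)
  env <- exp(-t_ms / model$decay_ms) - exp(-t_ms / model$rise_ms)
  env <- env / max(env)
  w <- model$peak_uv * env * cos(2 * pi * model$ring_hz * t_ms / 1000)
  pmin(pmax(w, -model$clip_uv), model$clip_uv)
}

#' Background noise model for simulated recordings
#'
#' Realistic EEG background for exercising the pipeline: 1/f ("pink")
#' activity, broadband white noise, 50 Hz mains, stereotyped blinks on
#' the vertical EOG with a frontally weighted scalp projection, and a
#' log-normal per-subject amplitude random effect. The study itself
#' specifies no noise model; these are the package's defaults.
#'
#' @param pink_sd,white_sd per-channel standard deviations (micro-V).
#' @param pink_exponent spectral exponent alpha in 1/f^alpha power.
#' @param line_amp 50 Hz line amplitude (micro-V).
#' @param line_hz mains frequency.
#' @param blink_rate_per_min expected blink rate.
#' @param blink_amp_uv blink amplitude on the vertical EOG.
#' @param blink_dur_ms blink kernel duration.
#' @param subject_sd sd of the log-normal per-subject amplitude effect.
#' @return object of class `fg_noise_model`.
#' @export
noise_model <- function(pink_sd = 6, pink_exponent = 1, white_sd = 2,
                        line_amp = 1.5, line_hz = 50,
                        blink_rate_per_min = 4, blink_amp_uv = 150,
                        blink_dur_ms = 300, subject_sd = 0.2) {
  fg_assert(all(c(pink_sd, white_sd, line_amp, blink_rate_per_min,
                  blink_amp_uv, subject_sd) >= 0), "input",
            "all noise scales must be >= 0")
  structure(list(pink_sd = pink_sd, pink_exponent = pink_exponent,
                 white_sd = white_sd, line_amp = line_amp, line_hz = line_hz,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp_uv = blink_amp_uv, blink_dur_ms = blink_dur_ms,
                 subject_sd = subject_sd),
            class = "fg_noise_model")
}

# 1/f^alpha noise via spectral shaping, unit variance
pink_noise <- function(n, alpha) {
  if (n < 4) return(rnorm(n))
  white <- rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index, DC guarded
  sp <- sp / f^(alpha / 2)
  x <- Re(fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Behavioral response model
#'
#' Per TMS condition, a 3x3 confusion matrix P(response | stimulus) and a
#' log-normal reaction-time distribution with additive per-condition
#' shifts. Defaults encode the behavioral structure of the design: frame
#' detection is selectively worst under early stimulation; stack
#' detection suffers under early and again under late stimulation, with
#' late errors dominated by stacks reported as frames; homogenous
#' detection dips slightly whenever TMS is applied (most under the
#' intermediate window); figure-to-homogenous error rates do not depend
#' on TMS timing. Sham stimulation shifts RTs without touching the
#' confusion matrices.
#'
#' @param confusion named list over conditions of 3x3 row-stochastic
#'   matrices (rows/cols ordered stack, frame, homogenous).
#' @param rt_median_ms named medians per stimulus kind (ms, no-TMS).
#' @param rt_sdlog log-normal sdlog.
#' @param rt_shift_ms additive RT shift per TMS condition (ms).
#' @param sham if `TRUE`, RT shifts apply but confusion matrices revert
#'   to the no-TMS matrix in every condition.
#' @return object of class `fg_behavior_model`.
#' @export
behavior_model <- function(confusion = default_confusion(),
                           rt_median_ms = c(stack = 590, frame = 620,
                                            homogenous = 560),
                           rt_sdlog = 0.25,
                           rt_shift_ms = c(none = 0, early = 32,
                                           intermediate = 33, late = 51),
                           sham = FALSE) {
  for (cc in tms_conditions_4) {
    m <- confusion[[cc]]
    fg_assert(!is.null(m) && all(dim(m) == c(3, 3)), "input",
              "confusion[['%s']] must be a 3x3 matrix", cc)
    fg_assert(all(m >= 0 & m <= 1) && all(abs(rowSums(m) - 1) < 1e-9),
              "input", "confusion rows must be probabilities summing to 1")
  }
  structure(list(confusion = confusion, rt_median_ms = rt_median_ms,
                 rt_sdlog = rt_sdlog, rt_shift_ms = rt_shift_ms,
                 sham = sham),
            class = "fg_behavior_model")
}

#' @rdname behavior_model
#' @export
default_confusion <- function() {
  mk <- function(v) {
    m <- matrix(v, 3, 3, byrow = TRUE,
                dimnames = list(kinds_3, kinds_3))
    m
  }
  list(
    none = mk(c(0.80, 0.15, 0.05,
                0.13, 0.82, 0.05,
                0.05, 0.05, 0.90)),
    early = mk(c(0.68, 0.26, 0.06,
                 0.24, 0.70, 0.06,
                 0.085, 0.085, 0.83)),
    intermediate = mk(c(0.79, 0.16, 0.05,
                        0.14, 0.81, 0.05,
                        0.09, 0.09, 0.82)),
    late = mk(c(0.65, 0.30, 0.05,
                0.15, 0.80, 0.05,
                0.075, 0.075, 0.85))
  )
}
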