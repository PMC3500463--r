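# shared fixtures, all generated in code

# miniature screen: keeps movie generation fast while preserving the
# nested three-region geometry
small_params <- function(...) {
  stimulus_params(screen_size = c(96L, 64L), frame_extent_px = 25L,
                  inner_extent_px = 15L, offset_px = c(-10L, 10L), ...)
}

quiet_noise <- function(...) {
  noise_model(pink_sd = 0, white_sd = 0, line_amp = 0,
              blink_rate_per_min = 0, subject_sd = 0, ...)
}

# oracle for pipeline recovery tests: the analytic template pushed through
# the same filter cascade and resampling, with the Cz-reference factor
# (re-referencing removes the small Cz share of the occipital weight map
# from every channel, scaling the pooled trace by 1 - w[Cz])
filtered_template <- function(kind, condition, times_ms,
                              templates = erp_templates(),
                              fs = 1048, fs_target = 256,
                              baseline = c(-100, 0)) {
  tt <- seq(0, 8, by = 1 / fs)
  cont <- ground_truth_erp(kind, condition, templates, (tt - 1) * 1000)
  filt <- mirror_filter(cont, fs)
  res <- resample_to(filt, fs, fs_target)$data
  t_ms <- ((seq_along(res) - 1) / fs_target - 1) * 1000
  out <- vapply(times_ms, function(m) res[which.min(abs(t_ms - m))],
                numeric(1))
  w_cz <- occipital_weights(standard_montage())[["Cz"]]
  out <- out * (1 - w_cz)
  out - mean(out[times_ms >= baseline[1] & times_ms <= baseline[2]])
}

# independent brute-force BH step-up: literal definition, O(m^2)
brute_force_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * q / m) k_max <- k
  }
  reject <- rep(FALSE, m)
  if (k_max > 0) reject[ord[seq_len(k_max)]] <- TRUE
  reject
}
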