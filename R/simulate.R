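#' Simulate one subject's continuous TMS-EEG session and behavior
#'
#' Builds a continuous multichannel recording as the sum of (i) the clean
#' stimulus-locked ERP stream (templates scaled by the per-condition
#' gains and projected through the occipital weight map), (ii) background
#' noise (pink + white + 50 Hz line), (iii) blink activity on the EOG
#' channels with a known frontal scalp projection, and (iv) large TMS
#' pulse-pair artifacts on TMS trials. The clean ERP stream is retained
#' as ground truth, so `data - clean` is exactly the sampled
#' noise-plus-artifact stream. Behavioral responses are drawn from the
#' behavior model's confusion matrices and RT distributions.
#'
#' @param schedule `fg_schedule` (one row per trial).
#' @param montage `fg_montage`.
#' @param templates [erp_templates()].
#' @param artifact [tms_artifact_model()]; set `NULL` for no artifacts.
#' @param noise [noise_model()].
#' @param behavior [behavior_model()].
#' @param fs sampling rate, Hz.
#' @param trial_spacing_s stimulus-onset asynchrony, seconds; must leave
#'   room for non-overlapping epochs plus interpolation context.
#' @param subject subject identifier.
#' @param amp_gain subject-level amplitude multiplier (drawn by
#'   [simulate_cohort()]).
#' @param seed RNG seed; the whole product is a pure function of it.
#' @param store_components if `TRUE`, keep the noise/artifact stream too
#'   (memory heavy; used by additivity checks).
#' @return object of class `fg_recording`: list with `data`
#'   (channels x samples, micro-V), `clean` (ERP-only stream), `fs`,
#'   `labels`, `montage`, `events` (trial onsets with kind/condition),
#'   `pulses` (pulse-pair onsets + individual pulse samples),
#'   `behavior` (per-trial table), `blink_projection`, `subject`.
#' @export
simulate_subject <- function(schedule, montage = standard_montage(),
                             templates = erp_templates(),
                             artifact = tms_artifact_model(),
                             noise = noise_model(),
                             behavior = behavior_model(),
                             fs = 1048, trial_spacing_s = 2,
                             subject = 1L, amp_gain = 1, seed = 1L,
                             store_components = FALSE) {
  fg_assert(nrow(schedule) > 0, "input", "schedule is empty")
  fg_assert(trial_spacing_s >= 1.2, "scheduling",
            "trial spacing %.2f s would overlap epochs and interpolation context",
            trial_spacing_s)
  set.seed(as.integer(seed))
  n_trials <- nrow(schedule)
  lead <- 1.0 # seconds before first onset / after last epoch
  n <- as.integer(round((n_trials * trial_spacing_s + 2 * lead) * fs))
  labels <- montage$label
  n_ch <- length(labels)
  scalp <- montage$type == "scalp"

  onset_samples <- as.integer(round((lead + (seq_len(n_trials) - 1) *
                                       trial_spacing_s) * fs)) + 1L

  # --- clean ERP stream -------------------------------------------------
  w <- occipital_weights(montage)
  epoch_len <- as.integer(round(0.6 * fs)) # components end < 350 ms
  t_ms <- (seq_len(epoch_len) - 1) / fs * 1000
  clean <- matrix(0, n_ch, n, dimnames = list(labels, NULL))
  kind_cond_wave <- list()
  for (k in kinds_3) for (cc in tms_conditions_4) {
    kind_cond_wave[[paste(k, cc, sep = ".")]] <-
      ground_truth_erp(k, cc, templates, t_ms)
  }
  for (i in seq_len(n_trials)) {
    wave <- kind_cond_wave[[paste(schedule$kind[i], schedule$tms[i],
                                  sep = ".")]]
    if (all(wave == 0)) next
    idx <- onset_samples[i]:(onset_samples[i] + epoch_len - 1L)
    clean[scalp, idx] <- clean[scalp, idx] +
      amp_gain * outer(w[labels[scalp]], wave)
  }

  # --- noise + artifacts ------------------------------------------------
  nz <- matrix(0, n_ch, n, dimnames = list(labels, NULL))
  for (ch in seq_len(n_ch)) {
    v <- numeric(n)
    if (noise$pink_sd > 0) v <- v + noise$pink_sd * pink_noise(n, noise$pink_exponent)
    if (noise$white_sd > 0) v <- v + rnorm(n, sd = noise$white_sd)
    if (noise$line_amp > 0) {
      v <- v + noise$line_amp *
        sin(2 * pi * noise$line_hz * (seq_len(n) - 1) / fs + runif(1, 0, 2 * pi))
    }
    nz[ch, ] <- v
  }

  # blinks: VEOG kernel plus a known frontal scalp projection
  blink_proj <- pmax(montage$y, 0)^2 * 0.4
  blink_proj[!scalp] <- 0
  blink_proj[labels %in% c("VEOG1", "VEOG2")] <- c(1, -0.9)
  blink_proj[labels %in% c("HEOG1", "HEOG2")] <- c(0.08, -0.08)
  names(blink_proj) <- labels
  n_blinks <- rpois(1, noise$blink_rate_per_min * n / fs / 60)
  blink_kernel <- noise$blink_amp_uv *
    hann_bump(seq(0, noise$blink_dur_ms, by = 1000 / fs),
              c(0, noise$blink_dur_ms))
  bl <- length(blink_kernel)
  if (n_blinks > 0 && bl < n) {
    starts <- sort(sample.int(n - bl, n_blinks))
    for (s in starts) {
      idx <- s:(s + bl - 1L)
      nz[, idx] <- nz[, idx] + outer(blink_proj, blink_kernel)
    }
  }

  # TMS double-pulse artifacts
  pulses <- data.frame(sample = integer(0), condition = character(0),
                       trial = integer(0))
  if (!is.null(artifact)) {
    art_wave <- artifact_waveform(artifact, fs)
    al <- length(art_wave)
    art_topo <- 0.3 + 0.7 * w / max(w)
    topo <- numeric(n_ch)
    topo[scalp] <- art_topo[labels[scalp]]
    tms_trials <- which(schedule$tms != "none")
    for (i in tms_trials) {
      cond <- schedule$tms[i]
      ons <- artifact$onsets_ms[[cond]]
      pair_onset <- onset_samples[i] +
        as.integer(round(ons[1] / 1000 * fs))
      for (o_ms in ons) {
        s <- onset_samples[i] + as.integer(round(o_ms / 1000 * fs))
        idx <- s:(min(s + al - 1L, n))
        nz[, idx] <- nz[, idx] + outer(topo, art_wave[seq_along(idx)])
      }
      pulses <- rbind(pulses, data.frame(sample = pair_onset,
                                         condition = cond, trial = i))
    }
  }

  # --- behavior ---------------------------------------------------------
  beh <- sample_behavior(schedule, behavior, subject = subject)

  events <- data.frame(sample = onset_samples,
                       time_s = (onset_samples - 1) / fs,
                       trial = seq_len(n_trials),
                       kind = schedule$kind, tms = schedule$tms,
                       correct = beh$correct)
  fg_assert(all(diff(events$sample) > 0), "scheduling",
            "event times must be strictly increasing")

  structure(list(data = clean + nz,
                 clean = clean,
                 components = if (store_components) nz else NULL,
                 fs = fs, labels = labels, montage = montage,
                 events = events, pulses = pulses, behavior = beh,
                 blink_projection = blink_proj,
                 subject = subject, seed = as.integer(seed),
                 templates = templates),
            class = "fg_recording")
}

#' Sample a behavioral table from a behavior model
#'
#' Draws one response (from the per-condition confusion matrix) and one
#' reaction time (log-normal plus the condition shift) per scheduled
#' trial. Under a sham model the no-TMS confusion matrix applies in every
#' condition while the RT shifts remain.
#'
#' @param schedule `fg_schedule`.
#' @param behavior [behavior_model()].
#' @param subject subject id recorded in the table.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data.frame with `subject`, `block`, `trial`, `kind`, `tms`,
#'   `response`, `rt_ms`, `correct`.
#' @export
sample_behavior <- function(schedule, behavior = behavior_model(),
                            subject = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_trials <- nrow(schedule)
  conf_source <- if (isTRUE(behavior$sham)) {
    stats::setNames(rep(list(behavior$confusion[["none"]]),
                        length(tms_conditions_4)), tms_conditions_4)
  } else behavior$confusion
  resp <- character(n_trials); rt <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    pr <- conf_source[[schedule$tms[i]]][schedule$kind[i], ]
    resp[i] <- sample(kinds_3, 1, prob = pr)
    rt[i] <- rlnorm(1, log(behavior$rt_median_ms[[schedule$kind[i]]]),
                    behavior$rt_sdlog) +
      behavior$rt_shift_ms[[schedule$tms[i]]]
  }
  data.frame(subject = subject, block = schedule$block,
             trial = schedule$trial, kind = schedule$kind,
             tms = schedule$tms, response = resp, rt_ms = rt,
             correct = resp == schedule$kind)
}

#' Simulate a cohort of subjects
#'
#' Subject-level amplitude random effects are drawn once per subject
#' (log-normal, sd `noise$subject_sd`); per-subject seeds derive from the
#' master seed with [derive_seed()]. Optionally a number of "poor"
#' performers (near-chance stack detection, overall accuracy at or below
#' the 67% exclusion bar) can be included to exercise the behavioral
#' exclusion rule.
#'
#' @param n_subjects number of subjects (>= 2; paired statistics are
#'   undefined below that).
#' @param schedule trial schedule shared by all subjects.
#' @param n_poor number of additional poor-performing subjects appended.
#' @param seed master seed.
#' @inheritParams simulate_subject
#' @param ... passed on to [simulate_subject()].
#' @return object of class `fg_cohort`: list with `recordings` (list of
#'   `fg_recording`) and `behavior` (pooled table).
#' @export
simulate_cohort <- function(n_subjects = 11L, schedule = build_schedule(2, 24),
                            montage = standard_montage(),
                            templates = erp_templates(),
                            artifact = tms_artifact_model(),
                            noise = noise_model(),
                            behavior = behavior_model(),
                            n_poor = 0L, seed = 1L, ...) {
  fg_assert(n_subjects >= 2, "input",
            "need >= 2 subjects for paired statistics")
  set.seed(as.integer(seed))
  gains <- rlnorm(n_subjects + n_poor, 0, noise$subject_sd)
  poor_conf <- lapply(default_confusion(), function(m) {
    m[] <- 1 / 3 # responds at chance regardless of stimulus
    m
  })
  recs <- vector("list", n_subjects + n_poor)
  for (i in seq_len(n_subjects + n_poor)) {
    beh_i <- if (i > n_subjects) {
      behavior_model(confusion = poor_conf, sham = behavior$sham)
    } else behavior
    recs[[i]] <- simulate_subject(
      schedule, montage = montage, templates = templates,
      artifact = artifact, noise = noise, behavior = beh_i,
      subject = i, amp_gain = gains[i], seed = derive_seed(seed, i), ...)
  }
  beh <- do.call(rbind, lapply(recs, `[[`, "behavior"))
  structure(list(recordings = recs, behavior = beh,
                 subject_gains = gains, seed = as.integer(seed)),
            class = "fg_cohort")
}

#' Simulate subject-level pooled condition ERPs directly
#'
#' Light-weight generator for statistical power and recovery studies:
#' for every subject and every kind x condition cell it returns the
#' pooled peri-occipital ERP as ground truth x subject gain plus
#' independent Gaussian sample noise. `noise_sd` is the residual standard
#' deviation of a subject-level condition average (i.e. after trial
#' averaging and pooling); the default of 0.3 micro-V is the package's
#' calibration for a 200-trials-per-condition cohort.
#'
#' @param n_subjects subjects (>= 2).
#' @param templates [erp_templates()].
#' @param noise_sd per-sample residual sd of a subject condition mean
#'   (micro-V).
#' @param subject_sd sd of the log-normal amplitude random effect.
#' @param fs sampling rate of the ERP time base (Hz).
#' @param epoch_s epoch window `c(start, end)` in seconds.
#' @param seed RNG seed.
#' @return object of class `fg_erp_cohort`: list with `erps` (array
#'   subjects x cells x samples, cells named `kind.condition`),
#'   `times_ms`, `fs`.
#' @export
simulate_erp_cohort <- function(n_subjects = 11L,
                                templates = erp_templates(),
                                noise_sd = 0.3, subject_sd = 0.2,
                                fs = 256, epoch_s = c(-0.2, 0.5),
                                seed = 1L) {
  fg_assert(n_subjects >= 2, "input",
            "need >= 2 subjects for paired statistics")
  set.seed(as.integer(seed))
  times_ms <- seq(epoch_s[1], epoch_s[2], by = 1 / fs) * 1000
  cells <- as.vector(outer(kinds_3, tms_conditions_4, paste, sep = "."))
  erps <- array(0, dim = c(n_subjects, length(cells), length(times_ms)),
                dimnames = list(NULL, cells, NULL))
  gains <- rlnorm(n_subjects, 0, subject_sd)
  for (s in seq_len(n_subjects)) {
    for (j in seq_along(cells)) {
      kc <- strsplit(cells[j], ".", fixed = TRUE)[[1]]
      gt <- ground_truth_erp(kc[1], kc[2], templates, times_ms)
      erps[s, j, ] <- gains[s] * gt + rnorm(length(times_ms), sd = noise_sd)
    }
  }
  structure(list(erps = erps, times_ms = times_ms, fs = fs,
                 subject_gains = gains, seed = as.integer(seed)),
            class = "fg_erp_cohort")
}
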