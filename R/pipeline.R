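#' Assemble a full experiment configuration
#'
#' Profiles bundle the design constants with a simulation scale:
#'
#' * `"reference"` -- the full design: 25 blocks x 96 trials (200 trials
#'   per condition), 11 subjects, 1048 Hz acquisition. Too heavy for
#'   routine desk runs; provided as the canonical parameterization.
#' * `"desk"` -- 11 subjects x 48 trials (4 per condition): runs a full
#'   simulate/preprocess/stats cycle in minutes on one CPU.
#' * `"tiny"` -- 3 subjects x 24 trials (2 per condition): smoke-test and
#'   fixture scale.
#'
#' All profiles share the analysis constants: 0.5/30/50 Hz filters,
#' excision -2..65 ms with 250 ms context, downsampling to 256 Hz, Cz
#' reference, +/-75 micro-V and 50 micro-V/step rejection, -100..0 ms
#' baseline, 10-channel peri-occipital pool, test windows 80-230 ms
#' (figure-homogenous) and 200-350 ms (stack-frame), cumulation window
#' 227-313 ms, q = 0.05.
#'
#' @param profile one of `"reference"`, `"desk"`, `"tiny"`.
#' @param seed master seed.
#' @param ... named overrides of top-level config entries.
#' @return nested list of class `fg_config`.
#' @export
experiment_config <- function(profile = c("desk", "tiny", "reference"),
                              seed = 1L, ...) {
  profile <- match.arg(profile)
  sc <- switch(profile,
    reference = list(n_subjects = 11L, n_blocks = 25L, trials_per_block = 96L),
    desk = list(n_subjects = 11L, n_blocks = 2L, trials_per_block = 24L),
    tiny = list(n_subjects = 3L, n_blocks = 1L, trials_per_block = 24L))
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    n_subjects = sc$n_subjects,
    schedule = list(n_blocks = sc$n_blocks,
                    trials_per_block = sc$trials_per_block),
    stimulus = list(screen_size = c(1024L, 768L), refresh_rate = 60,
                    frame_extent_px = 153L, inner_extent_px = 115L,
                    offset_px = c(-192L, 192L)),
    fs = 1048,
    trial_spacing_s = 2,
    tms_windows_ms = tms_windows_ms(),
    templates = list(figural_amp = -1.5, surface_amp = 1.0),
    noise = list(),
    behavior = list(sham = FALSE),
    preproc = list(fs_target = 256, laplacian = TRUE),
    stats = list(q = 0.05,
                 window_figure = c(80, 230),
                 window_surface = c(200, 350),
                 window_cumulative = c(227, 313))
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- c("fg_config", "list")
  cfg
}

#' Read / write an experiment configuration as YAML
#'
#' Round-trips losslessly for all default-valued fields.
#'
#' @param config `fg_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("fg_config", "list")
  cfg
}

config_objects <- function(config) {
  list(
    schedule = build_schedule(config$schedule$n_blocks,
                              config$schedule$trials_per_block,
                              seed = config$seed),
    templates = do.call(erp_templates, config$templates %||% list()),
    noise = do.call(noise_model, config$noise %||% list()),
    behavior = do.call(behavior_model, config$behavior %||% list()),
    artifact = tms_artifact_model(),
    preproc = do.call(preproc_config, config$preproc %||% list())
  )
}

#' Run the full simulate -> preprocess -> stats experiment
#'
#' Simulates a cohort from the configuration, preprocesses every subject
#' (all-trials and correct-only ERP sets), computes the behavioral
#' statistics (RT/accuracy filters, both 3 x 4 within-subject ANOVAs,
#' error types), the sample-wise FDR difference-wave tests per TMS
#' condition, the cumulative 227-313 ms stack-frame statistic, and a
#' recovery report comparing the detected significant intervals with the
#' injected template windows.
#'
#' @param config [experiment_config()].
#' @return list of class `fg_experiment`: `behavior`, `eeg` (per-contrast
#'   per-condition `fg_sample_test`s), `cumulative` (all and
#'   correct-only), `recovery`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config("tiny")) {
  t0 <- Sys.time()
  obj <- config_objects(config)
  stage_sums <- list()

  cohort <- simulate_cohort(
    n_subjects = config$n_subjects, schedule = obj$schedule,
    templates = obj$templates, artifact = obj$artifact,
    noise = obj$noise, behavior = obj$behavior,
    fs = config$fs, trial_spacing_s = config$trial_spacing_s,
    seed = config$seed)
  stage_sums$simulate <- object_checksum(cohort$behavior)

  erps_all <- lapply(cohort$recordings, function(r) {
    run_preprocessing(r, obj$preproc)$erps
  })
  cfg_correct <- obj$preproc
  cfg_correct$trials <- "correct"
  erps_correct <- lapply(cohort$recordings, function(r) {
    run_preprocessing(r, cfg_correct)$erps
  })
  stage_sums$preprocess <- object_checksum(erps_all)

  beh <- filter_behavior(cohort$behavior)
  behavior <- behavior_stats(beh)

  q <- config$stats$q
  eeg <- list()
  for (cc in tms_conditions_4) {
    eeg[[cc]] <- list(
      figure_homogenous = tryCatch(
        samplewise_fdr_ttest(
          difference_waves(erps_all, "figure-homogenous", cc),
          config$stats$window_figure, q),
        figseg_masked_error = function(e) e,
        figseg_input_error = function(e) e),
      stack_frame = tryCatch(
        samplewise_fdr_ttest(
          difference_waves(erps_all, "stack-frame", cc),
          config$stats$window_surface, q),
        figseg_masked_error = function(e) e,
        figseg_input_error = function(e) e))
  }
  # at fixture scale a kind x condition cell can lose all its (correct)
  # trials; the failing variant is then reported as its condition object
  cumulative <- list(
    all = tryCatch(
      cumulative_diff_test(erps_all,
                           window = config$stats$window_cumulative,
                           trial_subset = "all"),
      figseg_input_error = function(e) e),
    correct = tryCatch(
      cumulative_diff_test(erps_correct,
                           window = config$stats$window_cumulative,
                           trial_subset = "correct"),
      figseg_input_error = function(e) e))
  stage_sums$stats <- object_checksum(list(behavior, cumulative))

  recovery <- data.frame(
    contrast = c("figure-homogenous", "stack-frame"),
    injected_start = c(obj$templates$figural$window_ms[1],
                       obj$templates$surface$window_ms[1]),
    injected_end = c(obj$templates$figural$window_ms[2],
                     obj$templates$surface$window_ms[2]),
    jaccard = c(
      recovery_jaccard(eeg$none$figure_homogenous,
                       obj$templates$figural$window_ms),
      recovery_jaccard(eeg$none$stack_frame,
                       obj$templates$surface$window_ms)))

  manifest <- list(
    config_checksum = object_checksum(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("figseg")),
    stage_checksums = stage_sums,
    started = format(t0), finished = format(Sys.time()))

  structure(list(behavior = behavior, eeg = eeg, cumulative = cumulative,
                 recovery = recovery, manifest = manifest,
                 erps = erps_all, erps_correct = erps_correct,
                 behavior_table = beh),
            class = "fg_experiment")
}

recovery_jaccard <- function(test, window) {
  if (!inherits(test, "fg_sample_test")) return(NA_real_)
  in_win <- test$table$time_ms >= test$window[1] &
    test$table$time_ms <= test$window[2]
  interval_jaccard(test$table$sig[in_win], test$table$time_ms[in_win],
                   window)
}

#' Generate the bundled miniature datasets
#'
#' Writes a deterministic miniature cohort: the trial schedule (CSV), the
#' pooled behavior table (CSV), and one subject's recording as a
#' BrainVision triplet. `tiny` is 3 subjects x 24 trials; `desk` is
#' 11 subjects x 48 trials.
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param dir output directory.
#' @param seed master seed.
#' @return invisibly, the written paths.
#' @export
make_fixtures <- function(scale = c("tiny", "desk"), dir, seed = 20260928) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (scale == "tiny") "tiny" else "desk"
  cfg <- experiment_config(profile, seed = seed)
  obj <- config_objects(cfg)
  paths <- character(0)
  paths <- c(paths, write_schedule(obj$schedule,
                                   file.path(dir, "schedule.csv")))
  cohort <- simulate_cohort(
    n_subjects = cfg$n_subjects, schedule = obj$schedule,
    templates = obj$templates, noise = obj$noise, behavior = obj$behavior,
    fs = cfg$fs, trial_spacing_s = cfg$trial_spacing_s, seed = seed)
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  paths <- c(paths, file.path(dir, "behavior.csv"))
  paths <- c(paths, write_brainvision(cohort$recordings[[1]],
                                      file.path(dir, "subject01")))
  invisible(paths)
}
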