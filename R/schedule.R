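kinds_3 <- c("stack", "frame", "homogenous")
tms_conditions_4 <- c("none", "early", "intermediate", "late")

#' Build a randomized, balanced trial schedule
#'
#' The experiment crosses 3 stimulus kinds with 4 TMS conditions (none,
#' early, intermediate, late), giving 12 trial types. Within every block
#' each type occurs exactly `trials_per_block / 12` times in randomized
#' order; the canonical session set of 25 blocks x 96 trials therefore
#' yields 200 trials per type, and the sham session of 48 blocks x 12
#' trials yields 576 trials in total.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block; must be divisible by 12.
#' @param seed master seed; per-trial seeds are derived with
#'   [derive_seed()] from the running trial counter.
#' @return data.frame of class `fg_schedule` with columns `block`, `trial`
#'   (within block), `kind`, `tms`, `seed`.
#' @export
build_schedule <- function(n_blocks = 25L, trials_per_block = 96L, seed = 1L) {
  fg_assert(n_blocks >= 1, "input", "n_blocks must be >= 1")
  fg_assert(trials_per_block %% 12 == 0, "input",
            "trials_per_block (%d) must be divisible by the 12 trial types",
            trials_per_block)
  set.seed(as.integer(seed))
  types <- expand.grid(kind = kinds_3, tms = tms_conditions_4,
                       stringsAsFactors = FALSE)
  reps <- trials_per_block %/% 12L
  blocks <- lapply(seq_len(n_blocks), function(b) {
    ord <- sample(rep(seq_len(12L), reps))
    data.frame(block = b, trial = seq_len(trials_per_block),
               kind = types$kind[ord], tms = types$tms[ord])
  })
  out <- do.call(rbind, blocks)
  out$seed <- derive_seed(seed, seq_len(nrow(out)))
  class(out) <- c("fg_schedule", "data.frame")
  out
}

#' TMS pulse-pair onset windows (ms after stimulus onset)
#'
#' A double pulse at 45 Hz: the second pulse follows the first within
#' 23 ms. The three stimulation windows are early 96-119 ms, intermediate
#' 156-179 ms and late 236-259 ms.
#'
#' @return named list of `c(first, second)` pulse onsets in ms.
#' @export
tms_windows_ms <- function() {
  list(early = c(96, 119), intermediate = c(156, 179), late = c(236, 259))
}

#' Pilot stimulation windows
#'
#' The stimulation timing pilot probed 23-ms double-pulse windows starting
#' at 56 ms and stepping by 20 ms up to a final window ending at 339 ms,
#' i.e. 14 windows.
#'
#' @return data.frame with `onset_ms`, `offset_ms`.
#' @export
pilot_windows <- function() {
  onset <- seq(56, 339 - 23, by = 20)
  data.frame(onset_ms = onset, offset_ms = onset + 23)
}

#' Export / import a trial schedule as CSV
#'
#' @param schedule `fg_schedule`.
#' @param path CSV file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the schedule.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial", "kind", "tms", "seed")
  fg_assert(all(need %in% names(out)), "input",
            "schedule file lacks columns: %s",
            paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("fg_schedule", "data.frame")
  out
}
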