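# Minimal BrainVision Core Data Format 1.0 I/O: multiplexed IEEE float32
# binary data with text .vhdr/.vmrk sidecars. Covers what the package's
# own recordings need (labels, sampling rate, stimulus + TMS markers).

#' Write a recording as a BrainVision triplet
#'
#' @param recording `fg_recording` (the `clean` ground-truth stream and
#'   montage coordinates are not part of the format and are dropped).
#' @param basename path without extension; writes `basename.vhdr`,
#'   `basename.vmrk`, `basename.eeg`.
#' @return invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(recording, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  n_ch <- nrow(recording$data)
  con <- file(vhdr, "w")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / recording$fs, digits = 12)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), recording$labels)
  ), con)
  close(con)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "",
          "[Common Infos]",
          paste0("DataFile=", basename(eeg)),
          "",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  i <- 2L
  ev <- recording$events
  for (r in seq_len(nrow(ev))) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%s_%s,%d,1,0", i, ev$kind[r],
                        ev$tms[r], ev$sample[r]))
    i <- i + 1L
  }
  if (nrow(recording$pulses) > 0) {
    for (r in seq_len(nrow(recording$pulses))) {
      mk <- c(mk, sprintf("Mk%d=TMS,T%s,%d,1,0", i,
                          recording$pulses$condition[r],
                          recording$pulses$sample[r]))
      i <- i + 1L
    }
  }
  writeLines(mk, vmrk)

  bcon <- file(eeg, "wb")
  writeBin(as.numeric(recording$data), bcon, size = 4, endian = "little")
  close(bcon)
  invisible(vhdr)
}

bv_section <- function(lines, name) {
  starts <- grep("^\\[", lines)
  s <- grep(paste0("^\\[", name, "\\]"), lines)
  if (length(s) == 0) return(character(0))
  nxt <- starts[starts > s[1]]
  end <- if (length(nxt)) nxt[1] - 1 else length(lines)
  lines[(s[1] + 1):end]
}

bv_value <- function(lines, key) {
  l <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (length(l) == 0) return(NULL)
  sub(paste0("^", key, "="), "", l[1])
}

#' Read a BrainVision triplet written by [write_brainvision()]
#'
#' Supports multiplexed IEEE float32 binary data. Stimulus markers of the
#' form `Skind_tms` are decoded back into an event table, `Tcondition`
#' markers into the TMS pulse table.
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @return `fg_recording` (without ground-truth stream; montage
#'   coordinates re-attached from [standard_montage()] when all labels
#'   match).
#' @export
read_brainvision <- function(vhdr_path) {
  hdr <- readLines(vhdr_path, warn = FALSE)
  common <- bv_section(hdr, "Common Infos")
  fg_assert(identical(bv_value(common, "DataFormat"), "BINARY") &&
              identical(bv_value(common, "DataOrientation"), "MULTIPLEXED"),
            "input", "only BINARY/MULTIPLEXED BrainVision data supported")
  fg_assert(identical(bv_value(bv_section(hdr, "Binary Infos"),
                               "BinaryFormat"), "IEEE_FLOAT_32"),
            "input", "only IEEE_FLOAT_32 BrainVision data supported")
  n_ch <- as.integer(bv_value(common, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_value(common, "SamplingInterval"))
  chans <- bv_section(hdr, "Channel Infos")
  labels <- vapply(chans, function(l) {
    strsplit(sub("^Ch[0-9]+=", "", l), ",")[[1]][1]
  }, character(1), USE.NAMES = FALSE)

  dir <- dirname(vhdr_path)
  eeg <- file.path(dir, bv_value(common, "DataFile"))
  sz <- file.info(eeg)$size
  n_samp <- as.integer(sz / 4 / n_ch)
  bcon <- file(eeg, "rb")
  raw <- readBin(bcon, "numeric", n = n_ch * n_samp, size = 4,
                 endian = "little")
  close(bcon)
  data <- matrix(raw, nrow = n_ch, dimnames = list(labels, NULL))

  vmrk <- file.path(dir, bv_value(common, "MarkerFile"))
  mklines <- bv_section(readLines(vmrk, warn = FALSE), "Marker Infos")
  events <- data.frame(sample = integer(0), time_s = numeric(0),
                       trial = integer(0), kind = character(0),
                       tms = character(0), correct = logical(0))
  pulses <- data.frame(sample = integer(0), condition = character(0),
                       trial = integer(0))
  tr <- 0L
  for (l in mklines) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", l), ",")[[1]]
    if (parts[1] == "Stimulus") {
      tr <- tr + 1L
      kt <- strsplit(sub("^S", "", parts[2]), "_")[[1]]
      events <- rbind(events, data.frame(
        sample = as.integer(parts[3]),
        time_s = (as.integer(parts[3]) - 1) / fs, trial = tr,
        kind = kt[1], tms = kt[2], correct = NA))
    } else if (parts[1] == "TMS") {
      pulses <- rbind(pulses, data.frame(
        sample = as.integer(parts[3]),
        condition = sub("^T", "", parts[2]), trial = NA_integer_))
    }
  }
  mont <- standard_montage()
  if (!all(labels %in% mont$label)) mont <- NULL
  structure(list(data = data, clean = NULL, components = NULL, fs = fs,
                 labels = labels, montage = mont, events = events,
                 pulses = pulses, behavior = NULL, subject = NA,
                 seed = NA_integer_),
            class = "fg_recording")
}
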