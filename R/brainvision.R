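## BrainVision (.vhdr/.vmrk/.eeg) export and import for continuous
## recordings, plus the package's CSV event dialect. The binary data file is
## multiplexed, little-endian, either IEEE float32 or int16 with a stated
## resolution (0.1 uV, matching the acquisition system's amplitude
## resolution).

#' Write a recording as a BrainVision triplet
#'
#' @param rec a `continuous_recording`.
#' @param basename path without extension; writes `<basename>.vhdr`,
#'   `.vmrk`, `.eeg` and `<basename>_events.csv`.
#' @param dialect `"float32"` (lossless) or `"int16"` (0.1 uV resolution).
#' @return invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, basename, dialect = c("float32", "int16")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "continuous_recording"))
  base <- basename(basename)
  C <- nrow(rec$data)
  resolution <- if (dialect == "int16") 0.1 else 1
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", C),
    sprintf("SamplingInterval=%g", 1e6 / rec$fs),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s",
            if (dialect == "int16") "INT_16" else "IEEE_FLOAT_32"),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,µV", seq_len(C), rec$channel_labels, resolution))
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = TRUE)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0")
  if (nrow(rec$events)) {
    code <- ifelse(rec$events$hand == "left", "S  1", "S  2")
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L, code,
                          rec$events$onset_sample))
  }
  writeLines(mrk, paste0(basename, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  x <- as.vector(rec$data)              # multiplexed: channels fastest
  if (dialect == "int16") {
    writeBin(as.integer(round(x / resolution)), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  write_events_csv(rec$events, paste0(basename, "_events.csv"))
  invisible(paste0(basename, ".vhdr"))
}

#' Read a BrainVision triplet
#'
#' Parses the `.vhdr` header (multiplexed binary layout, IEEE float32 or
#' int16), loads the data and events. Events are taken from the sidecar
#' `<basename>_events.csv` if present, otherwise reconstructed from the
#' `.vmrk` stimulus markers (`S  1` = left, `S  2` = right).
#'
#' @param vhdr path to the `.vhdr` file.
#' @param layout optional layout data.frame; defaults to
#'   [equidistant_layout()] of the channel count.
#' @return a `continuous_recording`.
#' @export
read_brainvision <- function(vhdr, layout = NULL) {
  lines <- readLines(vhdr, encoding = "UTF-8", warn = FALSE)
  get <- function(key) {
    m <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(m)) stop_cfg("missing header field %s", key)
    sub(sprintf("^%s=", key), "", m[1])
  }
  if (!identical(get("DataOrientation"), "MULTIPLEXED"))
    stop_cfg("only MULTIPLEXED orientation is supported")
  C <- as.integer(get("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get("SamplingInterval"))
  fmt <- get("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, "", 1)
  resolution <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  dir <- dirname(vhdr)
  eeg_path <- file.path(dir, get("DataFile"))
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "INT_16") {
    x <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
    data <- matrix(as.double(x), nrow = C) * resolution
  } else if (fmt == "IEEE_FLOAT_32") {
    x <- readBin(con, "double", n = sz / 4, size = 4, endian = "little")
    data <- matrix(x, nrow = C)
  } else stop_cfg("unsupported BinaryFormat %s", fmt)

  csv <- sub("\\.vhdr$", "_events.csv", vhdr)
  events <- if (file.exists(csv)) read_events_csv(csv) else {
    mlines <- readLines(file.path(dir, sub("\\.eeg$", ".vmrk",
                                           get("DataFile"))), warn = FALSE)
    stim <- grep("^Mk[0-9]+=Stimulus", mlines, value = TRUE)
    p <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
    ev <- data.frame(
      onset_sample = as.integer(vapply(p, `[`, "", 3)),
      hand = ifelse(gsub(" ", "", vapply(p, `[`, "", 2)) == "S1",
                    "left", "right"),
      run = "T", block = 1L, stringsAsFactors = FALSE)
    ev$trial_index <- seq_len(nrow(ev))
    class(ev) <- c("event_table", "data.frame")
    ev
  }
  structure(list(data = data, fs = fs, channel_labels = labels,
                 layout = layout %||% equidistant_layout(C),
                 events = events),
            class = "continuous_recording")
}

#' Write / read the CSV event dialect
#'
#' Columns: `onset_sample`, `hand`, `run`, `block`, `trial_index`.
#' @param events an `event_table`.
#' @param path CSV path.
#' @return `write_events_csv` returns the path invisibly;
#'   `read_events_csv` returns an `event_table`.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("onset_sample", "hand", "run",
                                             "block", "trial_index")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1))
  req <- c("onset_sample", "hand", "run", "block", "trial_index")
  if (!all(req %in% hdr))
    stop_cfg("event CSV must have columns %s", paste(req, collapse = ", "))
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(run = "character",
                                       hand = "character"))
  class(ev) <- c("event_table", "data.frame")
  ev
}
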