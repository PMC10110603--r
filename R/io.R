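#' Write / read a trace as delimited text with a sidecar metadata file
#'
#' Traces travel as two-column delimited text (`time_s`, `value`) plus a
#' plain-text sidecar (`<path>.meta`) with `key: value` lines carrying
#' `sampling_rate_hz`, `units` and `channel`.  Reading refuses unit-less
#' input rather than guessing pA versus nA.
#'
#' @param trace An [ephys_trace()].
#' @param path Output path for the data file; the sidecar is written to
#'   `paste0(path, ".meta")`.
#' @return `write_trace()` returns `path` invisibly; `load_trace()` returns
#'   an [ephys_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  dt <- data.table::data.table(time_s = trace_times(trace),
                               value = trace$samples)
  data.table::fwrite(dt, path, sep = "\t")
  writeLines(c(paste0("sampling_rate_hz: ", format(trace$sampling_rate, digits = 15)),
               paste0("units: ", trace$units),
               paste0("channel: ", trace$channel)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trace
#' @param meta_path Sidecar path (default `paste0(path, ".meta")`).
#' @export
load_trace <- function(path, meta_path = paste0(path, ".meta")) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(meta_path)) stop("sidecar metadata file not found: ", meta_path)
  meta <- .read_sidecar(meta_path)
  for (field in c("sampling_rate_hz", "units")) {
    if (is.null(meta[[field]])) {
      stop("sidecar ", meta_path, " is missing required field '", field, "'")
    }
  }
  dt <- data.table::fread(path)
  if (ncol(dt) < 2) stop("trace file must have columns time_s, value")
  ephys_trace(dt[[2]], as.numeric(meta$sampling_rate_hz), meta$units,
              channel = meta$channel %||% "ch1", t0 = dt[[1]][1])
}

.read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed sidecar line: ", lines[bad][1])
  stats::setNames(lapply(kv, `[`, 3), trimws(vapply(kv, `[`, "", 2)))
}

#' Read annotation intervals from CSV
#'
#' Annotations are `start_s`, `end_s`, `label` rows (e.g. `nonrem` baseline
#' stretches and `artifact` intervals).
#'
#' @param path CSV path.
#' @return data.frame with columns `start_s`, `end_s`, `label`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  ann[need]
}

#' Minimal EDF (European Data Format) writer and reader
#'
#' Standard 16-bit EDF: 256-byte fixed header, 256 bytes per signal header,
#' little-endian int16 data records with linear physical scaling.  One
#' second per data record; the signal is truncated to whole records with a
#' warning if needed.  Covers the single- or multi-channel continuous
#' recordings this package analyzes (no EDF+ annotations).
#'
#' @param signals Named list of numeric vectors (equal lengths), physical
#'   units microvolts.
#' @param path Output path.
#' @param sampling_rate Hz (integer samples per 1-s record).
#' @param units Physical dimension label (default `"uV"`).
#' @return `write_edf()` returns `path` invisibly.  `read_edf()` returns a
#'   list with `signals` (named list), `sampling_rate`, `units`, `header`.
#' @export
write_edf <- function(signals, path, sampling_rate, units = "uV") {
  if (!is.list(signals) || is.null(names(signals))) {
    signals <- stats::setNames(list(as.numeric(signals)), "EEG1")
  }
  fs <- as.integer(round(sampling_rate))
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1) stop("all signals must have equal length")
  n_rec <- n %/% fs
  if (n_rec * fs != n) {
    warning("signal truncated to ", n_rec, " whole 1-s records")
  }
  if (n_rec < 1) stop("signal shorter than one 1-s record")
  ns <- length(signals)
  pad <- function(x, w) {
    s <- substr(format(x), 1, w)
    formatC(s, width = -w, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("chloropatch", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8),
                pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  phys_min <- vapply(signals, function(s) floor(min(s, -1)), numeric(1))
  phys_max <- vapply(signals, function(s) ceiling(max(s, 1)), numeric(1))
  f1 <- function(fmt) paste0(vapply(seq_len(ns), fmt, character(1)), collapse = "")
  writeChar(f1(function(k) pad(names(signals)[k], 16)), con, eos = NULL)
  writeChar(f1(function(k) pad("synthetic electrode", 80)), con, eos = NULL)
  writeChar(f1(function(k) pad(units, 8)), con, eos = NULL)
  writeChar(f1(function(k) pad(phys_min[k], 8)), con, eos = NULL)
  writeChar(f1(function(k) pad(phys_max[k], 8)), con, eos = NULL)
  writeChar(f1(function(k) pad(-32768, 8)), con, eos = NULL)
  writeChar(f1(function(k) pad(32767, 8)), con, eos = NULL)
  writeChar(f1(function(k) pad("none", 80)), con, eos = NULL)
  writeChar(f1(function(k) pad(fs, 8)), con, eos = NULL)
  writeChar(f1(function(k) pad("", 32)), con, eos = NULL)
  scale <- (phys_max - phys_min) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      seg <- signals[[k]][((r - 1L) * fs + 1L):(r * fs)]
      dig <- as.integer(round((seg - phys_min[k]) / scale[k]) - 32768)
      dig <- pmin(32767L, pmax(-32768L, dig))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  rdv <- function(w) vapply(seq_len(ns), function(k) rd(w), character(1))
  labels <- rdv(16); transducer <- rdv(80); dims <- rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  prefilter <- rdv(80); spr <- as.integer(rdv(8)); rd(32 * ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- lapply(seq_len(ns), function(k) numeric(n_rec * spr[k]))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[k], size = 2, signed = TRUE,
                     endian = "little")
      signals[[k]][((r - 1L) * spr[k] + 1L):(r * spr[k])] <-
        phys_min[k] + (dig - dig_min[k]) * gain[k]
    }
  }
  names(signals) <- labels
  list(signals = signals,
       sampling_rate = spr / rec_dur,
       units = dims,
       header = list(version = version, patient = patient,
                     recording = recording, date = date, time = time,
                     n_records = n_rec, record_duration = rec_dur,
                     n_signals = ns, labels = labels))
}

#' Load an EEG recording from EDF or delimited text
#'
#' @param path `.edf` file, or a delimited trace file with sidecar (see
#'   [load_trace()]; units must be microvolts).
#' @param channel Channel label to select from a multi-channel EDF
#'   (default: first channel).
#' @param annotations Optional annotation CSV path or data.frame
#'   (see [read_annotations()]).
#' @return An [eeg_recording()].
#' @export
load_eeg <- function(path, channel = NULL, annotations = NULL) {
  ann <- if (is.character(annotations)) read_annotations(annotations) else annotations
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    k <- if (is.null(channel)) 1L else match(channel, names(edf$signals))
    if (is.na(k)) stop("channel '", channel, "' not found in ", path)
    eeg_recording(edf$signals[[k]], edf$sampling_rate[k], annotations = ann)
  } else {
    tr <- load_trace(path)
    if (!tr$units %in% c("uV", "µV", "microvolt", "microvolts")) {
      stop("EEG trace units must be microvolts; got '", tr$units, "'")
    }
    eeg_recording(tr$samples, tr$sampling_rate, annotations = ann)
  }
}
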