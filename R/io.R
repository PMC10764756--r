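#' Multi-channel EEG recording
#'
#' Constructs an `eeg_recording`: one subject's multi-channel EEG time series
#' together with its sampling rate and ordered channel labels. Samples are
#' stored as a numeric matrix with one column per channel.
#'
#' @param data numeric matrix, samples x channels.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channels character vector of unique channel labels (10-10 names,
#'   e.g. `"P8"`), one per column of `data`.
#' @param subject_id subject identifier.
#' @return An object of class `eeg_recording` with elements `subject_id`,
#'   `fs`, `channels` and `data`.
#' @export
eeg_recording <- function(data, fs, channels, subject_id = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stop("recording has zero-length channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  channels <- as.character(channels)
  if (length(channels) != ncol(data))
    stop(sprintf("channel label count (%d) does not match data columns (%d)",
                 length(channels), ncol(data)))
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  colnames(data) <- channels
  structure(
    list(subject_id = as.character(subject_id), fs = as.numeric(fs),
         channels = channels, data = data),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$channels), nrow(x$data), x$fs,
              nrow(x$data) / x$fs))
  invisible(x)
}

#' Number of samples per channel
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Extract one channel from a recording
#' @param rec an `eeg_recording`.
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% rec$channels)
    stop(sprintf("channel '%s' not present in recording '%s'",
                 channel, rec$subject_id))
  rec$data[, channel]
}

#' Read an EEG recording
#'
#' Reads one recording in one of three dialects: BrainVision
#' (`.vhdr`/`.eeg`, binary IEEE float-32 / int-16 or ASCII data),
#' EDF (European Data Format), or the plain matrix dialect (delimited
#' samples-by-channels text plus a JSON sidecar holding `fs` and `channels`).
#'
#' @param path path to the header file (`.vhdr` for BrainVision, `.edf` for
#'   EDF, the data file for the matrix dialect).
#' @param dialect one of `"brainvision"`, `"edf"`, `"matrix"`.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param sidecar for `dialect = "matrix"`, path to the JSON sidecar; defaults
#'   to `path` with its extension replaced by `.json`.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, dialect = c("matrix", "brainvision", "edf"),
                           subject_id = NULL, sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  switch(dialect,
    matrix      = read_matrix_recording(path, sidecar, subject_id),
    brainvision = read_brainvision(path, subject_id),
    edf         = read_edf(path, subject_id))
}

read_matrix_recording <- function(path, sidecar, subject_id) {
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  if (!file.exists(sidecar))
    stop(sprintf("matrix dialect requires a JSON sidecar; not found: %s",
                 sidecar))
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs) || is.null(meta$channels))
    stop("sidecar must provide 'fs' and 'channels'")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, sep = sep, header = FALSE)
  dat <- as.matrix(dat)
  if (ncol(dat) != length(meta$channels))
    stop(sprintf("data has %d columns but sidecar lists %d channels",
                 ncol(dat), length(meta$channels)))
  eeg_recording(dat, meta$fs, meta$channels, subject_id)
}

#' Write a recording in the matrix dialect
#'
#' Writes the samples-by-channels CSV and its JSON sidecar.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_matrix_recording <- function(rec, path) {
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channels),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal BrainVision reader: INI-style .vhdr header plus a data file in
# MULTIPLEXED or VECTORIZED orientation, BINARY (IEEE_FLOAT_32 / INT_16) or
# ASCII format. Resolution scaling is applied for INT_16.
read_brainvision <- function(path, subject_id) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list(); chans <- character(); resolutions <- numeric()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("^\\[|\\]$", "", ln); next }
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (section == "Channel Infos" && grepl("^Ch[0-9]+$", key)) {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      chans <- c(chans, trimws(parts[1]))
      res <- if (length(parts) >= 3 && nzchar(trimws(parts[3])))
        as.numeric(trimws(parts[3])) else 1
      resolutions <- c(resolutions, res)
    } else {
      kv[[paste(section, key)]] <- val
    }
  }
  need <- function(k) {
    v <- kv[[k]]
    if (is.null(v)) stop(sprintf("BrainVision header missing '%s'", k))
    v
  }
  n_chan <- as.integer(need("Common Infos NumberOfChannels"))
  samp_int_us <- as.numeric(need("Common Infos SamplingInterval"))
  fs <- 1e6 / samp_int_us
  fmt <- toupper(need("Common Infos DataFormat"))
  orient <- toupper(kv[["Common Infos DataOrientation"]] %||% "MULTIPLEXED")
  datafile <- file.path(dirname(path), need("Common Infos DataFile"))
  if (!file.exists(datafile))
    stop(sprintf("BrainVision data file not found: %s", datafile))
  if (length(chans) != n_chan)
    stop(sprintf("header declares %d channels but lists %d channel entries",
                 n_chan, length(chans)))
  if (fmt == "ASCII") {
    raw <- scan(datafile, what = double(), quiet = TRUE)
  } else {
    binfmt <- toupper(kv[["Binary Infos BinaryFormat"]] %||% "IEEE_FLOAT_32")
    sz <- file.info(datafile)$size
    if (binfmt == "IEEE_FLOAT_32") {
      raw <- readBin(datafile, "double", n = sz %/% 4, size = 4,
                     endian = "little")
    } else if (binfmt == "INT_16") {
      raw <- readBin(datafile, "integer", n = sz %/% 2, size = 2,
                     signed = TRUE, endian = "little")
    } else stop(sprintf("unsupported BinaryFormat '%s'", binfmt))
  }
  if (length(raw) %% n_chan != 0L)
    stop(sprintf(
      "data stream length %d is not a multiple of the %d declared channels",
      length(raw), n_chan))
  n <- length(raw) %/% n_chan
  if (n == 0L) stop("zero-length channels in BrainVision data")
  dat <- if (orient == "VECTORIZED") {
    matrix(raw, nrow = n, ncol = n_chan)
  } else {
    t(matrix(raw, nrow = n_chan, ncol = n))
  }
  dat <- sweep(dat, 2, resolutions, `*`)
  eeg_recording(dat, fs, chans, subject_id)
}

# Minimal EDF reader: 256-byte ASCII global header, 256 bytes of per-signal
# header fields, data records of little-endian int16 scaled from digital to
# physical units.
read_edf <- function(path, subject_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("truncated EDF header")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("EDF header declares no signals")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  take <- function(from, len) {
    vapply(seq_len(ns), function(i)
      fld(sig_hdr, from + (i - 1) * len, len), "")
  }
  # signal header layout: label(16) transducer(80) dim(8) physmin(8)
  # physmax(8) digmin(8) digmax(8) prefilter(80) nsamp(8) reserved(32)
  off <- 0
  labels <- take(off + 1, 16); off <- off + 16 * ns
  off <- off + 80 * ns                       # transducer
  off <- off + 8 * ns                        # physical dimension
  phys_min <- as.numeric(take(off + 1, 8)); off <- off + 8 * ns
  phys_max <- as.numeric(take(off + 1, 8)); off <- off + 8 * ns
  dig_min <- as.numeric(take(off + 1, 8)); off <- off + 8 * ns
  dig_max <- as.numeric(take(off + 1, 8)); off <- off + 8 * ns
  off <- off + 80 * ns                       # prefiltering
  nsamp <- as.integer(take(off + 1, 8))
  if (length(unique(nsamp)) != 1L)
    stop("EDF signals with differing samples-per-record are not supported")
  fs <- nsamp[1] / rec_dur
  dat <- matrix(0, nrow = n_rec * nsamp[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[s], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < nsamp[s]) stop("truncated EDF data record")
      gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      dat[((r - 1) * nsamp[s] + 1):(r * nsamp[s]), s] <-
        phys_min[s] + (v - dig_min[s]) * gain
    }
  }
  eeg_recording(dat, fs, labels, subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a subject score table
#'
#' Reads a delimited subject table with columns `id`, `age`, `sex`, `group`
#' (PD / control), `moca`, and optionally the NIH-Toolbox scores (`pvt`,
#' `pcpst`, `dccst`, `ficat`, `psmt`), `updrs`, `ledd`, `duration`, `gds`.
#' Empty cells are read as missing.
#'
#' @param path CSV/TSV path.
#' @return data.frame with one row per subject, ids unique, MoCA validated to
#'   lie in 0..30 where present.
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  names(tab) <- tolower(names(tab))
  validate_subject_table(tab)
  tab
}

validate_subject_table <- function(tab) {
  for (col in c("id", "age", "sex", "group"))
    if (!col %in% names(tab))
      stop(sprintf("subject table is missing required column '%s'", col))
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("subject ids must be unique")
  if ("moca" %in% names(tab)) {
    bad <- !is.na(tab$moca) & (tab$moca < 0 | tab$moca > 30)
    if (any(bad))
      stop("MoCA scores must lie in [0, 30]")
  }
  invisible(tab)
}
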