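## BrainVision core format: a .vhdr INI header describing a .eeg binary
## (multiplexed float32 or int16-with-resolution, uV) and a .vmrk marker
## file with sample positions. No installed R package reads this dialect,
## so the reader/writer is implemented here.

bv_crlf <- "\r\n"

parse_ini <- function(lines) {
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1L]]
    if (length(m) == 2L) {
      sec <- m[2L]
      out[[sec]] <- character()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L && is.null(sec)) next   # free-text preamble line
    if (eq < 0L || is.null(sec))
      stop("malformed INI line outside a [Section]: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    out[[sec]][key] <- substr(ln, eq + 1L, nchar(ln))
  }
  out
}

ini_get <- function(ini, section, key) {
  if (is.null(ini[[section]]) || is.na(ini[[section]][key]))
    stop(sprintf("missing [%s] %s entry in BrainVision header", section, key))
  unname(ini[[section]][key])
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` INI header, the `.vmrk` markers and the multiplexed
#' `.eeg` binary (IEEE float32, or int16 scaled by the per-channel
#' resolution), returning data in microvolts. Unix or CRLF line endings are
#' accepted.
#'
#' @param header_path path to the `.vhdr` file.
#' @return List with `data` (channels x samples matrix, uV),
#'   `channel_names`, `sampling_rate` (Hz), and `markers` (data.frame with
#'   `type`, `description`, `position` in samples, 1-based).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("no such header file: ", header_path)
  ini <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- "Common Infos"
  fmt <- ini_get(ini, ci, "DataFormat")
  if (toupper(fmt) != "BINARY") stop("unsupported DataFormat: ", fmt)
  orient <- ini_get(ini, ci, "DataOrientation")
  if (toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  n_ch <- as.integer(ini_get(ini, ci, "NumberOfChannels"))
  srate <- 1e6 / as.numeric(ini_get(ini, ci, "SamplingInterval"))
  binfmt <- toupper(ini_get(ini, "Binary Infos", "BinaryFormat"))
  dir <- dirname(header_path)
  eeg_path <- file.path(dir, ini_get(ini, ci, "DataFile"))
  vmrk_path <- file.path(dir, ini_get(ini, ci, "MarkerFile"))
  if (!file.exists(eeg_path)) stop("data file not found: ", eeg_path)

  chan <- ini[["Channel Infos"]]
  if (is.null(chan) || length(chan) != n_ch)
    stop(sprintf("header declares %d channels but [Channel Infos] has %d",
                 n_ch, length(chan)))
  parts <- strsplit(unname(chan), ",", fixed = TRUE)
  channel_names <- vapply(parts, `[`, "", 1L)
  resolution <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1, 0)

  sz <- file.info(eeg_path)$size
  if (binfmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4L
    raw <- readBin(eeg_path, "numeric", n = n_val, size = 4L,
                   endian = "little")
  } else if (binfmt == "INT_16") {
    n_val <- sz / 2L
    raw <- readBin(eeg_path, "integer", n = n_val, size = 2L, signed = TRUE,
                   endian = "little")
  } else stop("unknown BinaryFormat: ", binfmt)
  if (n_val %% n_ch != 0)
    stop(sprintf("data size (%d values) is not a multiple of %d channels",
                 n_val, n_ch))
  data <- matrix(raw, nrow = n_ch)            # multiplexed: channels vary fastest
  data <- data * resolution                   # recycles per channel (column-major)
  rownames(data) <- channel_names

  markers <- data.frame(type = character(), description = character(),
                        position = integer())
  if (file.exists(vmrk_path)) {
    mrk <- parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mrk) && length(mrk) > 0L) {
      mp <- strsplit(unname(mrk), ",", fixed = TRUE)
      markers <- data.frame(
        type = vapply(mp, `[`, "", 1L),
        description = vapply(mp, `[`, "", 2L),
        position = as.integer(vapply(mp, `[`, "", 3L)),
        stringsAsFactors = FALSE)
    }
  }
  list(data = data, channel_names = channel_names, sampling_rate = srate,
       markers = markers)
}

#' Write a BrainVision recording
#'
#' Writes the standard `.vhdr`/`.vmrk`/`.eeg` triple (multiplexed binary,
#' CRLF line endings) readable by [read_brainvision()] and by standard EEG
#' software.
#'
#' @param data channels x samples numeric matrix in uV.
#' @param channel_names one unique name per row of `data`.
#' @param sampling_rate Hz.
#' @param markers optional data.frame with `type`, `description`,
#'   `position` (1-based sample index).
#' @param out_prefix path prefix; `<out_prefix>.vhdr` etc. are written.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param resolution uV per bit for `INT_16` (default 0.1).
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(data, channel_names, sampling_rate,
                              markers = NULL, out_prefix,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  binary_format <- match.arg(binary_format)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("data must be finite")
  if (nrow(data) != length(channel_names))
    stop("nrow(data) must equal length(channel_names)")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  base <- basename(out_prefix)
  vhdr <- paste0(out_prefix, ".vhdr")
  vmrk <- paste0(out_prefix, ".vmrk")
  eeg <- paste0(out_prefix, ".eeg")

  res <- if (binary_format == "INT_16") rep(resolution, nrow(data)) else
    rep(1, nrow(data))
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(data)),
    paste0("SamplingInterval=", format(1e6 / sampling_rate, digits = 15)),
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nrow(data)), channel_names,
            format(res, digits = 15, trim = TRUE)))
  con <- file(vhdr, "wb")
  writeBin(charToRaw(paste0(paste(hdr, collapse = bv_crlf), bv_crlf)), con)
  close(con)

  mlines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]")
  if (!is.null(markers) && nrow(markers) > 0L)
    mlines <- c(mlines, sprintf("Mk%d=%s,%s,%d,1,0",
                                seq_len(nrow(markers)), markers$type,
                                markers$description,
                                as.integer(markers$position)))
  con <- file(vmrk, "wb")
  writeBin(charToRaw(paste0(paste(mlines, collapse = bv_crlf), bv_crlf)), con)
  close(con)

  con <- file(eeg, "wb")
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(data), con, size = 4L, endian = "little")
  } else {
    q <- as.integer(round(data / resolution))
    if (any(abs(q) > 32767))
      stop("data exceed the INT_16 range at resolution ", resolution)
    writeBin(q, con, size = 2L, endian = "little")
  }
  close(con)
  invisible(vhdr)
}

#' Export an epoch_set as a BrainVision triple
#'
#' Epochs are concatenated into one continuous multiplexed record with one
#' stimulus marker (`S  1`) at each epoch's time-zero sample, so
#' re-epoching with [epoch_and_baseline()] recovers the original epochs.
#'
#' @param epochs an [epoch_set()].
#' @param out_prefix path prefix for the triple.
#' @param ... passed to [write_brainvision()].
#' @return The header path, invisibly.
#' @export
write_brainvision_epochs <- function(epochs, out_prefix, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(0, d[2L], d[1L] * d[3L])
  for (tr in seq_len(d[1L]))
    flat[, ((tr - 1L) * d[3L] + 1L):(tr * d[3L])] <- epochs$data[tr, , ]
  pos <- (seq_len(d[1L]) - 1L) * d[3L] + epochs$time_zero_index
  markers <- data.frame(type = "Stimulus", description = "S  1",
                        position = pos)
  write_brainvision(flat, epochs$channel_names, epochs$sampling_rate,
                    markers, out_prefix, ...)
}
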