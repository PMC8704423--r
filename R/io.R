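# On-disk formats: WAV for stimuli (IEEE float32 mono), and a versioned
# raw-binary + JSON-sidecar container for epoched recordings.

#' Write a mono waveform as an IEEE-float WAV file
#'
#' @param x Numeric vector in [-1, 1] or a `tone_stimulus`.
#' @param path Output path.
#' @param fs Sampling rate (taken from a `tone_stimulus` automatically).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL) {
  if (inherits(x, "tone_stimulus")) { fs <- x$fs; x <- x$waveform }
  if (is.null(fs)) stop("fs required")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  wb <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wb(4 + 24 + 12 + 8 + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wb(16, 4); wb(3, 2); wb(1, 2)            # IEEE float, mono
  wb(fs, 4); wb(fs * 4, 4); wb(4, 2); wb(32, 2)
  writeChar("fact", con, eos = NULL); wb(4, 4); wb(n, 4)
  writeChar("data", con, eos = NULL); wb(data_bytes, 4)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file (IEEE float32 or 16-bit PCM)
#'
#' @param path WAV file path.
#' @return List: `waveform` (numeric, float scale), `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function() readChar(con, 4, useBytes = TRUE)
  ri <- function(size) readBin(con, "integer", size = size,
                               endian = "little")
  if (rc() != "RIFF") stop("not a RIFF file")
  ri(4)
  if (rc() != "WAVE") stop("not a WAVE file")
  fmt <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- rc()
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- ri(4)
    if (id == "fmt ") {
      fmt <- ri(2); nch <- ri(2); fs <- ri(4); ri(4); ri(2); bits <- ri(2)
      if (nch != 1) stop("only mono WAV supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      x <- if (fmt == 3 && bits == 32)
        readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
      else if (fmt == 1 && bits == 16)
        readBin(con, "integer", n = sz / 2, size = 2,
                endian = "little") / 32768
      else stop("unsupported WAV encoding (format ", fmt, ", ", bits, " bit)")
      return(list(waveform = x, fs = fs))
    } else readBin(con, "raw", sz + sz %% 2)
  }
}

#' Persist an epoched recording (binary array + JSON sidecar)
#'
#' The data array is written as little-endian float64 with samples fastest,
#' then channels, then trials; all metadata (dims, axes, channel table,
#' per-trial labels, format version) goes to `<prefix>.json`.
#'
#' @param epochs An `epoched_recording`.
#' @param prefix Path prefix; writes `<prefix>.bin` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  d <- dim(epochs$data)
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  close(con)
  meta <- list(format = "ffrtools-epochs", version = 1L,
               dims = list(trials = d[1], channels = d[2], samples = d[3]),
               layout = "samples-fastest, then channels, then trials",
               dtype = "float64-le",
               fs = epochs$fs, t0_ms = epochs$t0_ms,
               channel_meta = epochs$channel_meta,
               polarity = epochs$polarity, tone_id = epochs$tone_id)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(prefix)
}

#' Read an epoched recording written by [write_epochs()]
#' @param prefix Path prefix used at write time.
#' @return An `epoched_recording`.
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "ffrtools-epochs"))
    stop("not an ffrtools epochs container")
  d <- c(meta$dims$trials, meta$dims$channels, meta$dims$samples)
  con <- file(paste0(prefix, ".bin"), "rb")
  x <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
  close(con)
  cm <- as.data.frame(meta$channel_meta)
  if (!"depth_um" %in% names(cm)) cm$depth_um <- NA_real_
  epoched_recording(aperm(array(x, dim = rev(d)), c(3, 2, 1)),
                    fs = meta$fs, t0_ms = meta$t0_ms, channel_meta = cm,
                    polarity = meta$polarity, tone_id = meta$tone_id)
}
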