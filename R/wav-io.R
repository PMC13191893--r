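#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel 16-bit PCM, the container used
#' for ultrasonic recordings here (typically 250 kHz sampling). Samples are
#' expected in \code{[-1, 1]}; values outside are clipped.
#'
#' @param waveform numeric vector of samples in \code{[-1, 1]}.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(waveform, fs, path) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, fs > 0)
  x <- pmin(pmax(waveform, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Only uncompressed single-channel 16-bit PCM
#' is supported.
#'
#' @param path WAV file path.
#' @return list with `waveform` (numeric, scaled to \code{[-1, 1]}) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fs <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      ba_bits <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16) invisible(readBin(con, "raw", n = size - 16L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(list(waveform = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
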