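#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit PCM audio. Samples are rescaled to
#' real values in [-1, 1]. Multi-channel files must name the channel to keep.
#'
#' @param path path to a WAV file.
#' @param channel 1-based channel index to extract when the file has more
#'   than one channel.
#' @return list with \code{wave} (numeric vector in [-1, 1]) and
#'   \code{sample_rate} (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_tag <- function() {
    raw4 <- readBin(con, "raw", 4)
    if (length(raw4) < 4) "" else rawToChar(raw4[raw4 != 0])
  }
  if (!identical(read_tag(), "RIFF"))
    stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(read_tag(), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- read_tag()
    if (nchar(id) < 3) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, size = 2,
                     endian = "little", signed = FALSE)
      if (length(fmt) < 8) stop("truncated fmt chunk in ", path)
      if (fmt[1] != 1) stop("only PCM WAV supported (format tag ", fmt[1], ")")
      n_channels <- fmt[2]
      sample_rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("data chunk before fmt chunk in ", path)
      if (bits != 16) stop("only 16-bit PCM supported, got ", bits, " bits")
      n <- size %/% 2
      data <- readBin(con, "integer", n, size = 2, endian = "little")
      if (length(data) < n) stop("truncated data chunk in ", path)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data) || is.null(sample_rate))
    stop("no PCM data found in ", path)
  if (n_channels > 1) {
    if (is.null(channel))
      stop("file has ", n_channels, " channels; pass channel = <index>")
    if (channel < 1 || channel > n_channels)
      stop("channel out of range (file has ", n_channels, ")")
    data <- data[seq(channel, length(data), by = n_channels)]
  }
  list(wave = data / 32767, sample_rate = sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Writes a numeric waveform in [-1, 1] as 16-bit PCM mono. Values outside
#' [-1, 1] are clipped.
#'
#' @param wave numeric vector of samples in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path) {
  stopifnot(is.numeric(wave), length(wave) > 0, sample_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(pmin(1, pmax(-1, wave)) * 32767))))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
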