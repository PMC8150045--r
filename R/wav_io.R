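#' Write a 16-bit PCM WAV file
#'
#' Writes a mono RIFF/WAVE file with canonical 44-byte header. Samples are
#' interpreted as raw ADC counts and clipped to the signed 16-bit range, the
#' storage convention of the autonomous recorders emulated by the synthetic
#' generator.
#'
#' @param samples numeric vector of counts (rounded to integer on write)
#' @param fs sampling rate in Hz
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav_pcm16 <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L, fs > 0)
  x <- as.integer(pmin(pmax(round(samples), -32768), 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Chunk-aware reader for mono 16-bit PCM RIFF files (skips unknown chunks
#' such as LIST/fact). Returns counts, not normalised amplitudes.
#'
#' @param path input file path
#' @return list with `samples` (numeric counts), `fs` (Hz), `n` (sample count)
#' @export
read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NA_integer_
  channels <- NA_integer_
  bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2L, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      channels <- fmt[2L]
      if (fmt[1L] != 1L) stop("only PCM WAV supported: ", path)
      if (sz > 16L) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      if (sz %% 2L == 1L) invisible(readBin(con, raw(), n = 1L))
      break
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (!is.na(channels) && channels != 1L) stop("only mono WAV supported: ", path)
  if (!is.na(bits) && bits != 16L) stop("only 16-bit PCM supported: ", path)
  list(samples = as.numeric(samples), fs = fs, n = length(samples))
}
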