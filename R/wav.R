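#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for rendered stimuli (mono suffices: stimuli are
#' presented diotically).
#'
#' @param x Numeric samples in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 44100) {
  if (max(abs(x)) > 1) stop("samples must lie in [-1, 1]")
  pcm <- as.integer(round(x * 32767))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)            # PCM header size
  w16(1L)             # PCM format
  w16(1L)             # mono
  w32(sample_rate)
  w32(sample_rate * 2L)  # byte rate
  w16(2L)             # block align
  w16(16L)            # bits per sample
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
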