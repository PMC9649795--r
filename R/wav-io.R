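# RIFF/WAVE reading and writing. Supports PCM 8/16/24/32-bit and IEEE float
# 32/64-bit, mono or multichannel (mixed to mono by channel mean on load).
# Written in-package because no audio-file reader ships with the supported
# dependency stack; the format subset covers everything the synthesizers emit.

#' Load an audio file as a mono waveform
#'
#' Reads a RIFF/WAVE file (PCM 8/16/24/32-bit or IEEE float), averages
#' multichannel material to mono, scales samples to \[-1, 1\], and optionally
#' resamples to the canonical analysis rate.
#'
#' @param path Path to a `.wav` file.
#' @param fs_target If non-`NULL`, resample the result to this rate. Default
#'   `NULL` keeps the file's native rate.
#' @param label Stimulus label; defaults to the file name without extension.
#' @return A [waveform()].
#' @export
load_audio <- function(path, fs_target = NULL, label = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("Cannot read audio file '%s': file does not exist.", path),
          class = "roundsound_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file.", path),
          class = "roundsound_format_error")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- parse_fmt_chunk(body, path)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1) # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("'%s' is missing a fmt or data chunk.", path),
          class = "roundsound_format_error")
  }

  x <- decode_samples(data_raw, fmt, path)
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  w <- waveform(x, fmt$fs,
                label %||% sub("\\.[wW][aA][vV]$", "", basename(path)))
  if (!is.null(fs_target)) w <- resample_wave(w, fs_target)
  w
}

parse_fmt_chunk <- function(body, path) {
  u16 <- function(off) {
    sum(as.integer(body[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  format_tag <- u16(0)
  if (format_tag == 65534L && length(body) >= 26) {
    # WAVE_FORMAT_EXTENSIBLE: actual format is the leading GUID word.
    format_tag <- u16(24)
  }
  if (!format_tag %in% c(1L, 3L)) {
    abort(sprintf("'%s': unsupported WAVE format tag %d (PCM and IEEE float only).",
                  path, format_tag),
          class = "roundsound_format_error")
  }
  list(
    format = if (format_tag == 1L) "pcm" else "float",
    n_channels = u16(2),
    fs = u32(4),
    bits = u16(14)
  )
}

decode_samples <- function(raw, fmt, path) {
  n_bytes <- fmt$bits / 8
  n <- floor(length(raw) / n_bytes)
  if (fmt$format == "float") {
    if (!fmt$bits %in% c(32, 64)) {
      abort(sprintf("'%s': unsupported float bit depth %d.", path, fmt$bits),
            class = "roundsound_format_error")
    }
    return(readBin(raw, "double", n, size = n_bytes, endian = "little"))
  }
  switch(
    as.character(fmt$bits),
    "8" = (as.integer(raw[seq_len(n)]) - 128) / 128,
    "16" = readBin(raw, "integer", n, size = 2, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      m <- matrix(as.numeric(raw[seq_len(3 * n)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(raw, "integer", n, size = 4, endian = "little") / 2147483648,
    abort(sprintf("'%s': unsupported PCM bit depth %d.", path, fmt$bits),
          class = "roundsound_format_error")
  )
}

#' Write a waveform to a WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bit_depth 16 or 24 (integer PCM), or 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_audio <- function(w, path, bit_depth = 16) {
  stopifnot(is_waveform(w))
  if (!bit_depth %in% c(16, 24, 32)) {
    abort("bit_depth must be 16, 24, or 32.", class = "roundsound_argument_error")
  }
  x <- clamp(w$samples, -1, 1)
  n_bytes <- bit_depth / 8
  data_size <- length(x) * n_bytes
  fmt_tag <- if (bit_depth == 32) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(round(w$fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$fs) * n_bytes), con, size = 4, endian = "little")
  writeBin(as.integer(n_bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bit_depth == 16) {
    v <- as.integer(round(clamp(x * 32768, -32768, 32767)))
    writeBin(v, con, size = 2, endian = "little")
  } else if (bit_depth == 24) {
    v <- round(clamp(x * 8388608, -8388608, 8388607))
    v <- ifelse(v < 0, v + 16777216, v)
    bytes <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(bytes), con)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
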