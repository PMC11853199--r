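# Minimal RIFF/WAVE codec: integer PCM (8/16/24/32-bit) and IEEE float
# (32/64-bit) on read; 16-bit PCM on write. Amplitudes are mapped to
# [-1, 1] on the file's native full-scale so round trips are quantization-
# bounded. Multichannel files are returned as a samples matrix
# (rows = frames, columns = channels).

read_wav <- function(path) {
  if (!file.exists(path)) {
    stop_respscreen("file not found: %s", path, class = "respscreen_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop_respscreen("not a RIFF file: %s", path,
                    class = "respscreen_format_error")
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop_respscreen("not a WAVE file: %s", path,
                    class = "respscreen_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        format      = le_u16(body, 1L),
        n_channels  = le_u16(body, 3L),
        sample_rate = le_u32(body, 5L),
        bits        = le_u16(body, 15L)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_respscreen("corrupt WAVE file (missing fmt/data chunk): %s", path,
                    class = "respscreen_format_error")
  }
  fmt_code <- fmt$format
  if (fmt_code == 65534L) fmt_code <- 1L  # WAVE_FORMAT_EXTENSIBLE, assume PCM
  bytes_per <- fmt$bits %/% 8L
  n_values <- length(data_raw) %/% bytes_per
  if (n_values == 0L) {
    stop_respscreen("zero-length audio: %s", path,
                    class = "respscreen_empty_input_error")
  }
  x <- decode_pcm(data_raw, fmt_code, fmt$bits, n_values)
  n_frames <- n_values %/% fmt$n_channels
  x <- matrix(x[seq_len(n_frames * fmt$n_channels)],
              nrow = n_frames, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = x, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

le_u16 <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
le_u32 <- function(raw, i) {
  as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
    65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
}

decode_pcm <- function(raw, fmt_code, bits, n_values) {
  if (fmt_code == 3L) {  # IEEE float
    size <- bits %/% 8L
    if (!size %in% c(4L, 8L)) {
      stop_respscreen("unsupported float width: %d bits", bits,
                      class = "respscreen_format_error")
    }
    return(readBin(raw, "double", n_values, size = size, endian = "little"))
  }
  if (fmt_code != 1L) {
    stop_respscreen("unsupported WAVE format code: %d", fmt_code,
                    class = "respscreen_format_error")
  }
  if (bits == 8L) {  # unsigned
    return((as.integer(raw[seq_len(n_values)]) - 128) / 128)
  }
  if (bits == 16L) {
    v <- readBin(raw, "integer", n_values, size = 2, signed = TRUE,
                 endian = "little")
    return(v / 32768)
  }
  if (bits == 24L) {
    b <- as.numeric(raw)
    i <- seq_len(n_values)
    v <- b[3 * i - 2] + 256 * b[3 * i - 1] + 65536 * b[3 * i]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    return(v / 8388608)
  }
  if (bits == 32L) {
    v <- readBin(raw, "integer", n_values, size = 4, endian = "little")
    return(v / 2147483648)
  }
  stop_respscreen("unsupported PCM width: %d bits", bits,
                  class = "respscreen_format_error")
}

write_wav <- function(samples, sample_rate, path, bits = 16L) {
  samples <- as.matrix(samples)
  if (bits != 16L) {
    stop_respscreen("only 16-bit PCM output is supported",
                    class = "respscreen_format_error")
  }
  if (any(abs(samples) > 1 + 1e-9)) {
    stop_respscreen("amplitudes exceed [-1, 1]; rescale before writing",
                    class = "respscreen_contract_error")
  }
  n_channels <- ncol(samples)
  q <- as.integer(pmax(pmin(round(t(samples) * 32768), 32767), -32768))
  data_size <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_channels * 2L), con, size = 4,
           endian = "little")                               # byte rate
  writeBin(n_channels * 2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
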