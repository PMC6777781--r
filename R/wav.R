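# Minimal RIFF/WAVE codec for mono recordings. Supports the formats used by
# measurement soundcards in this context: 16- and 24-bit integer PCM and
# 32-bit IEEE float. Only what the package needs; not a general audio
# library.

#' Write a mono WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (values outside are clipped for
#'   integer formats).
#' @param path Output path.
#' @param sample_rate Sampling frequency in Hz.
#' @param bit_depth One of `"float32"`, `"pcm24"`, `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 48000L,
                      bit_depth = c("float32", "pcm24", "pcm16")) {
  bit_depth <- match.arg(bit_depth)
  stopifnot(is.numeric(samples), length(samples) >= 1L, sample_rate > 0)
  n <- length(samples)
  bytes_per <- switch(bit_depth, float32 = 4L, pcm24 = 3L, pcm16 = 2L)
  fmt_code <- if (bit_depth == "float32") 3L else 1L
  data_size <- n * bytes_per
  pad <- data_size %% 2L
  # float formats carry a 'fact' chunk with the frame count
  fact_size <- if (fmt_code == 3L) 12L else 0L
  riff_size <- 4L + 24L + fact_size + 8L + data_size + pad

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little") # byte rate
  writeBin(bytes_per, con, size = 2, endian = "little") # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  if (fmt_code == 3L) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(n), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else if (bit_depth == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else { # pcm24, packed little-endian 3-byte two's complement
    q <- round(pmax(-1, pmin(1, samples)) * 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    raw3 <- matrix(0L, nrow = 3L, ncol = n)
    raw3[1L, ] <- q %% 256
    raw3[2L, ] <- (q %/% 256) %% 256
    raw3[3L, ] <- (q %/% 65536) %% 256
    writeBin(as.raw(raw3), con)
  }
  if (pad) writeBin(raw(1L), con)
  invisible(path)
}

read_chunk_header <- function(con) {
  id <- readChar(con, 4, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) {
    return(NULL)
  }
  size <- readBin(con, "integer", size = 4, endian = "little")
  list(id = id, size = size)
}

#' Read a mono WAV file
#'
#' Parses RIFF chunks, tolerating extra chunks between `fmt ` and `data`.
#'
#' @param path WAV path (mono; 16/24-bit PCM or 32-bit float).
#' @return List with `samples` (numeric, nominal range \[-1, 1\]),
#'   `sample_rate`, `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF")) {
    stop("not a RIFF file: ", path)
  }
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt <- NULL
  repeat {
    ch <- read_chunk_header(con)
    if (is.null(ch)) stop("no data chunk found in ", path)
    if (ch$id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (ch$size > 16L) readBin(con, "raw", ch$size - 16L)
      if (channels != 1L) stop("only mono WAV files are supported")
      fmt <- list(code = fmt_code, rate = sample_rate, bits = bits)
    } else if (ch$id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      bytes_per <- fmt$bits %/% 8L
      n <- ch$size %/% bytes_per
      if (fmt$code == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = n, size = 4, endian = "little")
        bit_depth <- "float32"
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                           endian = "little") / 32767
        bit_depth <- "pcm16"
      } else if (fmt$code == 1L && fmt$bits == 24L) {
        raw <- readBin(con, "raw", n = 3L * n)
        b <- matrix(as.integer(raw), nrow = 3L)
        q <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
        q <- ifelse(q >= 8388608, q - 16777216, q)
        samples <- q / 8388607
        bit_depth <- "pcm24"
      } else {
        stop(sprintf("unsupported WAV format (code %d, %d bits)",
                     fmt$code, fmt$bits))
      }
      return(list(samples = samples, sample_rate = fmt$rate,
                  bit_depth = bit_depth))
    } else {
      readBin(con, "raw", ch$size + ch$size %% 2L) # skip, with pad byte
    }
  }
}
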