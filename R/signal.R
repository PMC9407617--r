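#' Construct a labeled signal
#'
#' A signal is a finite real-valued series with an optional sample rate and
#' identifying labels (cohort group and episode type, e.g. expiration or
#' inspiration). It is the unit every other stage of the package consumes.
#'
#' @param samples numeric vector, finite values, length >= 2.
#' @param sample_rate sampling frequency in Hz, or `NA` for abstract series.
#' @param id character identifier.
#' @param group group label (e.g. `"healthy"`), or `NA`.
#' @param episode episode label (e.g. `"EXP"`), or `NA`.
#' @return an object of class `mf_signal`.
#' @export
#' @examples
#' s <- signal(sin(2 * pi * 5 * seq(0, 1, length.out = 512)), sample_rate = 512)
#' print(s)
signal <- function(samples, sample_rate = NA_real_, id = "signal",
                   group = NA_character_, episode = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("a signal needs at least 2 samples")
  }
  if (!all(is.finite(samples))) {
    stop("signal contains non-finite values")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         id = as.character(id), group = as.character(group),
         episode = as.character(episode)),
    class = "mf_signal"
  )
}

#' @export
print.mf_signal <- function(x, ...) {
  sr <- if (is.na(x$sample_rate)) "no sample rate" else paste0(x$sample_rate, " Hz")
  cat(sprintf("<mf_signal '%s'> %d samples, %s, group=%s, episode=%s\n",
              x$id, length(x$samples), sr, x$group, x$episode))
  invisible(x)
}

#' @export
length.mf_signal <- function(x) length(x$samples)

as_samples <- function(x) {
  if (inherits(x, "mf_signal")) x$samples
  else if (inherits(x, "mf_cepstrum")) x$coefficients
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a numeric vector, mf_signal or mf_cepstrum")
}

# ---- WAV input/output (RIFF, integer PCM) -----------------------------------

#' Read a mono signal from a WAV file
#'
#' Supports uncompressed integer PCM at 16, 24 or 32 bits. Stereo files are
#' collapsed to mono by channel averaging, with a warning. Samples are scaled
#' to `[-1, 1)`.
#'
#' @param path WAV file path.
#' @param id,group,episode labels to attach (default id: file name).
#' @return an [signal()] object.
#' @export
read_wav <- function(path, id = NULL, group = NA_character_,
                     episode = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(tag, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  if (fmt$audio_format != 1) {
    stop("only integer PCM WAV supported (format tag ", fmt$audio_format, ")")
  }
  bytes <- fmt$bits / 8
  if (!fmt$bits %in% c(16, 24, 32)) {
    stop("unsupported bit depth: ", fmt$bits)
  }
  n_total <- length(data_raw) %/% bytes
  if (fmt$bits == 24) {
    # readBin has no 3-byte integers; assemble manually (little-endian, signed)
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    v <- readBin(data_raw, "integer", n_total, bytes, signed = TRUE,
                 endian = "little")
    x <- v / 2^(fmt$bits - 1)
  }
  if (fmt$n_channels > 1) {
    warning("collapsing ", fmt$n_channels, "-channel WAV to mono by averaging")
    nfrm <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(nfrm * fmt$n_channels)],
                         ncol = fmt$n_channels, byrow = TRUE))
  }
  signal(x, sample_rate = fmt$sample_rate,
         id = id %||% sub("\\.wav$", "", basename(path), ignore.case = TRUE),
         group = group, episode = episode)
}

#' Write a signal as 16-bit PCM WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param x an [signal()] object with a sample rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "mf_signal"))
  if (is.na(x$sample_rate)) stop("signal has no sample rate; cannot write WAV")
  v <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(v * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(x$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little") # byte rate
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- plain-text series ------------------------------------------------------

#' Read a numeric series from a text file
#'
#' Accepts one value per line or a delimited table, in which case the first
#' numeric column is used.
#'
#' @param path file path.
#' @param id,group,episode,sample_rate labels to attach.
#' @return an [signal()] object.
#' @export
read_series <- function(path, id = NULL, group = NA_character_,
                        episode = NA_character_, sample_rate = NA_real_) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  num <- which(vapply(tab, is.numeric, logical(1)))
  if (length(num) == 0) stop("no numeric column in ", path)
  signal(tab[[num[1]]], sample_rate = sample_rate,
         id = id %||% sub("\\.[^.]*$", "", basename(path)),
         group = group, episode = episode)
}

#' Write a signal as a single-column text file
#'
#' Full double precision (`%.17g`), one value per line, so that a
#' write/read round trip is exact.
#'
#' @param x an [signal()] object or numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  writeLines(sprintf("%.17g", as_samples(x)), path)
  invisible(path)
}

# dispatch on file extension
read_signal_file <- function(path, id = NULL, group = NA_character_,
                             episode = NA_character_) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    read_wav(path, id = id, group = group, episode = episode)
  } else {
    read_series(path, id = id, group = group, episode = episode)
  }
}
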