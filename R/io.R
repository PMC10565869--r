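#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float, mono
#' (`time_signal`) or stereo (`stereo_signal`, left = channel 0).
#'
#' @param x A `time_signal` or `stereo_signal`.
#' @param path Output file path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "stereo_signal")) {
    rate <- x$left$rate_hz
    mat <- rbind(x$left$samples, x$right$samples)
  } else {
    assert_time_signal(x)
    rate <- x$rate_hz
    mat <- matrix(x$samples, nrow = 1)
  }
  n_ch <- nrow(mat)
  inter <- as.vector(mat)  # frame-interleaved
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_bytes <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_format <- if (format == "pcm16") 1L else 3L
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(round(rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rate) * n_ch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(pmin(round(inter * 32767), 32767L), -32768L))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(inter), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Counterpart of [write_wav()]: reads 16-bit PCM or 32-bit float RIFF/WAVE
#' files; mono files return a `time_signal`, stereo files a `stereo_signal`
#' (left = channel 0).
#'
#' @param path Input file path.
#' @return A `time_signal` or `stereo_signal`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(audio_format = readBin(con, integer(), size = 2, endian = "little"),
                  n_ch = readBin(con, integer(), size = 2, endian = "little"),
                  rate = readBin(con, integer(), size = 4, endian = "little"),
                  byte_rate = readBin(con, integer(), size = 4, endian = "little"),
                  block_align = readBin(con, integer(), size = 2, endian = "little"),
                  bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16L) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = sz)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, integer(), n = length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little") / 32767
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    v <- readBin(data_raw, numeric(), n = length(data_raw) %/% 4L, size = 4,
                 endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  if (fmt$n_ch == 1L) {
    time_signal(v, fmt$rate)
  } else if (fmt$n_ch == 2L) {
    idx <- seq(1L, length(v), by = 2L)
    stereo_signal(time_signal(v[idx], fmt$rate),
                  time_signal(v[idx + 1L], fmt$rate))
  } else {
    stop("only mono and stereo WAV files are supported", call. = FALSE)
  }
}

#' Write filter or impulse-response taps to CSV
#'
#' Two columns `index,amplitude` with a header row and 0-based indices; the
#' sampling rate is recorded in a `# rate_hz:` comment line so files round
#' trip through [read_taps_csv()].
#'
#' @param x A `time_signal`, `ctc_filter` or `eq_filter` (anything with
#'   `taps`/`samples` and `rate_hz`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taps_csv <- function(x, path) {
  taps <- if (!is.null(x$taps)) x$taps else x$samples
  if (is.null(taps) || is.null(x$rate_hz)) {
    stop("`x` must carry taps/samples and a rate_hz", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", x$rate_hz), con)
  writeLines("index,amplitude", con)
  writeLines(sprintf("%d,%.17g", seq_along(taps) - 1L, taps), con)
  invisible(path)
}

#' Read taps from CSV
#'
#' @param path CSV file produced by [write_taps_csv()] (or any
#'   `index,amplitude` file; supply `rate_hz` if no rate comment is present).
#' @param rate_hz Fallback sampling rate.
#' @return A `time_signal`.
#' @export
read_taps_csv <- function(path, rate_hz = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# rate_hz:")) {
    rate_hz <- as.numeric(sub("# rate_hz:", "", first, fixed = TRUE))
  }
  if (is.null(rate_hz) || is.na(rate_hz)) {
    stop("no sampling rate in file and none supplied", call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("index", "amplitude") %in% names(df))) {
    stop("taps CSV must have columns `index` and `amplitude`", call. = FALSE)
  }
  time_signal(df$amplitude[order(df$index)], rate_hz)
}

#' Load a run configuration from JSON or YAML
#'
#' Reads a configuration file for [run_pipeline()], validates required keys
#' and fills defaults for the rest.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A `run_config` (see [run_config()]).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml: ", path, call. = FALSE)
  }
  required <- c("master_seed")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}
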