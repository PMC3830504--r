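# Minimal EDF (European Data Format) support: fixed 256-byte ASCII header,
# one 256-byte block per signal, then data records of little-endian int16
# samples scaled linearly between digital and physical ranges. Continuous
# recordings only; annotations channels are not interpreted.

read_ascii_field <- function(con, nchars) {
  raw <- readChar(con, nchars, useBytes = TRUE)
  trimws(raw)
}

#' Read an EDF file
#'
#' Parses a continuous EDF recording and returns every signal in its
#' physical units (the header's physical min/max against digital min/max
#' define the linear scaling).
#'
#' @param path Path to the EDF file.
#' @return A list with `labels` (character), `fs` (numeric, per-signal
#'   sampling rate in Hz), `signals` (list of numeric vectors, physical
#'   units) and `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii_field(con, 8)
  if (!identical(version, "0")) {
    stop("not an EDF file (version field '", version, "'): ", path,
         call. = FALSE)
  }
  readChar(con, 80, useBytes = TRUE)            # patient id
  readChar(con, 80, useBytes = TRUE)            # recording id
  readChar(con, 8, useBytes = TRUE)             # start date
  readChar(con, 8, useBytes = TRUE)             # start time
  header_bytes <- as.integer(read_ascii_field(con, 8))
  readChar(con, 44, useBytes = TRUE)            # reserved
  n_records <- as.integer(read_ascii_field(con, 8))
  record_dur <- as.numeric(read_ascii_field(con, 8))
  ns <- as.integer(read_ascii_field(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header reports no signals", call. = FALSE)

  fld <- function(width) {
    vapply(seq_len(ns), function(i) read_ascii_field(con, width),
           character(1))
  }
  labels <- fld(16)
  fld(80)                                        # transducer
  fld(8)                                         # physical dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                                        # prefiltering
  spr <- as.integer(fld(8))                      # samples per record
  fld(32)                                        # reserved
  seek(con, header_bytes)

  total_per_record <- sum(spr)
  data <- readBin(con, "integer", n = total_per_record * n_records,
                  size = 2, signed = TRUE, endian = "little")
  if (length(data) < total_per_record * n_records) {
    stop("EDF file truncated: expected ", total_per_record * n_records,
         " samples, got ", length(data), call. = FALSE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- phys_min - gain * dig_min
  ends <- cumsum(spr)
  starts <- ends - spr + 1L
  signals <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(starts[i]:ends[i],
                           (seq_len(n_records) - 1L) * total_per_record, `+`))
    signals[[i]] <- data[idx] * gain[i] + offs[i]
  }
  list(labels = labels, fs = spr / record_dur, signals = signals,
       n_records = n_records)
}

#' Write signals to an EDF file
#'
#' Writes continuous numeric signals as a one-second-record EDF file with
#' 16-bit quantization over each signal's observed physical range. Intended
#' for fixtures and interoperability; the trailing partial second is dropped
#' (EDF records have fixed length).
#'
#' @param signals Named list of numeric vectors (physical units, e.g. uV).
#' @param fs Sampling rate in Hz, shared by all signals.
#' @param path Output path.
#' @param physical_dimension Unit string stored per signal (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, physical_dimension = "uV") {
  stopifnot(is.list(signals), length(signals) >= 1, fs > 0)
  labels <- names(signals) %||% paste0("sig", seq_along(signals))
  ns <- length(signals)
  spr <- as.integer(round(fs))
  n_records <- min(vapply(signals, length, integer(1))) %/% spr
  if (n_records < 1) {
    stop("signals shorter than one EDF record (", spr, " samples)",
         call. = FALSE)
  }
  pad <- function(x, width) {
    s <- formatC(as.character(x), width = -width)
    substr(s, 1, width)
  }
  phys_min <- vapply(signals, function(s) floor(min(s)) - 1, numeric(1))
  phys_max <- vapply(signals, function(s) ceiling(max(s)) + 1, numeric(1))
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    writeChar(pad(x, width), con, nchars = width, eos = NULL)
  }
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("", 44)
  wr(n_records, 8)
  wr("1", 8)                                     # record duration, seconds
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(physical_dimension, 8)
  for (v in phys_min) wr(v, 8)
  for (v in phys_max) wr(v, 8)
  for (v in dig_min) wr(v, 8)
  for (v in dig_max) wr(v, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - phys_min[i]) / gain[i] + dig_min[i]))
      dig <- pmax(pmin(dig, 32767L), -32768L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
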