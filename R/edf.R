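# Minimal EDF (European Data Format) I/O. EDF is a fixed-layout format:
# a 256-byte ASCII header, 256 bytes of ASCII signal headers per signal,
# then data records of little-endian int16 samples scaled linearly between
# digital and physical ranges. Only continuous equal-rate signals are
# handled, which covers resting-state EEG exports.

read_ascii <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) {
    stop("truncated EDF header", call. = FALSE)
  }
  trimws(raw)
}

#' Read an EDF file into a recording
#'
#' Parses the fixed-layout EDF header and data records. All signals must
#' share one sampling rate; annotation channels are not supported. Scaling
#' from digital to physical units follows the EDF linear mapping.
#'
#' @param path Path to an `.edf` file.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                      # version
  read_ascii(con, 80)                     # patient id
  rec_field <- read_ascii(con, 80)        # recording id
  read_ascii(con, 8); read_ascii(con, 8)  # start date, time
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)                     # reserved
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur)) {
    stop("malformed EDF header: ", path, call. = FALSE)
  }
  field <- function(width) vapply(seq_len(ns), function(i) read_ascii(con, width), "")
  labels    <- field(16)
  field(80)                               # transducer
  field(8)                                # physical dimension
  phys_min  <- as.numeric(field(8))
  phys_max  <- as.numeric(field(8))
  dig_min   <- as.numeric(field(8))
  dig_max   <- as.numeric(field(8))
  field(80)                               # prefiltering
  spr       <- as.integer(field(8))       # samples per record
  field(32)                               # reserved
  if (length(unique(spr)) != 1) {
    stop("EDF signals with mixed sampling rates are not supported",
         call. = FALSE)
  }
  if (header_bytes != 256L * (ns + 1L)) {
    stop("EDF header size field inconsistent with signal count",
         call. = FALSE)
  }
  spr <- spr[1]
  rate <- spr / record_dur
  n_int <- n_records * ns * spr
  dig <- readBin(con, "integer", n = n_int, size = 2, endian = "little")
  if (length(dig) != n_int) {
    stop("truncated EDF data section: expected ", n_int, " samples, got ",
         length(dig), call. = FALSE)
  }
  # records x (signal-major within record) -> channels x samples
  dig <- array(dig, dim = c(spr, ns, n_records))
  out <- matrix(0, nrow = ns, ncol = spr * n_records)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    x <- as.vector(dig[, s, ])
    out[s, ] <- (x - dig_min[s]) * gain[s] + phys_min[s]
  }
  recording(out, rate = rate, labels = labels,
            subject_id = if (nzchar(rec_field)) rec_field else NA_character_)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as EDF
#'
#' Quantizes each channel to the 16-bit digital range over its physical
#' min/max, so the round trip is exact up to quantization (relative error
#' about 3e-5 of the channel range).
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param record_duration_s Duration of one EDF data record; the recording
#'   is truncated to a whole number of records.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration_s = 1) {
  stopifnot(inherits(rec, "recording"))
  spr <- round(rec$rate * record_duration_s)
  n_records <- floor(ncol(rec$data) / spr)
  if (n_records < 1) stop("recording shorter than one EDF record", call. = FALSE)
  ns <- nrow(rec$data)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr("", 80)
  wr(ifelse(is.na(rec$subject_id), "", rec$subject_id), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_records, 8)
  wr(format(record_duration_s), 8)
  wr(ns, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(phys_min[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(phys_max[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[s, idx] - phys_min[s]) * gain[s] + dig_min)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
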