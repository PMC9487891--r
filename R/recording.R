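#' Construct a continuous multichannel recording
#'
#' A `recording` bundles a channels-by-samples numeric matrix with its
#' sampling rate, channel labels and subject/condition tags. It is the
#' common currency of the signal stages.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling rate in Hz.
#' @param labels Channel labels; defaults to `E1...En`.
#' @param subject_id Subject identifier string.
#' @param condition Recording condition, `"EC"` (eyes closed) or `"EO"`
#'   (eyes open), or `NA` when not applicable.
#' @return An object of class `recording`.
#' @export
recording <- function(data, rate, labels = NULL, subject_id = NA_character_,
                      condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(labels)) labels <- montage_labels(nrow(data))
  if (length(labels) != nrow(data)) {
    stop("length(labels) must equal the number of channels", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.na(condition) && !condition %in% c("EC", "EO")) {
    stop("`condition` must be \"EC\", \"EO\" or NA", call. = FALSE)
  }
  rownames(data) <- labels
  structure(
    list(data = data, rate = rate, labels = labels,
         subject_id = subject_id, condition = condition),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

duration_s <- function(rec) ncol(rec$data) / rec$rate

#' Write a recording in the native delimited format
#'
#' The native on-disk format is a plain tab-separated samples-by-channels
#' matrix next to a JSON sidecar (`<path>.json`) holding the labels,
#' sampling rate and subject/condition tags. It round-trips losslessly at
#' full double precision.
#'
#' @param rec A [recording()].
#' @param path Output path for the matrix file (sidecar derived from it).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  mat <- t(rec$data)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(labels = rec$labels, rate = rec$rate,
               subject_id = rec$subject_id, condition = rec$condition,
               n_samples = ncol(rec$data))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' Supports the package's native delimited format (matrix + JSON sidecar,
#' see [write_recording()]) and EDF (European Data Format, see
#' [read_edf()]). With `format = "auto"` the sidecar's presence decides.
#'
#' @param path Path to the matrix file or the EDF file.
#' @param format `"auto"`, `"native"` or `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "native", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (file.exists(paste0(path, ".json"))) "native" else "edf"
  }
  if (format == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for native recording: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("labels", "rate", "n_samples")
  if (!all(req %in% names(meta))) {
    stop("malformed sidecar (need labels, rate, n_samples): ", sidecar,
         call. = FALSE)
  }
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
  if (nrow(mat) != meta$n_samples || ncol(mat) != length(meta$labels)) {
    stop(sprintf(
      "recording shape mismatch: file is %d x %d, sidecar declares %d x %d",
      nrow(mat), ncol(mat), meta$n_samples, length(meta$labels)),
      call. = FALSE)
  }
  recording(t(mat), rate = meta$rate, labels = meta$labels,
            subject_id = meta$subject_id %||% NA_character_,
            condition = meta$condition %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
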