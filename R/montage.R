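#' Canonical frequency band definitions
#'
#' The four analysis bands used throughout the pipeline: delta (0.5--4 Hz),
#' theta (4--8 Hz), alpha (8--13 Hz) and beta (13--30 Hz). Gamma is excluded
#' because scalp gamma is dominated by muscle artifact and shows poor
#' reliability in graph analyses.
#'
#' @param names Optional character vector restricting the returned bands.
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' band_definitions()
band_definitions <- function(names = NULL) {
  bands <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low  = c(0.5, 4, 8, 13),
    high = c(4, 8, 13, 30)
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, bands$band)
    if (length(unknown) > 0) {
      stop("unknown band(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    bands <- bands[match(names, bands$band), ]
  }
  bands
}

validate_bands <- function(bands, nyquist = Inf) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low <= 0) || any(bands$high <= bands$low)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (any(bands$high > nyquist)) {
    stop("band edge above Nyquist frequency (", nyquist, " Hz)", call. = FALSE)
  }
  invisible(bands)
}

#' Channel labels of the 128-channel geodesic montage
#'
#' @param n Number of channels (default 128).
#' @return Character vector `E1` ... `En`.
#' @export
montage_labels <- function(n = 128) paste0("E", seq_len(n))

#' Default periocular (eye-movement) channel exclusion list
#'
#' Eight channels at standard periocular positions of the 128-channel
#' geodesic net. The montage-specific identity of eye channels is a
#' configuration choice; this is the package default and can be overridden
#' wherever an exclusion list is accepted.
#'
#' @return Character vector of eight channel labels.
#' @export
default_eye_channels <- function() {
  c("E8", "E14", "E21", "E25", "E125", "E126", "E127", "E128")
}

#' Default region-of-interest electrode groupings
#'
#' Six sensory scalp regions over the 128-channel montage: left/right
#' temporal (auditory cortex, 7 electrodes each), left/right occipital
#' (visual cortex, 9 each) and left/right parietal (somatosensory cortex,
#' 9 each). Regions are disjoint.
#'
#' @return Named list mapping region name (`TL`, `TR`, `OL`, `OR`, `PL`,
#'   `PR`) to electrode labels.
#' @export
#' @examples
#' lengths(default_roi_set())
default_roi_set <- function() {
  list(
    TL = c("E35", "E39", "E40", "E41", "E45", "E46", "E50"),
    TR = c("E101", "E102", "E103", "E108", "E109", "E110", "E115"),
    OL = c("E58", "E59", "E60", "E64", "E65", "E66", "E67", "E70", "E71"),
    OR = c("E76", "E77", "E83", "E84", "E85", "E90", "E91", "E95", "E96"),
    PL = c("E31", "E37", "E42", "E47", "E51", "E52", "E53", "E54", "E61"),
    PR = c("E78", "E79", "E80", "E86", "E87", "E92", "E93", "E97", "E98")
  )
}

validate_roi_set <- function(rois, labels = NULL) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  all_el <- unlist(rois, use.names = FALSE)
  if (anyDuplicated(all_el)) {
    stop("ROI regions must be disjoint", call. = FALSE)
  }
  if (!is.null(labels)) {
    missing <- setdiff(all_el, labels)
    if (length(missing) > 0) {
      stop("ROI electrodes not in montage: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(rois)
}
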