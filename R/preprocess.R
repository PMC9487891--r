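#' Construct an epoch set
#'
#' Fixed-length epoch collection for one subject and condition, stored as
#' an epochs x channels x samples array. Produced by [epoch_and_select()]
#' and consumed by the connectivity stage.
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param rate Sampling rate (Hz).
#' @param labels Channel labels.
#' @param band Band label; `"broadband"` before [band_decompose()].
#' @param referenced Logical: has the average reference been applied?
#' @param subject_id,condition Provenance tags.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, rate, labels, band = "broadband",
                      referenced = FALSE, subject_id = NA_character_,
                      condition = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(labels)) {
    stop("labels must match the channel dimension", call. = FALSE)
  }
  structure(list(data = data, rate = rate, labels = labels, band = band,
                 referenced = referenced, subject_id = subject_id,
                 condition = condition,
                 epoch_length_s = dim(data)[3] / rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz [%s]%s\n",
              d[1], d[2], d[3], x$rate, x$band,
              if (x$referenced) " (avg-ref)" else ""))
  invisible(x)
}

# IIR difference equation applied column-wise via the C-level routines in
# stats::filter (convolution for the numerator, recursive for the
# denominator); exact match to signal::filter, far less per-call overhead
iir_filter_cols <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(rbind(matrix(0, nb - 1, ncol(x)), x), b / a[1],
                     method = "convolution", sides = 1)
  v <- v[nb:nrow(v), , drop = FALSE]
  y <- stats::filter(v, -a[-1] / a[1], method = "recursive")
  matrix(as.numeric(y), ncol = ncol(x))
}

# forward-backward (zero net phase) filtering with end zero-padding,
# column-wise; matches signal::filtfilt on each column
filtfilt_cols <- function(flt, x) {
  n <- nrow(x)
  pad <- matrix(0, 2 * max(length(flt$a), length(flt$b)), ncol(x))
  y <- iir_filter_cols(flt$b, flt$a, rbind(x, pad))
  y <- iir_filter_cols(flt$b, flt$a, y[nrow(y):1, , drop = FALSE])
  y[nrow(y):1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

butter_bandpass <- function(x, low, high, rate, order = 4) {
  # zero-phase (forward-backward) 4th-order Butterworth band-pass, flat in
  # the passband. When the lower edge falls below 0.002 of Nyquist the
  # band-pass recursion becomes numerically unstable, so a cascaded
  # high-pass + low-pass of the same order substitutes there (slight
  # passband droop, unconditionally stable). `x` may be a vector or a
  # channels x samples matrix.
  nyq <- rate / 2
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else t(x)
  if (low / nyq >= 0.002) {
    bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
    y <- filtfilt_cols(bp, xm)
  } else {
    hp <- signal::butter(order, low / nyq, type = "high")
    lp <- signal::butter(order, high / nyq, type = "low")
    y <- filtfilt_cols(lp, filtfilt_cols(hp, xm))
  }
  if (vec) as.numeric(y) else t(y)
}

#' Band-pass filter and resample a continuous recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass between
#' `low` and `high` Hz, then polyphase resampling to `target_rate`. The
#' default settings implement the broadband conditioning step: 0.5-30 Hz,
#' resampled to 500 Hz.
#'
#' @param rec A [recording()].
#' @param low,high Band edges (Hz); `high` must not exceed the target
#'   Nyquist frequency.
#' @param target_rate Output sampling rate (Hz); `NULL` keeps the input rate.
#' @param order Butterworth order per pass.
#' @return A filtered, resampled [recording()].
#' @export
condition_signal <- function(rec, low = 0.5, high = 30, target_rate = 500,
                             order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$data) == 0) stop("empty recording", call. = FALSE)
  if (is.null(target_rate)) target_rate <- rec$rate
  if (low <= 0 || high <= low) stop("need 0 < low < high", call. = FALSE)
  if (high > target_rate / 2) {
    stop("`high` exceeds the Nyquist frequency of the target rate",
         call. = FALSE)
  }
  filt <- butter_bandpass(rec$data, low = low, high = high,
                          rate = rec$rate, order = order)
  if (target_rate != rec$rate) {
    frac <- ratio_pq(target_rate, rec$rate)
    if (frac[1] == 1) {
      # integer decimation: the band-pass above already removed all content
      # beyond the target Nyquist, so plain subsampling is alias-free and
      # exactly amplitude-preserving
      filt <- filt[, seq(1, ncol(filt), by = frac[2]), drop = FALSE]
    } else {
      filt <- t(apply(filt, 1, function(x) {
        signal::resample(x, p = frac[1], q = frac[2])
      }))
    }
  }
  recording(filt, rate = target_rate, labels = rec$labels,
            subject_id = rec$subject_id, condition = rec$condition)
}

ratio_pq <- function(p, q) {
  # reduce p/q to smallest integers (rates are rational in practice)
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) stop("cannot express rate ratio as a small fraction",
                          call. = FALSE)
  }
  pi_ <- round(p * scale); qi <- round(q * scale)
  g <- gcd_int(pi_, qi)
  c(pi_ / g, qi / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Remove named channels from a recording
#'
#' Default behaviour drops the eight periocular channels of the
#' 128-channel montage ([default_eye_channels()]), leaving 120 channels;
#' the order of the remaining channels is preserved.
#'
#' @param rec A [recording()].
#' @param labels Channel labels to remove.
#' @return A [recording()] without those channels.
#' @export
drop_channels <- function(rec, labels = default_eye_channels()) {
  stopifnot(inherits(rec, "recording"))
  unknown <- setdiff(labels, rec$labels)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(rec$labels %in% labels)
  if (!any(keep)) stop("cannot drop every channel", call. = FALSE)
  recording(rec$data[keep, , drop = FALSE], rate = rec$rate,
            labels = rec$labels[keep], subject_id = rec$subject_id,
            condition = rec$condition)
}

#' Segment a recording into fixed-length epochs and select clean ones
#'
#' Tiles the recording into non-overlapping consecutive epochs of
#' `length_s` seconds, discards epochs whose peak absolute amplitude
#' exceeds `reject_threshold` (a deterministic surrogate for visual
#' artifact rejection), and keeps the first `n_keep` surviving epochs in
#' time order. The default keeps 72 epochs of 2 s, the panel count used
#' for every subject downstream.
#'
#' @param rec A [recording()].
#' @param length_s Epoch length in seconds.
#' @param n_keep Number of epochs to keep; `NULL` keeps all survivors.
#' @param reject_threshold Peak-amplitude rejection threshold (same units
#'   as the signal); `Inf` disables rejection.
#' @return An [epoch_set()].
#' @export
epoch_and_select <- function(rec, length_s = 2, n_keep = 72,
                             reject_threshold = Inf) {
  stopifnot(inherits(rec, "recording"))
  spe <- round(length_s * rec$rate)
  n_total <- floor(ncol(rec$data) / spe)
  if (!is.null(n_keep) && n_total < n_keep) {
    stop(sprintf("recording holds only %d epochs of %gs; %d requested",
                 n_total, length_s, n_keep), call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(n_total, nrow(rec$data), spe))
  keep <- logical(n_total)
  for (e in seq_len(n_total)) {
    seg <- rec$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
    arr[e, , ] <- seg
    keep[e] <- max(abs(seg)) <= reject_threshold
  }
  surviving <- which(keep)
  if (is.null(n_keep)) {
    sel <- surviving
  } else {
    if (length(surviving) < n_keep) {
      stop(sprintf(
        "subject %s/%s: only %d of %d epochs survive the %g amplitude threshold (%d required)",
        rec$subject_id, rec$condition, length(surviving), n_total,
        reject_threshold, n_keep), call. = FALSE)
    }
    sel <- surviving[seq_len(n_keep)]
  }
  out <- epoch_set(arr[sel, , , drop = FALSE], rate = rec$rate,
                   labels = rec$labels, subject_id = rec$subject_id,
                   condition = rec$condition)
  attr(out, "selected") <- sel
  out
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every time point, the mean across the retained channels,
#' so the cross-channel mean of every sample is zero. Idempotent; calling
#' it on an already referenced epoch set warns and returns it unchanged.
#'
#' @param ep An [epoch_set()].
#' @return The referenced [epoch_set()].
#' @export
rereference_average <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  if (ep$referenced) {
    warning("epoch set is already average-referenced; returning unchanged")
    return(ep)
  }
  d <- ep$data
  means <- apply(d, c(1, 3), mean)           # epochs x samples
  for (ch in seq_len(dim(d)[2])) d[, ch, ] <- d[, ch, ] - means
  out <- ep
  out$data <- d
  out$referenced <- TRUE
  out
}

#' Decompose broadband epochs into frequency bands
#'
#' Applies the zero-phase Butterworth band-pass per band, epoch and
#' channel. Returns one epoch set per band with identical epoch structure.
#'
#' @param ep A broadband [epoch_set()].
#' @param bands Band definition tibble (see [band_definitions()]).
#' @param order Butterworth order per pass.
#' @return Named list of [epoch_set()]s, one per band.
#' @export
band_decompose <- function(ep, bands = band_definitions(), order = 4) {
  stopifnot(inherits(ep, "epoch_set"))
  validate_bands(bands, nyquist = ep$rate / 2)
  d <- dim(ep$data)
  out <- purrr::map(seq_len(nrow(bands)), function(b) {
    arr <- array(NA_real_, dim = d)
    for (e in seq_len(d[1])) {
      seg <- matrix(ep$data[e, , ], nrow = d[2])
      arr[e, , ] <- butter_bandpass(seg, bands$low[b], bands$high[b],
                                    ep$rate, order)
    }
    res <- ep
    res$data <- arr
    res$band <- bands$band[b]
    res
  })
  names(out) <- bands$band
  out
}

# one-sided periodogram averaged across epochs: frequencies x channels
epoch_periodogram <- function(ep) {
  d <- dim(ep$data)
  n <- d[3]
  freqs <- (0:(floor(n / 2))) * ep$rate / n
  psd <- matrix(0, nrow = length(freqs), ncol = d[2])
  for (e in seq_len(d[1])) {
    seg <- matrix(ep$data[e, , ], nrow = d[2])   # channels x samples
    X <- stats::mvfft(t(seg))                    # samples x channels

    P <- Mod(X[seq_along(freqs), , drop = FALSE])^2 / (n * ep$rate)
    if (n %% 2 == 0) {
      P[2:(length(freqs) - 1), ] <- 2 * P[2:(length(freqs) - 1), ]
    } else {
      P[2:length(freqs), ] <- 2 * P[2:length(freqs), ]
    }
    psd <- psd + P
  }
  list(freq = freqs, psd = psd / d[1])
}

#' Absolute and relative band power per channel
#'
#' Averaged per-epoch periodograms (epochs act as the averaging segments)
#' integrated over each band; relative power is the band's share of the
#' total power in the broadband analysis range, so relative powers per
#' channel sum to one up to band-edge coverage.
#'
#' @param ep A broadband [epoch_set()].
#' @param bands Band definition tibble.
#' @param total_range Range (Hz) defining the total power for the relative
#'   measure.
#' @return Tibble with columns `channel`, `band`, `power`, `rel_power`.
#'   Channels with zero total power get `NA` relative power.
#' @export
band_power <- function(ep, bands = band_definitions(),
                       total_range = c(0.5, 30)) {
  stopifnot(inherits(ep, "epoch_set"))
  validate_bands(bands, nyquist = ep$rate / 2)
  if (any(bands$low < total_range[1]) || any(bands$high > total_range[2])) {
    stop("band outside the analyzed total range", call. = FALSE)
  }
  pg <- epoch_periodogram(ep)
  in_range <- function(lo, hi) pg$freq >= lo & pg$freq < hi
  total <- colSums(pg$psd[in_range(total_range[1], total_range[2]), ,
                          drop = FALSE])
  rows <- purrr::map(seq_len(nrow(bands)), function(b) {
    p <- colSums(pg$psd[in_range(bands$low[b], bands$high[b]), , drop = FALSE])
    tibble::tibble(channel = ep$labels, band = bands$band[b], power = p,
                   rel_power = ifelse(total > 0, p / total, NA_real_))
  })
  dplyr::bind_rows(rows)
}
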