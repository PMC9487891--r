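# Phase extraction and phase-lag-index (PLI) connectivity. The PLI of two
# signals is |< sign(sin(delta-phi)) >| over time: the asymmetry of the
# instantaneous phase-difference distribution around zero. Phase
# differences of exactly 0 or pi contribute nothing, which makes the index
# insensitive to volume-conduction-like zero-lag mixing.

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited epochs
#'
#' Computes the analytic-signal angle per epoch, channel and sample. The
#' stored `edge_frac` marks the fraction of each epoch end that downstream
#' PLI sums discard to suppress Hilbert edge artifacts.
#'
#' @param ep A band-limited [epoch_set()].
#' @param edge_frac Fraction (0 to <0.5) of samples trimmed from each end
#'   of an epoch in subsequent PLI computation.
#' @return An object of class `phase_epoch`: phases wrapped to (-pi, pi].
#' @export
instantaneous_phase <- function(ep, edge_frac = 0.05) {
  stopifnot(inherits(ep, "epoch_set"))
  if (edge_frac < 0 || edge_frac >= 0.5) {
    stop("`edge_frac` must lie in [0, 0.5)", call. = FALSE)
  }
  d <- dim(ep$data)
  ph <- array(NA_real_, dim = d)
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- ep$data[e, ch, ]
      if (stats::sd(x) == 0) {
        stop(sprintf("constant (zero-variance) channel %s in epoch %d",
                     ep$labels[ch], e), call. = FALSE)
      }
      ph[e, ch, ] <- Arg(analytic_signal(x))
    }
  }
  structure(list(data = ph, labels = ep$labels, band = ep$band,
                 rate = ep$rate, edge_frac = edge_frac,
                 subject_id = ep$subject_id, condition = ep$condition),
            class = "phase_epoch")
}

#' Phase lag index of two phase series
#'
#' `PLI = |mean(sign(sin(phase_a - phase_b)))|`. Samples whose phase
#' difference is exactly 0 or pi (sign of sin equals zero) contribute
#' zero, lowering rather than inflating the index. Ranges over \[0, 1\]:
#' 0 for no coupling or coupling centred on zero lag, 1 for perfect
#' locking at a nonzero lag.
#'
#' @param phase_a,phase_b Equal-length numeric phase series (radians).
#' @return Scalar PLI in \[0, 1\].
#' @export
#' @examples
#' pli_pair(rep(pi / 2, 100), rep(0, 100))  # constant pi/2 lag -> 1
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (length(phase_a) < 1) stop("empty phase series", call. = FALSE)
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' Per-epoch PLI connectivity matrices
#'
#' Evaluates [pli_pair()] over all unordered channel pairs of every epoch,
#' after trimming the phase object's `edge_frac` from both epoch ends.
#' Matrices are symmetric with zero diagonal.
#'
#' @param ph A [instantaneous_phase()] result.
#' @return A numeric array, epochs x channels x channels, with channel
#'   dimnames; class `pli_array`.
#' @export
pli_matrix <- function(ph) {
  stopifnot(inherits(ph, "phase_epoch"))
  d <- dim(ph$data)
  if (d[2] < 2) stop("need at least two channels", call. = FALSE)
  trim <- ceiling(ph$edge_frac * d[3])
  keep <- (trim + 1):(d[3] - trim)
  out <- array(0, dim = c(d[1], d[2], d[2]),
               dimnames = list(NULL, ph$labels, ph$labels))
  for (e in seq_len(d[1])) {
    p <- matrix(ph$data[e, , keep], nrow = d[2])
    for (i in seq_len(d[2] - 1)) {
      s <- sign(sin(sweep(p[(i + 1):d[2], , drop = FALSE], 2, p[i, ], `-`)))
      v <- abs(rowMeans(s))
      out[e, i, (i + 1):d[2]] <- v
      out[e, (i + 1):d[2], i] <- v
    }
  }
  structure(out, band = ph$band, class = "pli_array")
}

# single-epoch matrix extraction keeping dimnames
pli_epoch <- function(pli_arr, e) {
  m <- pli_arr[e, , ]
  dimnames(m) <- dimnames(pli_arr)[2:3]
  m
}

#' Mean PLI between two electrode regions
#'
#' Unweighted mean of the connectivity values over all cross-region
#' electrode pairs; within-region pairs are excluded by construction.
#'
#' @param m A channels x channels PLI matrix with labelled dimnames.
#' @param roi_a,roi_b Region names, distinct.
#' @param rois Named list mapping regions to electrode labels
#'   (default [default_roi_set()]).
#' @return Scalar mean PLI.
#' @export
roi_mean_pli <- function(m, roi_a, roi_b, rois = default_roi_set()) {
  if (identical(roi_a, roi_b)) stop("regions must differ", call. = FALSE)
  for (r in c(roi_a, roi_b)) {
    if (!r %in% names(rois)) stop("undefined region: ", r, call. = FALSE)
  }
  labs <- colnames(m)
  ia <- match(rois[[roi_a]], labs)
  ib <- match(rois[[roi_b]], labs)
  if (anyNA(ia) || anyNA(ib)) {
    stop("ROI electrodes missing from the matrix", call. = FALSE)
  }
  mean(m[ia, ib])
}

#' ROI-pair mean PLI across epochs
#'
#' Convenience wrapper evaluating [roi_mean_pli()] for a set of region
#' pairs on every epoch of a [pli_matrix()] array.
#'
#' @param pli_arr A `pli_array`.
#' @param pairs Two-column matrix or data frame of region names; defaults
#'   to the four same-side sensory pairings (temporal-occipital and
#'   temporal-parietal, left and right).
#' @param rois Named region list.
#' @return Tibble with columns `epoch`, `roi_a`, `roi_b`, `pli`.
#' @export
roi_pair_pli <- function(pli_arr,
                         pairs = cbind(c("TL", "TR", "TL", "TR"),
                                       c("OL", "OR", "PL", "PR")),
                         rois = default_roi_set()) {
  stopifnot(inherits(pli_arr, "pli_array"))
  pairs <- as.matrix(pairs)
  rows <- purrr::map(seq_len(dim(pli_arr)[1]), function(e) {
    m <- pli_epoch(pli_arr, e)
    tibble::tibble(
      epoch = e,
      roi_a = pairs[, 1], roi_b = pairs[, 2],
      pli = vapply(seq_len(nrow(pairs)), function(k) {
        roi_mean_pli(m, pairs[k, 1], pairs[k, 2], rois)
      }, numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}
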