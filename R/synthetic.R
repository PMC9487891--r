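#' Specify a phase-coupling structure for synthetic signals
#'
#' A coupling spec describes one band-limited component of a synthetic
#' multichannel signal: which channel pairs are phase-coupled, at what lag,
#' and how concentrated the phase noise is. Coupled pairs are driven so the
#' instantaneous phase difference of pair `(i, j)` is `delta` plus wrapped
#' Gaussian noise with standard deviation `1/sqrt(kappa)`; `kappa = Inf`
#' means perfect locking, `kappa = 0` means a uniform (independent) phase
#' difference. Channels not targeted by any edge evolve as independent
#' frequency-jittered phase random walks, so signals are band-limited but
#' not strictly periodic.
#'
#' @param band Band label (one of [band_definitions()]'s names) or a
#'   numeric centre frequency in Hz.
#' @param edges Data frame with columns `i`, `j` (channel indices: `j` is
#'   driven by `i`), `delta` (phase lag, radians, in (-pi, pi)) and `kappa`
#'   (phase-noise concentration, >= 0). May have zero rows.
#' @param amplitude Per-channel amplitude (scalar recycled).
#' @param noise_sd Additive white-noise standard deviation.
#' @param drift_sd Per-sample standard deviation of the frequency-jitter
#'   random walk (radians). With `drift_sd = 0` the latent phases are exact
#'   ramps starting at phase zero.
#' @return An object of class `coupling_spec`.
#' @export
#' @examples
#' coupling_spec("theta", data.frame(i = 1, j = 2, delta = pi / 2, kappa = 6))
coupling_spec <- function(band = "alpha",
                          edges = data.frame(i = integer(), j = integer(),
                                             delta = numeric(), kappa = numeric()),
                          amplitude = 1, noise_sd = 0, drift_sd = 0.05) {
  if (is.character(band)) {
    bd <- band_definitions(band)
    freq <- (bd$low + bd$high) / 2
    freq_range <- c(bd$low, bd$high)
  } else {
    freq <- as.numeric(band)
    freq_range <- c(freq, freq)
    band <- paste0(freq, "Hz")
  }
  edges <- tibble::as_tibble(edges)
  req <- c("i", "j", "delta", "kappa")
  if (!all(req %in% names(edges))) {
    stop("`edges` needs columns i, j, delta, kappa", call. = FALSE)
  }
  if (nrow(edges) > 0) {
    if (any(edges$i == edges$j)) stop("self-coupling edges are not allowed", call. = FALSE)
    if (any(edges$delta <= -pi | edges$delta >= pi)) {
      stop("`delta` must lie in (-pi, pi)", call. = FALSE)
    }
    if (any(edges$kappa < 0)) stop("`kappa` must be >= 0", call. = FALSE)
    if (anyDuplicated(edges$j)) {
      stop("each channel may be driven by at most one edge", call. = FALSE)
    }
  }
  stopifnot(noise_sd >= 0, drift_sd >= 0, all(amplitude > 0))
  structure(list(band = band, freq = freq, freq_range = freq_range,
                 edges = edges, amplitude = amplitude, noise_sd = noise_sd,
                 drift_sd = drift_sd),
            class = "coupling_spec")
}

# wrapped-normal circular noise with von Mises-style concentration kappa;
# kappa = Inf -> 0, kappa = 0 -> uniform on (-pi, pi]
rwrapped <- function(n, kappa) {
  if (is.infinite(kappa)) return(rep(0, n))
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  x <- stats::rnorm(n, 0, 1 / sqrt(kappa))
  (x + pi) %% (2 * pi) - pi
}

# latent phase ramp with frequency jitter. Deterministic case (no drift):
# an exact ramp at the centre frequency starting at phase 0. Stochastic
# case: each channel draws its own base frequency within the band, starts
# at a uniform phase and accumulates a random-walk drift, so independent
# channels are band-limited yet mutually incoherent.
latent_phase <- function(n, freq_range, rate, drift_sd) {
  if (drift_sd == 0) {
    return(2 * pi * mean(freq_range) * (seq_len(n) - 1) / rate)
  }
  f <- stats::runif(1, freq_range[1], freq_range[2])
  2 * pi * f * (seq_len(n) - 1) / rate +
    stats::runif(1, -pi, pi) + cumsum(stats::rnorm(n, 0, drift_sd))
}

#' Generate a synthetic phase-coupled multichannel recording
#'
#' Each channel is a sum over the supplied coupling specs (one per band
#' component) of `amplitude * cos(phase)` plus additive white noise, where
#' the latent phases follow the coupling graph of each spec: a driven
#' channel's phase is its driver's phase minus `delta` plus wrapped phase
#' noise, so the pair's instantaneous phase difference is `delta` plus that
#' noise. Driver chains are resolved in dependency order; cycles are an
#' error.
#'
#' @param spec A [coupling_spec()] or a list of them.
#' @param n_channels Number of channels (>= 1).
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Optional integer seed making the output reproducible.
#' @param subject_id,condition Tags forwarded to the [recording()].
#' @return A [recording()].
#' @export
#' @examples
#' sp <- coupling_spec("alpha", data.frame(i = 1, j = 2, delta = pi / 2, kappa = Inf))
#' rec <- generate_recording(sp, n_channels = 4, duration_s = 2, rate = 200, seed = 1)
generate_recording <- function(spec, n_channels, duration_s, rate, seed = NULL,
                               subject_id = NA_character_,
                               condition = NA_character_) {
  if (inherits(spec, "coupling_spec")) spec <- list(spec)
  stopifnot(all(vapply(spec, inherits, TRUE, "coupling_spec")))
  if (duration_s <= 0 || rate <= 0) {
    stop("duration and rate must be positive", call. = FALSE)
  }
  if (n_channels < 1) stop("need at least one channel", call. = FALSE)
  for (sp in spec) {
    if (duration_s * rate < 2 * rate / max(sp$freq, 1e-9) &&
        duration_s * sp$freq < 2) {
      stop("recording too short: need at least two cycles of ", sp$band,
           call. = FALSE)
    }
    if (nrow(sp$edges) > 0 &&
        any(c(sp$edges$i, sp$edges$j) < 1 | c(sp$edges$i, sp$edges$j) > n_channels)) {
      stop("coupling edge references a channel outside 1..", n_channels,
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * rate)
  x <- matrix(0, nrow = n_channels, ncol = n)
  for (sp in spec) {
    amp <- rep_len(sp$amplitude, n_channels)
    phases <- matrix(NA_real_, nrow = n_channels, ncol = n)
    driven <- sp$edges$j
    free <- setdiff(seq_len(n_channels), driven)
    for (c_idx in free) {
      phases[c_idx, ] <- latent_phase(n, sp$freq_range, rate, sp$drift_sd)
    }
    pending <- sp$edges
    while (nrow(pending) > 0) {
      ready <- !is.na(phases[pending$i, 1, drop = TRUE])
      if (!any(ready)) {
        stop("coupling edges contain a cycle", call. = FALSE)
      }
      for (k in which(ready)) {
        e <- pending[k, ]
        phases[e$j, ] <- phases[e$i, ] - e$delta + rwrapped(n, e$kappa)
      }
      pending <- pending[!ready, , drop = FALSE]
    }
    x <- x + amp * cos(phases)
    if (sp$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n_channels * n, 0, sp$noise_sd),
                      nrow = n_channels)
    }
  }
  recording(x, rate = rate, subject_id = subject_id, condition = condition)
}

#' Specify a synthetic cohort with known group structure
#'
#' Defines a three-group, two-condition resting-state cohort emulating the
#' early-implant (eCI), late-implant (lCI) and normal-hearing (NH) design:
#' per-group subject counts, covariate distributions (age in years,
#' nonverbal IQ), a hub-coupling template per group and condition, and a
#' linear behavioural model tying speech-perception accuracy (ACC, %) to
#' the subject's ground-truth hub breadth in the eyes-closed condition.
#'
#' Each subject-condition recording carries a theta-band hub: channel 1 is
#' phase-coupled (lag `delta`, concentration `kappa`) to `h` neighbouring
#' channels, where `h` is drawn uniformly from the group/condition range.
#' A broader hub yields a more star-like spanning tree (higher leaf number
#' and kappa), so group ranges that differ only in the eyes-closed
#' condition inject a group-by-condition interaction in tree topology, and
#' the behavioural slope on `h` injects a topology-behaviour correlation.
#' Default group sizes are 31/24/29; covariate means and SDs follow the
#' study demographics; default effect magnitudes target standardized
#' effects of about 1-1.5 SD between groups and metric-behaviour
#' correlations near 0.5-0.6.
#'
#' @param n_per_group Named vector of subject counts.
#' @param hub_range_ec Named list of `c(min, max)` hub-breadth ranges for
#'   the eyes-closed condition, one per group.
#' @param hub_range_eo Hub-breadth range shared by all groups in the
#'   eyes-open condition.
#' @param band Coupled band label.
#' @param delta,kappa Coupling lag (radians) and phase-noise concentration.
#' @param n_channels,duration_s,rate Recording geometry per subject and
#'   condition.
#' @param noise_sd,drift_sd Additive noise SD and phase-jitter SD.
#' @param behavior List with `intercept`, `slope` (per unit hub breadth)
#'   and `noise_sd`, on the 0-100 accuracy scale (clipped after the linear
#'   model).
#' @param age,iq Named lists of per-group `mean` and `sd` vectors.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(eCI = 31, lCI = 24, NH = 29),
                        hub_range_ec = list(eCI = c(5, 9), lCI = c(2, 5),
                                            NH = c(5, 9)),
                        hub_range_eo = c(3, 7),
                        band = "theta", delta = pi / 2, kappa = 6,
                        n_channels = 14, duration_s = 8, rate = 128,
                        noise_sd = 0.5, drift_sd = 0.05,
                        behavior = list(intercept = 45, slope = 4, noise_sd = 9),
                        age = list(mean = c(eCI = 8.8, lCI = 10.8, NH = 9.1),
                                   sd = c(eCI = 2.9, lCI = 2.9, NH = 1.7)),
                        iq = list(mean = c(eCI = 113, lCI = 108, NH = 116),
                                  sd = c(eCI = 9, lCI = 8, NH = 8))) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("`n_per_group` must be a named vector", call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("every group needs at least one subject", call. = FALSE)
  if (!setequal(groups, names(hub_range_ec))) {
    stop("`hub_range_ec` must name the same groups as `n_per_group`", call. = FALSE)
  }
  max_hub <- max(unlist(hub_range_ec), hub_range_eo)
  if (max_hub + 1 > n_channels) {
    stop("hub breadth exceeds available channels", call. = FALSE)
  }
  stopifnot(behavior$noise_sd >= 0, noise_sd >= 0)
  structure(list(n_per_group = n_per_group, hub_range_ec = hub_range_ec,
                 hub_range_eo = hub_range_eo, band = band, delta = delta,
                 kappa = kappa, n_channels = n_channels,
                 duration_s = duration_s, rate = rate, noise_sd = noise_sd,
                 drift_sd = drift_sd, behavior = behavior, age = age, iq = iq),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of paired EC/EO recordings
#'
#' Draws per-subject covariates, hub breadths and behavioural scores under
#' the [cohort_spec()] model and synthesizes one eyes-closed and one
#' eyes-open recording per subject via [generate_recording()]. One master
#' seed spawns independent per-subject substreams, so the whole cohort is
#' reproducible while subjects stay independent.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @return A list with `subjects` (tibble: subject_id, group, age, iq, acc,
#'   plus ground-truth hub breadths `hub_ec`, `hub_eo`), `recordings`
#'   (named list per subject of `EC`/`EO` [recording()]s) and `spec`.
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  groups <- names(spec$n_per_group)
  subj <- tibble::tibble(
    group = rep(groups, times = spec$n_per_group)
  )
  n <- nrow(subj)
  subj$subject_id <- sprintf("S%03d", seq_len(n))
  subj$seed <- sample.int(.Machine$integer.max - 1L, n)
  subj$age <- round(unname(stats::rnorm(n, spec$age$mean[subj$group],
                                        spec$age$sd[subj$group])), 1)
  subj$age <- pmax(subj$age, 4)
  subj$iq <- round(unname(stats::rnorm(n, spec$iq$mean[subj$group],
                                       spec$iq$sd[subj$group])))
  rng_ec <- do.call(rbind, spec$hub_range_ec)[subj$group, , drop = FALSE]
  subj$hub_ec <- unname(rng_ec[, 1] +
                          floor(stats::runif(n) * (rng_ec[, 2] - rng_ec[, 1] + 1)))
  subj$hub_eo <- spec$hub_range_eo[1] +
    floor(stats::runif(n) * (spec$hub_range_eo[2] - spec$hub_range_eo[1] + 1))
  b <- spec$behavior
  subj$acc <- b$intercept + b$slope * subj$hub_ec + stats::rnorm(n, 0, b$noise_sd)
  subj$acc <- unname(round(pmin(pmax(subj$acc, 0), 100), 2))

  hub_spec <- function(h) {
    edges <- if (h > 0) {
      data.frame(i = 1L, j = seq_len(h) + 1L, delta = spec$delta,
                 kappa = spec$kappa)
    } else {
      data.frame(i = integer(), j = integer(), delta = numeric(),
                 kappa = numeric())
    }
    coupling_spec(spec$band, edges, amplitude = 1, noise_sd = spec$noise_sd,
                  drift_sd = spec$drift_sd)
  }
  recs <- purrr::map(seq_len(n), function(k) {
    list(
      EC = generate_recording(hub_spec(subj$hub_ec[k]), spec$n_channels,
                              spec$duration_s, spec$rate,
                              seed = subj$seed[k],
                              subject_id = subj$subject_id[k], condition = "EC"),
      EO = generate_recording(hub_spec(subj$hub_eo[k]), spec$n_channels,
                              spec$duration_s, spec$rate,
                              seed = subj$seed[k] + 1L,
                              subject_id = subj$subject_id[k], condition = "EO")
    )
  })
  names(recs) <- subj$subject_id
  list(
    subjects = dplyr::select(subj, "subject_id", "group", "age", "iq", "acc",
                             "hub_ec", "hub_eo"),
    recordings = recs,
    spec = spec
  )
}

#' Write / read the subject table as CSV
#'
#' Columns `subject_id`, `group`, `age`, `iq`, `acc` (ground-truth columns
#' are kept if present).
#'
#' @param subjects Subject tibble from [generate_cohort()].
#' @param path CSV path.
#' @return `path` invisibly / a tibble.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("subject_id", "group", "age", "iq", "acc")
  if (!all(req %in% names(tbl))) {
    stop("subject table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tbl
}
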