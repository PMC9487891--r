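#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the study defaults:
#' broadband conditioning 0.5-30 Hz resampled to 500 Hz, 2-s epochs with
#' 72 kept per subject and condition, the eight-channel periocular
#' exclusion list, the four analysis bands, the six-region ROI set, a 5%
#' Hilbert edge trim, the 1e-12 zero-PLI floor, 5000 permutations and
#' alpha 0.05.
#'
#' @param bands Band definition tibble.
#' @param filter_low,filter_high Broadband conditioning edges (Hz).
#' @param target_rate Resampling rate (Hz); `NULL` keeps the input rate.
#' @param epoch_length_s Epoch length (s).
#' @param n_epochs Epochs kept per subject and condition.
#' @param reject_threshold Peak-amplitude epoch rejection threshold.
#' @param eye_channels Channel exclusion list (only channels present in a
#'   recording are dropped during the pipeline).
#' @param rois Named ROI list, or `NULL` to skip ROI-pair connectivity.
#' @param roi_pairs Two-column matrix of region pairings.
#' @param edge_frac Hilbert edge-trim fraction.
#' @param eps Zero-PLI distance floor.
#' @param n_perm Correlation permutations.
#' @param alpha Significance level.
#' @param covariates Covariate columns used by the statistical stage.
#' @param seed Seed for the stochastic statistics (permutations).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bands = band_definitions(),
                            filter_low = 0.5, filter_high = 30,
                            target_rate = 500,
                            epoch_length_s = 2, n_epochs = 72,
                            reject_threshold = Inf,
                            eye_channels = default_eye_channels(),
                            rois = default_roi_set(),
                            roi_pairs = cbind(c("TL", "TR", "TL", "TR"),
                                              c("OL", "OR", "PL", "PR")),
                            edge_frac = 0.05, eps = 1e-12,
                            n_perm = 5000, alpha = 0.05,
                            covariates = c("age", "iq"),
                            seed = 1L) {
  bands <- tibble::as_tibble(bands)
  validate_bands(bands)
  if (!is.null(target_rate) && filter_high > target_rate / 2) {
    stop("filter_high exceeds the target Nyquist frequency", call. = FALSE)
  }
  stopifnot(epoch_length_s > 0, is.null(n_epochs) || n_epochs >= 1,
            edge_frac >= 0, edge_frac < 0.5, eps > 0, n_perm >= 1,
            alpha > 0, alpha < 1)
  if (!is.null(rois)) validate_roi_set(rois)
  structure(list(bands = bands, filter_low = filter_low,
                 filter_high = filter_high, target_rate = target_rate,
                 epoch_length_s = epoch_length_s, n_epochs = n_epochs,
                 reject_threshold = reject_threshold,
                 eye_channels = eye_channels, rois = rois,
                 roi_pairs = roi_pairs, edge_frac = edge_frac, eps = eps,
                 n_perm = n_perm, alpha = alpha, covariates = covariates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (JSON or YAML)
#'
#' Round-trips losslessly; the format is chosen from the file extension.
#'
#' @param config A [pipeline_config()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `path` invisibly / a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$bands <- as.list(lst$bands)
  lst$roi_pairs <- list(a = lst$roi_pairs[, 1], b = lst$roi_pairs[, 2])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    stop("config path must end in .json, .yaml or .yml", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lst$bands <- tibble::as_tibble(lst$bands)
  lst$roi_pairs <- cbind(unlist(lst$roi_pairs$a), unlist(lst$roi_pairs$b))
  if (!is.null(lst$rois)) lst$rois <- purrr::map(lst$rois, unlist)
  if (length(lst$reject_threshold) == 0 || is.character(lst$reject_threshold)) {
    lst$reject_threshold <- Inf    # JSON cannot carry Inf
  }
  do.call(pipeline_config, lst[setdiff(names(lst), character(0))])
}

# preprocess + connectivity + tree stage for one recording; returns
# per-epoch metrics and ROI-pair values. Band filtering runs on the
# continuous conditioned signal (one filter pass per channel and band,
# avoiding per-epoch transients); epoch selection is decided on the
# broadband signal and the same windows are sliced from every band.
process_recording <- function(rec, config) {
  cond <- condition_signal(rec, config$filter_low, config$filter_high,
                           config$target_rate)
  drop <- intersect(config$eye_channels, cond$labels)
  if (length(drop) > 0) cond <- drop_channels(cond, drop)
  ep <- epoch_and_select(cond, config$epoch_length_s, config$n_epochs,
                         config$reject_threshold)
  sel <- attr(ep, "selected") %||% seq_len(dim(ep$data)[1])
  spe <- round(config$epoch_length_s * cond$rate)
  roi_ok <- !is.null(config$rois) &&
    all(unlist(config$rois) %in% cond$labels)
  res <- purrr::map(seq_len(nrow(config$bands)), function(b) {
    filt <- butter_bandpass(cond$data, low = config$bands$low[b],
                            high = config$bands$high[b], rate = cond$rate)
    arr <- array(NA_real_, dim = c(length(sel), nrow(filt), spe))
    for (k in seq_along(sel)) {
      arr[k, , ] <- filt[, ((sel[k] - 1) * spe + 1):(sel[k] * spe)]
    }
    bep <- epoch_set(arr, rate = cond$rate, labels = cond$labels,
                     band = config$bands$band[b],
                     subject_id = rec$subject_id, condition = rec$condition)
    bep <- rereference_average(bep)
    ph <- instantaneous_phase(bep, config$edge_frac)
    pli <- pli_matrix(ph)
    metrics <- epoch_tree_metrics(pli, config$eps)
    metrics$band <- bep$band
    roi <- NULL
    if (roi_ok) {
      roi <- roi_pair_pli(pli, config$roi_pairs, config$rois)
      roi$band <- bep$band
    }
    list(metrics = metrics, roi = roi)
  })
  list(
    metrics = dplyr::bind_rows(purrr::map(res, "metrics")) |>
      dplyr::mutate(subject_id = rec$subject_id, condition = rec$condition),
    roi = dplyr::bind_rows(purrr::compact(purrr::map(res, "roi"))) |>
      (\(d) if (nrow(d) > 0) dplyr::mutate(d, subject_id = rec$subject_id,
                                           condition = rec$condition) else d)()
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes signal conditioning, epoching, average re-referencing, band
#' decomposition, PLI connectivity, MST extraction and subject-level
#' aggregation for every subject and condition, then the statistical
#' stage: normality-gated (parametric or aligned-rank) mixed ANOVA per
#' metric and band with covariates, Bonferroni post-hocs, and
#' permutation-tested behaviour correlations for the metrics of
#' `cor_metrics` in `cor_band`/`cor_condition`. With `output_dir` set, the
#' metric panel, ROI table, statistical report and a manifest (config plus
#' seeds) are written as CSV/JSON; reruns with identical inputs are
#' bit-identical.
#'
#' @param cohort List with `subjects` (tibble with `subject_id`, `group`,
#'   covariates and `acc`) and `recordings` (per subject, a list with
#'   `EC` and `EO` [recording()]s), e.g. from [generate_cohort()].
#' @param config A [pipeline_config()].
#' @param metrics Metric columns analysed by the ANOVA stage.
#' @param cor_metrics,cor_band,cor_condition Correlation family.
#' @param output_dir Optional output directory.
#' @return List with `metrics` (subject-level panel), `roi` (ROI-pair
#'   PLI), `anova`, `posthoc`, `correlations`, `shapiro` tibbles.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         metrics = c("leaf", "diameter", "kappa",
                                     "tree_hierarchy", "degree_max"),
                         cor_metrics = c("kappa", "leaf", "diameter"),
                         cor_band = "theta", cor_condition = "EC",
                         output_dir = NULL) {
  subjects <- cohort$subjects
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  per_rec <- purrr::map(subjects$subject_id, function(sid) {
    recs <- cohort$recordings[[sid]]
    if (is.null(recs)) {
      stop("no recordings for subject ", sid, call. = FALSE)
    }
    purrr::map(c("EC", "EO"), function(cond) {
      if (is.null(recs[[cond]])) {
        stop("missing ", cond, " recording for subject ", sid, call. = FALSE)
      }
      process_recording(recs[[cond]], config)
    })
  })
  flat <- purrr::flatten(per_rec)
  metric_epochs <- dplyr::bind_rows(purrr::map(flat, "metrics"))
  roi_epochs <- dplyr::bind_rows(purrr::map(flat, "roi"))
  panel <- aggregate_epochs(metric_epochs,
                            by = c("subject_id", "condition", "band"))
  roi_panel <- NULL
  if (nrow(roi_epochs) > 0) {
    roi_panel <- roi_epochs |>
      dplyr::group_by(.data$subject_id, .data$condition, .data$band,
                      .data$roi_a, .data$roi_b) |>
      dplyr::summarise(pli = mean(.data$pli), .groups = "drop")
  }
  panel <- dplyr::left_join(panel, subjects, by = "subject_id")

  stat <- analyze_metric_panel(panel, metrics = metrics, config = config)
  cor_tbl <- NULL
  sub_ec <- panel[panel$band == cor_band & panel$condition == cor_condition, ]
  if (nrow(sub_ec) > 0 && "acc" %in% names(sub_ec)) {
    cor_tbl <- correlate_behavior(sub_ec, intersect(cor_metrics, names(sub_ec)),
                                  behavior = "acc", n_perm = config$n_perm,
                                  seed = config$seed)
    cor_tbl$band <- cor_band
    cor_tbl$condition <- cor_condition
  }
  out <- list(metrics = panel, roi = roi_panel, anova = stat$anova,
              posthoc = stat$posthoc, shapiro = stat$shapiro,
              correlations = cor_tbl)
  if (!is.null(output_dir)) write_pipeline_outputs(out, config, output_dir)
  out
}

#' Normality-gated ANOVA stage over a metric panel
#'
#' For each band and metric: log-transform, Shapiro-Wilk gate per
#' group-condition cell, then the parametric or aligned-rank mixed ANOVA
#' with covariates, plus Bonferroni post-hocs.
#'
#' @param panel Subject-level metric panel (one row per subject x
#'   condition x band) joined with the subject table.
#' @param metrics Metric column names.
#' @param config A [pipeline_config()].
#' @return List of tibbles `anova`, `posthoc`, `shapiro`.
#' @export
analyze_metric_panel <- function(panel, metrics, config = pipeline_config()) {
  combos <- tidyr::expand_grid(band = unique(panel$band), metric = metrics)
  res <- purrr::pmap(combos, function(band, metric) {
    sub <- panel[panel$band == band, ]
    gate <- transform_and_gate(sub, metric, alpha = config$alpha)
    covs <- intersect(config$covariates, names(sub))
    fit <- if (gate$route == "art") {
      art_anova(gate$data, ".value", covs)
    } else {
      mixed_anova(gate$data, ".value", covs)
    }
    ph <- posthoc_bonferroni(gate$data, ".value", covs)
    list(
      anova = dplyr::mutate(fit$table, band = band, metric = metric,
                            .before = 1),
      posthoc = dplyr::mutate(ph, band = band, metric = metric, .before = 1),
      shapiro = dplyr::mutate(gate$shapiro, band = band, metric = metric,
                              .before = 1)
    )
  })
  list(anova = dplyr::bind_rows(purrr::map(res, "anova")),
       posthoc = dplyr::bind_rows(purrr::map(res, "posthoc")),
       shapiro = dplyr::bind_rows(purrr::map(res, "shapiro")))
}

write_pipeline_outputs <- function(out, config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
    }
  }
  wcsv(out$metrics, "mst_metrics.csv")
  wcsv(out$roi, "roi_pli.csv")
  wcsv(out$anova, "stat_report.csv")
  wcsv(out$posthoc, "posthoc.csv")
  wcsv(out$correlations, "correlations.csv")
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
    config_hash = sum(utf8ToInt(cfg_json)) %% 1e9,
    seed = config$seed,
    n_subjects = length(unique(out$metrics$subject_id))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
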