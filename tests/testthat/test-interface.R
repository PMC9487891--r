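test_that("native recording format round-trips losslessly", {
  set.seed(50)
  rec <- recording(matrix(rnorm(3 * 200), nrow = 3), 128,
                   labels = c("E1", "E2", "E3"), subject_id = "S007",
                   condition = "EO")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-15)
  expect_identical(back$labels, rec$labels)
  expect_identical(back$subject_id, "S007")
  expect_identical(back$condition, "EO")
  expect_equal(back$rate, 128)
})

test_that("native reader validates sidecar and shape", {
  rec <- recording(matrix(rnorm(2 * 50), nrow = 2), 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$n_samples <- 999
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "shape mismatch")
  file.remove(paste0(path, ".json"))
  expect_error(read_recording(path, format = "native"), "sidecar")
  expect_error(read_recording("/nonexistent/file.tsv"), "not found")
})

test_that("EDF round-trip preserves shape, rate and values", {
  set.seed(51)
  rec <- recording(matrix(rnorm(4 * 512, sd = 40), nrow = 4), 128,
                   subject_id = "S001")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(dim(back$data), dim(rec$data))
  expect_equal(back$rate, 128)
  expect_identical(back$labels, rec$labels)
  # int16 quantization over the channel range
  expect_equal(back$data, rec$data, tolerance = 1e-2)
  rng <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(back$data - rec$data)), rng / 65535 * 1.01)
})

test_that("truncated EDF files raise explicit parse errors", {
  rec <- recording(matrix(rnorm(2 * 256), nrow = 2), 128)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:(length(full) - 100)], path)
  expect_error(read_edf(path), "truncated EDF data")
  writeBin(full[1:100], path)
  expect_error(read_edf(path), "truncated EDF header")
})

test_that("pipeline config round-trips through JSON and YAML", {
  cfg <- pipeline_config(n_epochs = 6, n_perm = 250, seed = 17,
                         bands = band_definitions(c("theta", "alpha")))
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$bands, cfg$bands)
    expect_equal(back$rois, cfg$rois)
    expect_equal(back$n_perm, cfg$n_perm)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$roi_pairs, cfg$roi_pairs, ignore_attr = TRUE)
  }
  expect_error(write_config(cfg, "x.txt"), "must end in")
})

small_cohort <- function(seed = 61) {
  generate_cohort(cohort_spec(n_per_group = c(eCI = 2, lCI = 2, NH = 2),
                              duration_s = 8), seed = seed)
}

small_config <- function() {
  pipeline_config(bands = band_definitions(c("theta", "alpha")),
                  target_rate = NULL, n_epochs = 3,
                  eye_channels = character(0), rois = NULL,
                  n_perm = 99, seed = 3)
}

test_that("pipeline bookkeeping: subjects x conditions x bands rows", {
  res <- run_pipeline(small_cohort(), small_config(),
                      metrics = c("kappa", "leaf"),
                      cor_metrics = "kappa")
  expect_equal(nrow(res$metrics), 6 * 2 * 2)
  expect_setequal(unique(res$metrics$band), c("theta", "alpha"))
  expect_true(all(res$metrics$n_epochs == 3))
  expect_equal(sort(unique(res$anova$metric)), c("kappa", "leaf"))
  expect_equal(nrow(res$correlations), 3)   # one metric x three groups
})

test_that("pipeline reruns are bit-identical on disk", {
  coh <- small_cohort()
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(coh, cfg, metrics = "kappa", cor_metrics = "kappa",
               output_dir = d1)
  run_pipeline(coh, cfg, metrics = "kappa", cor_metrics = "kappa",
               output_dir = d2)
  for (f in c("mst_metrics.csv", "stat_report.csv", "correlations.csv",
              "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("a missing condition recording aborts naming the subject", {
  coh <- small_cohort()
  coh$recordings$S003$EO <- NULL
  expect_error(run_pipeline(coh, small_config()), "EO recording.*S003")
  coh$recordings$S003 <- NULL
  expect_error(run_pipeline(coh, small_config()), "S003")
})

test_that("tidy and autoplot surfaces work on pipeline objects", {
  set.seed(71)
  m <- rand_pli_matrix(8)
  t <- build_mst(m)
  expect_equal(nrow(tidy(t)), 7)
  expect_equal(glance(t)$leaf, tree_metrics(t)$leaf)
  ph <- structure(list(data = array(runif(1 * 8 * 50, -pi, pi),
                                    dim = c(1, 8, 50)),
                       labels = paste0("E", 1:8), band = "theta", rate = 100,
                       edge_frac = 0, subject_id = NA, condition = NA),
                  class = "phase_epoch")
  p <- autoplot(pli_matrix(ph))
  expect_s3_class(p, "ggplot")
  panel <- tibble::tibble(group = rep(c("eCI", "lCI"), each = 4),
                          condition = rep(c("EC", "EO"), 4),
                          band = "theta", kappa = rnorm(8), acc = rnorm(8))
  expect_s3_class(plot_metric_by_group(panel, "kappa"), "ggplot")
  expect_s3_class(plot_behavior_correlation(panel, "kappa"), "ggplot")
})
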