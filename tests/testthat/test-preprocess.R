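make_sine_rec <- function(freq, rate = 1000, dur = 4, amp = 1, n_ch = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  recording(matrix(rep(amp * sin(2 * pi * freq * t), each = n_ch),
                   nrow = n_ch, byrow = FALSE), rate)
}

test_that("broadband conditioning preserves passband tones and halves samples", {
  rec <- make_sine_rec(10, rate = 1000, dur = 4)
  out <- condition_signal(rec, 0.5, 30, 500)
  expect_equal(ncol(out$data), ncol(rec$data) / 2)
  expect_equal(out$rate, 500)
  # steady-state amplitude preserved within 1%
  mid <- out$data[1, 500:1500]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
})

test_that("stopband tones are attenuated below 5% RMS", {
  rec <- make_sine_rec(50, rate = 1000, dur = 4)
  out <- condition_signal(rec, 0.5, 30, NULL)
  mid <- 1000:3000
  expect_lt(sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(rec$data[1, mid]^2)),
            0.05)
})

test_that("conditioning is linear and maps zero to zero", {
  set.seed(4)
  x <- matrix(rnorm(2 * 1000), nrow = 2)
  rec1 <- recording(x, 250)
  rec4 <- recording(4 * x, 250)
  out1 <- condition_signal(rec1, 0.5, 30, NULL)
  out4 <- condition_signal(rec4, 0.5, 30, NULL)
  expect_equal(out4$data, 4 * out1$data, tolerance = 1e-12)
  zero <- condition_signal(recording(matrix(0, 1, 1000), 250), 0.5, 30, NULL)
  expect_equal(max(abs(zero$data)), 0)
  expect_error(condition_signal(rec1, 0.5, 200, 250), "Nyquist")
})

test_that("channel exclusion retains 120 of 128 channels and keeps order", {
  rec <- recording(matrix(rnorm(128 * 100), nrow = 128), 500)
  out <- drop_channels(rec)
  expect_equal(nrow(out$data), 120)
  expect_identical(out$labels, setdiff(montage_labels(128),
                                       default_eye_channels()))
  expect_identical(drop_channels(rec, character(0))$data, rec$data)
  expect_error(drop_channels(rec, "E999"), "unknown channel")
  expect_error(drop_channels(rec, montage_labels(128)), "every channel")
})

test_that("epoching tiles the recording and head-selects survivors", {
  rate <- 32
  rec <- recording(matrix(rnorm(2 * 300 * rate, sd = 1), nrow = 2), rate)
  expect_equal(dim(epoch_and_select(rec, 2, 72)$data)[1], 72)
  expect_equal(dim(epoch_and_select(rec, 2, NULL)$data)[1], 150)
  # spikes in epochs 3 and 7 -> filter-then-head keeps {1,2,4,5,6,8}
  spe <- 2 * rate
  rec$data[1, (2 * spe) + 1] <- 100
  rec$data[1, (6 * spe) + 5] <- -100
  ep <- epoch_and_select(rec, 2, 6, reject_threshold = 50)
  expect_identical(attr(ep, "selected"), c(1L, 2L, 4L, 5L, 6L, 8L))
  expect_error(epoch_and_select(rec, 2, 151), "151 requested")
  expect_error(epoch_and_select(rec, 2, 150, reject_threshold = 50),
               "survive")
})

test_that("epoching then concatenation reconstructs the trimmed recording", {
  rec <- recording(matrix(rnorm(3 * 650), nrow = 3), 100)
  ep <- epoch_and_select(rec, 2, NULL)
  rebuilt <- do.call(cbind, lapply(seq_len(dim(ep$data)[1]),
                                   function(e) matrix(ep$data[e, , ], nrow = 3)))
  expect_identical(rebuilt, unname(rec$data[, 1:600]))
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  set.seed(11)
  ep <- epoch_set(array(rnorm(4 * 6 * 50), dim = c(4, 6, 50)), 100,
                  paste0("E", 1:6))
  ref <- rereference_average(ep)
  expect_lt(max(abs(apply(ref$data, c(1, 3), mean))), 1e-10)
  expect_warning(again <- rereference_average(ref), "already")
  expect_identical(again$data, ref$data)
  # zero-mean two-channel input is unchanged
  v <- rnorm(100)
  arr2 <- array(0, dim = c(1, 2, 100))
  arr2[1, 1, ] <- v; arr2[1, 2, ] <- -v
  ep2 <- epoch_set(arr2, 100, c("E1", "E2"))
  expect_equal(rereference_average(ep2)$data, ep2$data, tolerance = 1e-12)
  # all-equal channels collapse to zero
  w <- rnorm(50)
  arr3 <- array(0, dim = c(1, 3, 50))
  for (ch in 1:3) arr3[1, ch, ] <- w
  ep3 <- epoch_set(arr3, 100, paste0("E", 1:3))
  expect_lt(max(abs(rereference_average(ep3)$data)), 1e-12)
})

test_that("band decomposition separates tones and conserves variance", {
  rate <- 250
  t <- seq(0, 16 - 1 / rate, by = 1 / rate)
  rec <- recording(matrix(sin(2 * pi * 6 * t), nrow = 1), rate)
  ep <- epoch_and_select(rec, 16, NULL)   # one long epoch: steady-state view
  out <- band_decompose(ep)
  expect_named(out, c("delta", "theta", "alpha", "beta"))
  expect_true(all(vapply(out, function(o) identical(dim(o$data), dim(ep$data)),
                         TRUE)))
  v_in <- stats::var(as.numeric(ep$data))
  expect_gt(stats::var(as.numeric(out$theta$data)) / v_in, 0.9)
  expect_lt(stats::var(as.numeric(out$alpha$data)) / v_in, 0.05)

  # white noise: band variances approximately partition broadband variance
  set.seed(9)
  wn <- condition_signal(recording(matrix(rnorm(16 * rate), nrow = 1), rate),
                         0.5, 30, NULL)
  epw <- epoch_and_select(wn, 16, NULL)
  bands <- band_decompose(epw)
  v_tot <- stats::var(as.numeric(epw$data))
  v_sum <- sum(vapply(bands, function(b) stats::var(as.numeric(b$data)),
                      numeric(1)))
  expect_equal(v_sum / v_tot, 1, tolerance = 0.15)
})

test_that("band power concentrates on tones and is flat for white noise", {
  rate <- 250
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  ep <- epoch_and_select(recording(matrix(sin(2 * pi * 10 * t), nrow = 1),
                                   rate), 2, NULL)
  bp <- band_power(ep)
  expect_gte(bp$rel_power[bp$band == "alpha"], 0.99)
  expect_equal(sum(bp$rel_power), 1, tolerance = 1e-6)

  rel <- replicate(20, {
    ep <- epoch_and_select(recording(matrix(rnorm(16 * rate), nrow = 1), rate),
                           2, NULL)
    band_power(ep)$rel_power
  })
  widths <- band_definitions()$high - band_definitions()$low
  expect_equal(rowMeans(rel), widths / 29.5, tolerance = 0.05)

  zero_ep <- epoch_set(array(0, dim = c(2, 1, 500)), rate, "E1")
  expect_error(instantaneous_phase(zero_ep), "zero-variance")
  bz <- band_power(zero_ep)
  expect_true(all(is.na(bz$rel_power)))
  expect_true(all(bz$power == 0))
})
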