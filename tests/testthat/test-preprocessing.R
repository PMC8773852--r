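test_that("the periodized db6 transform reconstructs perfectly and conserves energy", {
  set.seed(1)
  for (n in c(256L, 512L, 1024L)) {
    x <- rnorm(n)
    co <- evombn:::.dwt(x, 8L)
    expect_equal(evombn:::.idwt(co), x, tolerance = 1e-12)
    expect_equal(sum(x^2), sum(unlist(co$d)^2) + sum(co$a^2), tolerance = 1e-10)
  }
})

test_that("denoising removes DC and baseline wander but keeps morphology", {
  y <- denoise_signal(rep(5, 300))
  expect_lt(abs(mean(y)), 1e-9)
  expect_identical(denoise_signal(rep(0, 512)), rep(0, 512))
  expect_error(denoise_signal(rnorm(100)), "shorter")
  # clean beat train + slow sinusoid: correlation with the clean signal improves
  clean <- generate_record(fs = 250, duration = 20, bpm = 60, seed = 3,
                           noise_sd = 0, baseline_amp = 0)$signal[2, ]
  t_s <- (seq_along(clean) - 1) / 250
  dirty <- clean + 0.8 * sin(2 * pi * 0.05 * t_s)
  den <- denoise_signal(dirty, fs = 250)
  expect_gt(cor(den, clean), cor(dirty, clean))
})

test_that("resampling honors the rounded length contract and rescales peaks", {
  rec <- generate_record(fs = 1000, duration = 4, bpm = 60, seed = 1)
  out <- resample_record(rec, 250)
  expect_equal(ncol(out$signal), 1000L)
  expect_equal(out$fs, 250)
  expect_equal(out$rpeak_truth,
               as.integer(round((rec$rpeak_truth - 1L) / 4) + 1L))
  same <- resample_record(rec, 1000)
  expect_identical(same$signal, rec$signal)
  rec500 <- generate_record(fs = 500, duration = 8, bpm = 60, seed = 2)
  expect_equal(ncol(resample_record(rec500, 250)$signal), ncol(rec500$signal) / 2)
  expect_error(resample_record(rec, 2000), "upsampling")
})

test_that("R-peak detection recovers planted peaks and is deterministic", {
  rec <- generate_record(fs = 250, duration = 10, bpm = 60, seed = 1,
                         noise_sd = 0, baseline_amp = 0)
  det <- detect_rpeaks(rec$signal[2, ], 250)
  expect_length(det, length(rec$rpeak_truth))
  expect_true(all(abs(det - rec$rpeak_truth) <= 5))
  expect_identical(det, detect_rpeaks(rec$signal[2, ], 250))
  expect_identical(detect_rpeaks(rep(0, 1000), 250), integer(0))
  expect_true(all(diff(det) > 0))
})

test_that("segmentation cuts the inclusive 127+1+128 window and drops edges", {
  rec <- generate_record(fs = 250, duration = 4, bpm = 60, seed = 1)
  beats <- segment_beats(rec, c(200L))
  expect_length(beats, 1L)
  expect_equal(dim(beats[[1]]), c(12L, 256L))
  expect_equal(beats[[1]], rec$signal[, 73:328], ignore_attr = TRUE)
  expect_length(segment_beats(rec, c(100L)), 0L)   # 100 - 127 < 1
  expect_length(segment_beats(rec, c(900L)), 0L)   # 900 + 128 > 1000
  well <- seq(150L, 800L, length.out = 10L)
  expect_length(segment_beats(rec, as.integer(well)), 10L)
  rec$fs <- 500
  expect_error(segment_beats(rec, 200L), "250")
})

test_that("z-scoring matches the population formula and flags degenerate leads", {
  z <- zscore_beat(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(zscore_beat(z), z, tolerance = 1e-9)   # idempotent
  flat <- matrix(rnorm(2 * 10), 2, 10, dimnames = list(c("I", "II"), NULL))
  flat[2, ] <- 7
  expect_error(zscore_beat(flat), "lead II")
})

test_that("the composed chain yields only 256-sample, standardized beats", {
  rec <- generate_record(fs = 500, duration = 16, bpm = 66, seed = 9,
                         class_label = "IMI", noise_sd = 0.03, patient_id = "P9")
  ds <- preprocess_record(rec)
  expect_gt(dim(ds$x)[3], 5L)
  expect_equal(dim(ds$x)[1:2], c(12L, 256L))
  mus <- apply(ds$x, c(1, 3), mean)
  sds <- apply(ds$x, c(1, 3), function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(mus)), 1e-9)
  expect_lt(max(abs(sds - 1)), 1e-9)
  expect_true(all(ds$labels == "IMI"))
  expect_true(all(ds$patient_id == "P9"))
})
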