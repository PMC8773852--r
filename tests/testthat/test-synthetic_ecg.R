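test_that("generated records plant the requested beats and samples", {
  rec <- generate_record(fs = 250, duration = 10, bpm = 60, seed = 1)
  expect_length(rec$rpeak_truth, 10L)
  expect_equal(dim(rec$signal), c(12L, 2500L))
  rec2 <- generate_record(fs = 1000, duration = 4, bpm = 60, seed = 1)
  expect_equal(ncol(rec2$signal), 4000L)
  expect_true(all(rec$rpeak_truth >= 1 & rec$rpeak_truth <= 2500))
})

test_that("record generation is deterministic under a fixed seed", {
  a <- generate_record(fs = 250, duration = 10, bpm = 60, seed = 1)
  b <- generate_record(fs = 250, duration = 10, bpm = 60, seed = 1)
  expect_identical(a$signal, b$signal)
  expect_identical(a$rpeak_truth, b$rpeak_truth)
})

test_that("invalid record arguments are rejected", {
  expect_error(generate_record(duration = 0), "positive")
  expect_error(generate_record(bpm = -10), "positive")
  expect_error(generate_record(fs = 50), "100")
})

test_that("class signatures cover each territory's anatomical leads", {
  map <- mi_lead_map()
  expect_identical(map$AMI, c("V3", "V4"))
  expect_identical(map$IMI, c("II", "III", "aVF"))
  expect_setequal(map$ASMI, c("V1", "V2", "V3", "V4"))
  for (cls in c("AMI", "ASMI", "ALMI", "IMI", "ILMI")) {
    sig <- class_signature(cls)
    expect_true(all(map[[cls]] %in% sig$affected_leads))
  }
  expect_length(class_signature("HC")$affected_leads, 0L)
  set.seed(1)
  expect_length(class_signature("OMI")$affected_leads, 2L)
  expect_error(class_signature("XXX"), "unknown class")
})

test_that("beat datasets have the forced counts, shape and z-scoring", {
  ds <- generate_beat_dataset(50, c("HC", "IMI"), n_patients = 10,
                              noise_sd = 0.05, seed = 7)
  expect_equal(dim(ds$x), c(12L, 256L, 100L))
  expect_length(unique(ds$patient_id), 10L)
  mus <- apply(ds$x, c(1, 3), mean)
  sds <- apply(ds$x, c(1, 3), function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(mus)), 1e-6)
  expect_lt(max(abs(sds - 1)), 1e-6)
})

test_that("each patient carries exactly one class", {
  ds <- generate_beat_dataset(30, c("HC", "AMI", "IMI"), n_patients = 9, seed = 3)
  per_patient <- tapply(as.character(ds$labels), ds$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1L))
})

test_that("identical seeds give bit-identical datasets; zero noise collapses a class", {
  a <- generate_beat_dataset(10, c("HC", "IMI"), 4, noise_sd = 0.05, seed = 5)
  b <- generate_beat_dataset(10, c("HC", "IMI"), 4, noise_sd = 0.05, seed = 5)
  expect_identical(a$x, b$x)
  z <- generate_beat_dataset(5, c("IMI"), 2, noise_sd = 0, seed = 5)
  for (k in 2:5) expect_equal(z$x[, , k], z$x[, , 1])
})

test_that("the IMI perturbation lives on inferior leads, not elsewhere", {
  hc <- generate_beat_dataset(1, "HC", 1, noise_sd = 0, seed = 1)
  imi <- generate_beat_dataset(1, "IMI", 1, noise_sd = 0, seed = 1)
  dist <- rowMeans(abs(imi$x[, , 1] - hc$x[, , 1]))
  names(dist) <- ecg_lead_names()
  expect_gt(min(dist[c("II", "III", "aVF")]), dist["V1"])
})

test_that("dataset argument validation", {
  expect_error(generate_beat_dataset(10, c("HC", "ZZZ"), 5), "unknown class")
  expect_error(generate_beat_dataset(10, c("HC", "IMI"), 1), "n_patients")
  expect_error(generate_beat_dataset(10, "HC", 2, noise_sd = -1), "noise_sd")
})

test_that("beats survive a CSV round trip", {
  ds <- generate_beat_dataset(6, c("HC", "IMI"), 4, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_beats_csv(ds, path)
  back <- read_beats_csv(path)
  expect_equal(back$x, ds$x, tolerance = 1e-12)
  expect_identical(back$patient_id, ds$patient_id)
  expect_identical(as.character(back$labels), as.character(ds$labels))
})
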