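# zero-weight LSE model used by several tests: excitations are sigmoid(0)
zero_lse <- function(feat_dims = rep(4L, 12), class_mode = "multiclass",
                     class_set = c("A", "B")) {
  cfg <- lse_config(class_mode = class_mode,
                    positive_class = if (class_mode == "binary") "A" else NULL,
                    seed = 1)
  m <- evombn:::.new_lse(feat_dims, class_set, cfg)
  m$W1 <- m$W1 * 0; m$W2 <- m$W2 * 0; m$Wc <- m$Wc * 0
  m
}

test_that("squeeze is the per-lead mean and is linear", {
  y <- rep(list(c(2, 4)), 12)
  expect_equal(unname(lse_squeeze(y)), rep(3, 12))
  expect_equal(unname(lse_squeeze(rep(list(rep(0, 5)), 12))), rep(0, 12))
  y2 <- lapply(y, function(v) 2.5 * v)
  expect_equal(lse_squeeze(y2), 2.5 * lse_squeeze(y))
  expect_error(lse_squeeze(rep(list(numeric(0)), 12)), "empty")
})

test_that("excitation is the bounded two-layer gate with hidden width 12/r", {
  m <- zero_lse()
  expect_equal(unname(lse_excite(rep(1, 12), m)), rep(0.5, 12))
  expect_equal(nrow(m$W1), 12L)  # r = 1 -> hidden width 12
  m4 <- evombn:::.new_lse(rep(4L, 12), c("A", "B"), lse_config(r = 4, seed = 1))
  expect_equal(dim(m4$W1), c(3L, 12L))
  expect_equal(dim(m4$W2), c(12L, 3L))
  set.seed(2)
  e <- lse_excite(rnorm(12), m4)
  expect_true(all(e > 0 & e < 1))
  # saturating one output row drives that excitation to 1
  m4$W2[3, ] <- 1e6
  e <- lse_excite(rep(1, 12), m4)
  expect_equal(unname(e[3]), 1)
  expect_error(lse_config(r = 5), "divide")
})

test_that("scaling is elementwise and shape-preserving", {
  y <- rep(list(c(2, 4)), 12)
  expect_equal(lse_scale(y, rep(1, 12)), lapply(y, function(v) matrix(v, 1)))
  expect_true(all(unlist(lse_scale(y, rep(0, 12))) == 0))
  o <- lse_scale(y, rep(0.5, 12))
  expect_equal(as.numeric(o[[1]]), c(1, 2))
})

test_that("classification normalizes correctly in both modes", {
  set.seed(3)
  y <- lapply(1:12, function(i) rnorm(4))
  mm <- evombn:::.new_lse(rep(4L, 12), c("A", "B", "C"), lse_config(seed = 2))
  p <- lse_classify(y, mm)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, lse_classify(y, mm))
  mb <- evombn:::.new_lse(rep(4L, 12),  c("A", "rest"),
                          lse_config(class_mode = "binary", positive_class = "A",
                                     seed = 2))
  pb <- lse_classify(y, mb)
  expect_true(pb > 0 && pb < 1)
  expect_error(lse_classify(lapply(1:12, function(i) rnorm(9)), mm), "match")
})

test_that("forcing e = 1 reduces the LSE exactly to concatenation + FC", {
  set.seed(4)
  y <- lapply(1:12, function(i) rnorm(4))
  m <- evombn:::.new_lse(rep(4L, 12), c("A", "B"), lse_config(seed = 5))
  fwd <- lse_forward(m, y, force_identity = TRUE)
  expect_true(all(fwd$e == 1))
  z <- m$Wc %*% unlist(y) + m$bc
  manual <- exp(z - max(z)); manual <- manual / sum(manual)
  expect_equal(unname(fwd$p), as.numeric(manual), tolerance = 1e-12)
})

test_that("LSE training separates a single-informative-lead bank", {
  bank <- make_toy_bank(n = 120, signal_lead = 2, seed = 11)
  train <- which(seq_len(120) %% 4 != 0)
  test <- which(seq_len(120) %% 4 == 0)
  cfg <- lse_config(epochs = 30, class_mode = "binary", positive_class = "A",
                    seed = 3)
  res <- train_lse(bank, rep(17L, 12), config = cfg, idx = train)
  p <- predict_lse(res$model, bank, idx = test)
  acc <- mean((p >= 0.5) == (bank$labels[test] == "A"))
  expect_gt(acc, 0.9)
  expect_length(res$history, 30L)
})

test_that("training is seeded-deterministic and epochs = 0 is a no-op", {
  bank <- make_toy_bank(n = 40, seed = 12)
  cfg <- lse_config(epochs = 5, seed = 9)
  a <- train_lse(bank, rep(17L, 12), config = cfg)
  b <- train_lse(bank, rep(17L, 12), config = cfg)
  expect_identical(a$model$Wc, b$model$Wc)
  expect_identical(a$model$W1, b$model$W1)
  cfg0 <- lse_config(epochs = 0, seed = 9)
  m0 <- train_lse(bank, rep(17L, 12), config = cfg0)$model
  fresh <- evombn:::.new_lse(m0$feat_dims, m0$class_set, cfg0)
  expect_identical(m0$Wc, fresh$Wc)
  expect_error(train_lse(bank, rep(4L, 12), config = cfg), "not cached")
  expect_error(train_lse(bank, rep(3L, 12), config = cfg), "invalid genome")
})

test_that("mean excitations are bounded and 0.5 for a zero gate", {
  bank <- make_toy_bank(n = 30, seed = 13)
  m <- zero_lse()
  m$genome <- rep(17L, 12)
  me <- mean_excitations(m, bank)
  expect_equal(unname(me), rep(0.5, 12))
  cfg <- lse_config(epochs = 10, class_mode = "binary", positive_class = "A",
                    seed = 2)
  tr <- train_lse(bank, rep(17L, 12), config = cfg)
  me2 <- mean_excitations(tr$model, bank)
  expect_true(all(me2 > 0 & me2 < 1))
  expect_named(me2, ecg_lead_names())
})

test_that("excitation concentrates on the informative lead", {
  hits <- 0L
  for (s in 1:5) {
    bank <- make_toy_bank(n = 80, signal_lead = 6, seed = 20 + s)
    cfg <- lse_config(epochs = 30, class_mode = "binary", positive_class = "A",
                      seed = s)
    tr <- train_lse(bank, rep(17L, 12), config = cfg)
    me <- mean_excitations(tr$model, bank)
    if (me[6] > mean(me[-6])) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
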