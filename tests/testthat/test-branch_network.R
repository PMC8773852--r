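test_that("a built branch always has exactly 17 convolutional layers", {
  for (plan in list(branch_width_plan("desk"), branch_width_plan("paper"))) {
    net <- build_branch(plan, n_classes = 7, seed = 1)
    expect_equal(conv_layer_count(net), 17L)
    expect_length(net$units, 17L)
  }
  expect_error(build_branch(rep(8L, 16)), "17")
})

test_that("seeded builds are identical; pooled feature shapes follow the plan", {
  a <- build_branch(branch_width_plan("desk"), 7, seed = 3)
  b <- build_branch(branch_width_plan("desk"), 7, seed = 3)
  expect_identical(a, b)
  ds <- generate_beat_dataset(4, "HC", 2, seed = 1)
  plan <- c(rep(4L, 8), rep(6L, 9))
  net <- build_branch(plan, 1, seed = 1)
  expect_equal(ncol(extract_features(net, ds, 1, 17)), plan[17])
  expect_equal(ncol(extract_features(net, ds, 1, 5)), plan[5])
  expect_error(extract_features(net, ds, 1, 18), "1..17")
})

test_that("branch gradients match finite differences through every layer type", {
  set.seed(42)
  net <- build_branch(rep(3L, 17), n_classes = 3, seed = 2)
  X <- array(rnorm(1 * 32 * 4), dim = c(1, 32, 4))
  y <- evombn:::.one_hot(c("a", "b", "c", "a"), c("a", "b", "c"))
  w <- c(1, 2, 0.5)
  loss_of <- function(n) {
    f <- evombn:::.branch_fwd(n, X, training = TRUE, keep_cache = TRUE)
    weighted_ce_loss(f$p, y, w)
  }
  fwd <- evombn:::.branch_fwd(net, X, training = TRUE, keep_cache = TRUE)
  g <- evombn:::.branch_bwd(net, fwd, evombn:::.wce_grad_logits(fwd$p, y, w))
  eps <- 1e-6
  numgrad <- function(bump) {
    (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
  }
  # conv weights at the stem, a strided unit, and the top; BN scale; shortcut
  for (l in c(1L, 5L, 17L)) {
    bump <- function(d) { n <- net; n$units[[l]]$W[1] <- n$units[[l]]$W[1] + d; n }
    expect_equal(numgrad(bump), g$units[[l]]$W[1], tolerance = 1e-4)
  }
  bump <- function(d) { n <- net; n$units[[9]]$bn$gamma[2] <- n$units[[9]]$bn$gamma[2] + d; n }
  expect_equal(numgrad(bump), g$units[[9]]$gamma[2], tolerance = 1e-4)
  bump <- function(d) { n <- net; n$shortcuts[[2]]$W[1] <- n$shortcuts[[2]]$W[1] + d; n }
  expect_equal(numgrad(bump), g$shortcuts[[2]]$W[1], tolerance = 1e-4)
  bump <- function(d) { n <- net; n$head$W[1] <- n$head$W[1] + d; n }
  expect_equal(numgrad(bump), g$head$W[1], tolerance = 1e-4)
})

test_that("weighted cross entropy matches hand arithmetic and brute force", {
  expect_lt(weighted_ce_loss(c(1 - 1e-7, 1e-7), c(1, 0)), 1e-5)
  expect_equal(weighted_ce_loss(c(0.5, 0.5), c(1, 0)), 2 * -log(0.5),
               tolerance = 1e-9)
  # brute-force oracle: explicit double loop over classes and samples
  set.seed(8)
  for (rep in 1:5) {
    c_n <- sample(2:5, 1); n <- sample(3:6, 1)
    p <- matrix(runif(c_n * n), c_n, n); p <- sweep(p, 2, colSums(p), "/")
    y <- evombn:::.one_hot(sample(letters[1:c_n], n, TRUE), letters[1:c_n])
    w <- runif(c_n, 0.5, 3)
    brute <- 0
    for (s in seq_len(n)) for (i in seq_len(c_n)) {
      pi <- min(max(p[i, s], 1e-7), 1 - 1e-7)
      brute <- brute - w[i] * (y[i, s] * log(pi) + (1 - y[i, s]) * log(1 - pi))
    }
    expect_equal(weighted_ce_loss(p, y, w), brute / n, tolerance = 1e-9)
  }
})

test_that("loss is linear in the class weights and validates shapes", {
  p <- c(0.3, 0.7); y <- c(1, 0)
  base <- weighted_ce_loss(p, y, c(1, 1))
  only1 <- weighted_ce_loss(p, y, c(1, 1e-12))
  expect_equal(weighted_ce_loss(p, y, c(2, 1e-12)), 2 * only1, tolerance = 1e-9)
  expect_equal(weighted_ce_loss(p, y, c(1, 1)),
               weighted_ce_loss(p, y), tolerance = 1e-12)  # uniform = default
  expect_error(weighted_ce_loss(c(0.5, 0.5), c(1, 0, 0)), "shape")
  expect_error(weighted_ce_loss(c(0.9, 0.5), c(1, 0)), "sum to 1")
  expect_gt(base, 0)
})

test_that("inverse-frequency class weights behave as specified", {
  expect_equal(class_weights(c(90, 10)), c(100 / 180, 5), tolerance = 1e-9)
  expect_equal(class_weights(c(25, 25, 25, 25)), rep(1, 4))
  expect_equal(class_weights(c(10, 90)), rev(class_weights(c(90, 10))))
  expect_error(class_weights(c(10, 0)), ">= 1")
})

test_that("the step-decay schedule divides the rate by 10 every 10 epochs", {
  expect_equal(schedule_lr(0.1, c(0, 10, 20)), c(0.1, 0.01, 0.001))
  expect_equal(schedule_lr(0.1, 9), 0.1)
  expect_error(train_schedule(epochs = 0), "epochs")
})

test_that("branch training descends on separable data and is lead-local", {
  fx <- get_tiny_bank()
  ds <- fx$dataset
  net <- build_branch(branch_width_plan("desk"), 2, seed = 1)
  tr <- train_branch(net, 2, ds, train_schedule("desk", epochs = 3, seed = 1))
  expect_length(tr$history, 3L)
  expect_lt(tr$history[3], tr$history[1])
  # permuting other leads' samples cannot change this branch's features
  ds2 <- ds
  set.seed(1)
  for (lead in c(1, 5, 9)) ds2$x[lead, , ] <- ds2$x[lead, sample(256), ]
  f1 <- extract_features(tr$net, ds, 2, 17)
  f2 <- extract_features(tr$net, ds2, 2, 17)
  expect_identical(f1, f2)
  expect_error(train_branch(net, 2, ds, train_schedule(epochs = -1)), "epochs")
})

test_that("the feature bank covers 9 levels per lead and round-trips", {
  fx <- get_tiny_bank()
  bank <- fx$bank
  expect_identical(bank$level_set, c(seq(2L, 16L, 2L), 17L))
  expect_length(bank$level_set, 9L)
  for (lead in c(1, 6, 12)) {
    expect_setequal(names(bank$features[[lead]]), as.character(bank$level_set))
    expect_equal(ncol(bank$features[[lead]][["17"]]),
                 branch_width_plan("desk")[17])
    expect_equal(nrow(bank$features[[lead]][["2"]]), length(bank$labels))
  }
  path <- tempfile(fileext = ".rds")
  write_feature_bank(bank, path)
  expect_identical(read_feature_bank(path)$features, bank$features)
  expect_error(build_feature_bank(fx$nets[1:5], fx$dataset), "per lead")
})
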