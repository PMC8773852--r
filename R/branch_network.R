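# Per-lead residual 1-D CNN branch. A branch stacks 17 "basic units"
# (convolution -> batch normalization -> ReLU): a stem unit with kernel 7,
# then 8 residual blocks of two kernel-3 units each (units 2-3, 4-5, ...,
# 16-17). Temporal stride 2 is applied at units 5, 9 and 13, where the
# channel width also steps up under the default plan; a 1x1 projection
# (conv + BN) carries the shortcut whenever channels or stride differ.
# The pooled activation after unit l is the "level-l feature" that the
# genome can select for a lead.

.stride_units <- c(5L, 9L, 13L)

#' Channel-width plans for a branch network
#'
#' The `"paper"` profile follows a standard 1-D ResNet widening schedule
#' (32, 64, 128, 256 channels across the 17 units); the `"desk"` profile is
#' a narrow (8-channel) plan sized for laptop-scale experiments and the test
#' suite. Any length-17 integer vector is a valid custom plan.
#'
#' @param profile `"paper"` or `"desk"`.
#' @return Integer vector of 17 channel counts.
#' @export
branch_width_plan <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
    paper = c(rep(32L, 4), rep(64L, 4), rep(128L, 4), rep(256L, 5)),
    desk = rep(8L, 17)
  )
}

.new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rmean = rep(0, c), rvar = rep(1, c))
}

#' Build a residual branch network for one lead
#'
#' Constructs an untrained branch with exactly 17 convolutional layers plus
#' the training head (global average pooling and a fully-connected softmax
#' classifier, used only while the branch itself is being trained).
#'
#' @param width_plan integer vector of 17 channel counts
#'   (see [branch_width_plan()]).
#' @param n_classes number of classes for the training head.
#' @param seed integer seed for He-normal weight initialization.
#' @return A `branch_net` object.
#' @export
#' @examples
#' net <- build_branch(branch_width_plan("desk"), n_classes = 7, seed = 1)
#' conv_layer_count(net)  # 17
build_branch <- function(width_plan = branch_width_plan(), n_classes = 7L,
                         seed = 1L) {
  if (length(width_plan) != 17L) {
    stop("width_plan must have exactly 17 entries (one per basic unit)")
  }
  set.seed(seed)
  units <- vector("list", 17L)
  cin <- 1L
  for (l in 1:17) {
    k <- if (l == 1L) 7L else 3L
    cout <- width_plan[l]
    units[[l]] <- list(
      W = .he_init(cout, cin, k),
      b = rep(0, cout),
      bn = .new_bn(cout),
      stride = if (l %in% .stride_units) 2L else 1L,
      kernel = k
    )
    cin <- cout
  }
  shortcuts <- vector("list", 8L)
  for (bk in 1:8) {
    in_ch <- width_plan[2L * bk - 1L]
    out_ch <- width_plan[2L * bk + 1L]
    stride <- units[[2L * bk + 1L]]$stride
    if (in_ch != out_ch || stride > 1L) {
      shortcuts[[bk]] <- list(
        W = .he_init(out_ch, in_ch, 1L),
        b = rep(0, out_ch),
        bn = .new_bn(out_ch),
        stride = stride
      )
    }
  }
  head_dim <- width_plan[17]
  structure(
    list(units = units, shortcuts = shortcuts,
         head = list(W = .he_init(n_classes, head_dim), b = rep(0, n_classes)),
         width_plan = as.integer(width_plan), n_classes = as.integer(n_classes)),
    class = "branch_net"
  )
}

#' Count convolutional layers of a branch network
#'
#' Programmatic census of the convolution kernels in the 17 basic units
#' (shortcut 1x1 projections are bookkeeping, not counted as units).
#'
#' @param net a `branch_net`.
#' @return Integer.
#' @export
conv_layer_count <- function(net) {
  sum(vapply(net$units, function(u) !is.null(u$W), logical(1)))
}

#' @export
print.branch_net <- function(x, ...) {
  cat(sprintf("<branch_net> 17 conv units, widths %s..%s, %d-class head\n",
              x$width_plan[1], x$width_plan[17], x$n_classes))
  invisible(x)
}

# Forward pass. Returns the post-activation of every unit (acts), the head
# probabilities, updated BN running stats, and (if keep_cache) everything the
# backward pass needs.
.branch_fwd <- function(net, X, training = FALSE, keep_cache = FALSE,
                        upto = 17L, with_head = TRUE) {
  acts <- vector("list", 17L)
  cache <- if (keep_cache) list(blocks = vector("list", 8L)) else NULL
  u1 <- net$units[[1]]
  c1 <- .conv1d_fwd(X, u1$W, u1$b, u1$stride)
  bn1 <- .bn_fwd(c1, u1$bn, training)
  net$units[[1]]$bn <- bn1$p
  a <- .relu(bn1$Y)
  acts[[1]] <- a
  if (keep_cache) cache$stem <- list(X = X, bn = bn1$cache, a = a)
  if (upto >= 2L) {
    for (bk in 1:8) {
      la <- 2L * bk; lb <- 2L * bk + 1L
      if (la > upto) break
      ua <- net$units[[la]]; ub <- net$units[[lb]]
      s <- a
      ca <- .conv1d_fwd(s, ua$W, ua$b, ua$stride)
      bna <- .bn_fwd(ca, ua$bn, training)
      net$units[[la]]$bn <- bna$p
      aa <- .relu(bna$Y)
      acts[[la]] <- aa
      if (lb > upto) break
      cb <- .conv1d_fwd(aa, ub$W, ub$b, ub$stride)
      bnb <- .bn_fwd(cb, ub$bn, training)
      net$units[[lb]]$bn <- bnb$p
      sc <- net$shortcuts[[bk]]
      if (!is.null(sc)) {
        cs <- .conv1d_fwd(s, sc$W, sc$b, sc$stride)
        bns <- .bn_fwd(cs, sc$bn, training)
        net$shortcuts[[bk]]$bn <- bns$p
        ns <- bns$Y
      } else {
        bns <- NULL
        ns <- s
      }
      a <- .relu(bnb$Y + ns)
      acts[[lb]] <- a
      if (keep_cache) {
        cache$blocks[[bk]] <- list(
          s = s, bn_a = bna$cache, aa = aa, bn_b = bnb$cache,
          bn_s = if (is.null(bns)) NULL else bns$cache, a = a
        )
      }
    }
  }
  out <- list(acts = acts, net = net, cache = cache)
  if (with_head && upto == 17L) {
    f <- .gap_fwd(a)
    logits <- net$head$W %*% f + net$head$b
    out$f <- f
    out$p <- .softmax_cols(logits)
  }
  out
}

# Backward pass from the gradient w.r.t. head logits. Returns a parameter
# gradient tree parallel to .branch_params().
.branch_bwd <- function(net, fwd, dlogits) {
  g <- list(units = vector("list", 17L), shortcuts = vector("list", 8L),
            head = NULL)
  f <- fwd$f
  g$head <- list(W = dlogits %*% t(f), b = rowSums(dlogits))
  df <- t(net$head$W) %*% dlogits
  a17 <- fwd$acts[[17]]
  dA <- .gap_bwd(df, dim(a17)[2])
  for (bk in 8:1) {
    cb <- fwd$cache$blocks[[bk]]
    la <- 2L * bk; lb <- 2L * bk + 1L
    ua <- net$units[[la]]; ub <- net$units[[lb]]
    dz <- .relu_bwd(dA, cb$a)
    bnb <- .bn_bwd(dz, ub$bn, cb$bn_b)
    cvb <- .conv1d_bwd(cb$aa, ub$W, bnb$dX, ub$stride)
    g$units[[lb]] <- list(W = cvb$dW, b = cvb$db,
                          gamma = bnb$dgamma, beta = bnb$dbeta)
    sc <- net$shortcuts[[bk]]
    if (!is.null(sc)) {
      bns <- .bn_bwd(dz, sc$bn, cb$bn_s)
      cvs <- .conv1d_bwd(cb$s, sc$W, bns$dX, sc$stride)
      g$shortcuts[[bk]] <- list(W = cvs$dW, b = cvs$db,
                                gamma = bns$dgamma, beta = bns$dbeta)
      dS_sc <- cvs$dX
    } else {
      dS_sc <- dz
    }
    dna <- .relu_bwd(cvb$dX, cb$aa)
    bna <- .bn_bwd(dna, ua$bn, cb$bn_a)
    cva <- .conv1d_bwd(cb$s, ua$W, bna$dX, ua$stride)
    g$units[[la]] <- list(W = cva$dW, b = cva$db,
                          gamma = bna$dgamma, beta = bna$dbeta)
    dA <- cva$dX + dS_sc
  }
  st <- fwd$cache$stem
  u1 <- net$units[[1]]
  dn1 <- .relu_bwd(dA, st$a)
  bn1 <- .bn_bwd(dn1, u1$bn, st$bn)
  cv1 <- .conv1d_bwd(st$X, u1$W, bn1$dX, u1$stride)
  g$units[[1]] <- list(W = cv1$dW, b = cv1$db,
                       gamma = bn1$dgamma, beta = bn1$dbeta)
  g
}

.branch_params <- function(net) {
  list(
    units = lapply(net$units, function(u)
      list(W = u$W, b = u$b, gamma = u$bn$gamma, beta = u$bn$beta)),
    shortcuts = lapply(net$shortcuts, function(s) {
      if (is.null(s)) NULL else
        list(W = s$W, b = s$b, gamma = s$bn$gamma, beta = s$bn$beta)
    }),
    head = list(W = net$head$W, b = net$head$b)
  )
}

.branch_set_params <- function(net, p) {
  for (l in 1:17) {
    net$units[[l]]$W <- p$units[[l]]$W
    net$units[[l]]$b <- p$units[[l]]$b
    net$units[[l]]$bn$gamma <- p$units[[l]]$gamma
    net$units[[l]]$bn$beta <- p$units[[l]]$beta
  }
  for (bk in 1:8) {
    if (!is.null(net$shortcuts[[bk]])) {
      net$shortcuts[[bk]]$W <- p$shortcuts[[bk]]$W
      net$shortcuts[[bk]]$b <- p$shortcuts[[bk]]$b
      net$shortcuts[[bk]]$bn$gamma <- p$shortcuts[[bk]]$gamma
      net$shortcuts[[bk]]$bn$beta <- p$shortcuts[[bk]]$beta
    }
  }
  net$head$W <- p$head$W
  net$head$b <- p$head$b
  net
}

# ---- loss and schedule -----------------------------------------------------

#' Weighted cross-entropy loss
#'
#' Computes `-sum_i w_i * (y_i log p_i + (1 - y_i) log(1 - p_i))`, the
#' class-weighted cross entropy used to train both the branch networks and
#' the LSE head. Probabilities are clipped to `[1e-7, 1 - 1e-7]`. With all
#' weights 1 and a one-hot target this is the standard per-class binary
#' cross-entropy sum. For matrices (classes x samples) the mean per-sample
#' loss is returned.
#'
#' @param p predicted class probabilities: vector, or classes x samples
#'   matrix with columns summing to 1.
#' @param y one-hot targets, same shape as `p`.
#' @param w positive class weights, length `nrow(p)` (default all 1).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' weighted_ce_loss(c(0.5, 0.5), c(1, 0))  # 2 * -log(0.5) ~ 1.3863
weighted_ce_loss <- function(p, y, w = NULL) {
  p <- as.matrix(p); y <- as.matrix(y)
  if (!all(dim(p) == dim(y))) stop("p and y must have identical shapes")
  if (is.null(w)) w <- rep(1, nrow(p))
  if (length(w) != nrow(p)) stop("w must have one weight per class")
  if (any(w <= 0)) stop("class weights must be positive")
  if (any(abs(colSums(p) - 1) > 1e-6)) {
    stop("columns of p must sum to 1")
  }
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  per_sample <- -colSums(w * (y * log(pc) + (1 - y) * log(1 - pc)))
  mean(per_sample)
}

# gradient of the weighted CE w.r.t. softmax logits, mean over batch
.wce_grad_logits <- function(p, y, w) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  dP <- -w * (y / pc - (1 - y) / (1 - pc))   # dL/dp
  inner <- colSums(dP * p)
  (p * (dP - matrix(inner, nrow(p), ncol(p), byrow = TRUE))) / ncol(p)
}

#' Inverse-frequency class weights
#'
#' `w_i = N_total / (c * N_i)`: classes with fewer samples get strictly
#' larger weights; balanced classes all get weight 1.
#'
#' @param counts positive integer vector of per-class sample counts.
#' @return Numeric weights, same names/order as `counts`.
#' @export
#' @examples
#' class_weights(c(90, 10))  # 0.5556, 5
class_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 1)) stop("all class counts must be >= 1")
  sum(counts) / (length(counts) * counts)
}

#' Step-decay learning rate
#'
#' The branch training schedule: the initial rate divided by 10 every 10
#' epochs, `lr0 * 10^(-floor(epoch / 10))`, with epochs counted from 0.
#'
#' @param lr0 initial learning rate.
#' @param epoch 0-based epoch index.
#' @return Learning rate at that epoch.
#' @export
#' @examples
#' schedule_lr(0.1, c(0, 10, 20))  # 0.1, 0.01, 0.001
schedule_lr <- function(lr0, epoch) {
  lr0 * 10^(-floor(epoch / 10))
}

#' Branch training schedule
#'
#' SGD-with-momentum hyperparameters. The `"paper"` profile is the full-size
#' recipe (lr0 0.1 decayed by 10 every 10 epochs, momentum 0.9, batch 128,
#' 30 epochs); the `"desk"` profile shrinks epochs and batch for small
#' synthetic runs.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param lr0,momentum,batch,epochs,seed overrides of the profile values.
#' @param class_weights optional explicit per-class weights; by default
#'   computed from the training-set class counts via [class_weights()].
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(profile = c("desk", "paper"), lr0 = NULL,
                           momentum = 0.9, batch = NULL, epochs = NULL,
                           seed = 1L, class_weights = NULL) {
  profile <- match.arg(profile)
  def <- switch(profile,
    paper = list(lr0 = 0.1, batch = 128L, epochs = 30L),
    desk = list(lr0 = 0.05, batch = 32L, epochs = 3L)
  )
  out <- list(
    lr0 = lr0 %||% def$lr0, momentum = momentum,
    batch = as.integer(batch %||% def$batch),
    epochs = as.integer(epochs %||% def$epochs),
    seed = as.integer(seed), class_weights = class_weights
  )
  if (out$lr0 <= 0 || out$momentum < 0 || out$batch < 1) {
    stop("invalid schedule: lr0, momentum, batch must be positive")
  }
  if (out$epochs < 1) stop("epochs must be >= 1")
  structure(out, class = "train_schedule")
}

# one-hot matrix [classes x n] from a factor
.one_hot <- function(labels, class_set) {
  y <- matrix(0, length(class_set), length(labels))
  y[cbind(match(as.character(labels), class_set), seq_along(labels))] <- 1
  y
}

#' Train one branch network on a single lead
#'
#' Minimizes the weighted cross entropy with SGD + momentum under the
#' step-decay schedule of [schedule_lr()]. Training uses only the given
#' lead's row of each beat; the branch head classifies the full class set of
#' the dataset (all MI subcategories plus HC when available), which is a
#' feature-learning strategy, not the final diagnosis.
#'
#' @param net a `branch_net` from [build_branch()].
#' @param lead_index lead to train on, 1..12 in [ecg_lead_names()] order.
#' @param dataset a `beat_dataset`.
#' @param schedule a [train_schedule()].
#' @return List with `net` (trained) and `history` (mean loss per epoch,
#'   length `schedule$epochs`).
#' @export
train_branch <- function(net, lead_index, dataset, schedule = train_schedule()) {
  stopifnot(inherits(net, "branch_net"), inherits(dataset, "beat_dataset"))
  n <- dim(dataset$x)[3]
  if (n == 0) stop("empty dataset")
  if (lead_index < 1 || lead_index > dim(dataset$x)[1]) {
    stop("lead_index out of range")
  }
  class_set <- dataset$class_set
  if (length(class_set) != net$n_classes) {
    stop("dataset class set (", length(class_set),
         ") does not match branch head (", net$n_classes, " classes)")
  }
  w <- schedule$class_weights %||%
    class_weights(as.integer(table(dataset$labels)[class_set]))
  y_all <- .one_hot(dataset$labels, class_set)
  set.seed(schedule$seed)
  params <- .branch_params(net)
  vel <- .tree_zeros(params)
  history <- numeric(schedule$epochs)
  for (epoch in 0:(schedule$epochs - 1L)) {
    lr <- schedule_lr(schedule$lr0, epoch)
    perm <- sample.int(n)
    losses <- c()
    for (start in seq.int(1L, n, by = schedule$batch)) {
      idx <- perm[start:min(start + schedule$batch - 1L, n)]
      X <- array(dataset$x[lead_index, , idx], dim = c(1L, dim(dataset$x)[2], length(idx)))
      y <- y_all[, idx, drop = FALSE]
      net <- .branch_set_params(net, params)
      fwd <- .branch_fwd(net, X, training = TRUE, keep_cache = TRUE)
      net <- fwd$net  # BN running stats
      losses <- c(losses, weighted_ce_loss(fwd$p, y, w))
      dlogits <- .wce_grad_logits(fwd$p, y, w)
      grads <- .branch_bwd(net, fwd, dlogits)
      upd <- .sgd_step(params, grads, vel, lr, schedule$momentum)
      params <- upd$params
      vel <- upd$vel
    }
    history[epoch + 1L] <- mean(losses)
  }
  net <- .branch_set_params(net, params)
  list(net = net, history = history)
}

#' Extract pooled features at a given level
#'
#' Runs the branch forward (inference mode) on one lead of every beat and
#' returns the global-average-pooled activation after basic unit `level`.
#' Works for trained and untrained branches alike: features are a property
#' of the architecture state, not of convergence.
#'
#' @param net a `branch_net`.
#' @param dataset a `beat_dataset`.
#' @param lead_index lead to read, 1..12.
#' @param level basic-unit index, 1..17.
#' @param batch internal forward batch size.
#' @return Matrix `n_beats x width_plan[level]`.
#' @export
extract_features <- function(net, dataset, lead_index, level, batch = 64L) {
  if (level < 1 || level > 17) stop("level must be in 1..17")
  n <- dim(dataset$x)[3]
  out <- matrix(0, n, net$width_plan[level])
  for (start in seq.int(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    X <- array(dataset$x[lead_index, , idx], dim = c(1L, dim(dataset$x)[2], length(idx)))
    fwd <- .branch_fwd(net, X, training = FALSE, upto = as.integer(level),
                       with_head = FALSE)
    out[idx, ] <- t(.gap_fwd(fwd$acts[[level]]))
  }
  out
}

#' Default feature levels cached for the architecture search
#'
#' The even unit indices 2..16 plus the top level 17 — the 9 levels the
#' genome may assign to a lead.
#'
#' @return Integer vector of 9 levels.
#' @export
default_level_set <- function() c(seq.int(2L, 16L, by = 2L), 17L)

#' Build a feature bank over all leads and levels
#'
#' Runs every trained branch once over the dataset and caches the pooled
#' feature vectors for each (lead, level, beat) triple. With the bank in
#' hand, evaluating a genome's fitness only requires training an LSE head —
#' no branch is ever retrained during the search.
#'
#' @param nets list of 12 `branch_net` objects, in [ecg_lead_names()] order.
#' @param dataset a `beat_dataset`.
#' @param level_set levels to cache; defaults to [default_level_set()].
#' @return A `feature_bank`: `features[[lead]][[as.character(level)]]` is an
#'   `n_beats x channels` matrix; `labels` and `patient_id` align with beats.
#' @export
build_feature_bank <- function(nets, dataset, level_set = default_level_set()) {
  if (length(nets) != dim(dataset$x)[1]) {
    stop("need one trained branch per lead (got ", length(nets), ")")
  }
  if (any(vapply(nets, is.null, logical(1)))) stop("missing branch network")
  level_set <- sort(unique(as.integer(level_set)))
  n <- dim(dataset$x)[3]
  feats <- vector("list", length(nets))
  for (lead in seq_along(nets)) {
    net <- nets[[lead]]
    per_level <- lapply(level_set, function(l) matrix(0, n, net$width_plan[l]))
    names(per_level) <- as.character(level_set)
    for (start in seq.int(1L, n, by = 64L)) {
      idx <- start:min(start + 63L, n)
      X <- array(dataset$x[lead, , idx], dim = c(1L, dim(dataset$x)[2], length(idx)))
      fwd <- .branch_fwd(net, X, training = FALSE, with_head = FALSE)
      for (l in level_set) {
        per_level[[as.character(l)]][idx, ] <- t(.gap_fwd(fwd$acts[[l]]))
      }
    }
    feats[[lead]] <- per_level
  }
  structure(
    list(features = feats, labels = dataset$labels,
         patient_id = dataset$patient_id, level_set = level_set,
         lead_order = dataset$lead_order, class_set = dataset$class_set,
         manifest = list(n_beats = n, created = as.character(Sys.time()),
                         widths = nets[[1]]$width_plan)),
    class = "feature_bank"
  )
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %d beats, %d leads, levels {%s}\n",
              length(x$labels), length(x$features),
              paste(x$level_set, collapse = ",")))
  invisible(x)
}

#' Persist / load a feature bank
#'
#' Single-file serialization (compressed R serialization with the manifest
#' embedded); the round trip reproduces bit-identical arrays.
#'
#' @param bank a `feature_bank`.
#' @param path file path.
#' @return `write_feature_bank` returns `path` invisibly; `read_feature_bank`
#'   returns the `feature_bank`.
#' @export
write_feature_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  saveRDS(bank, path)
  invisible(path)
}

#' @rdname write_feature_bank
#' @export
read_feature_bank <- function(path) {
  bank <- readRDS(path)
  stopifnot(inherits(bank, "feature_bank"))
  bank
}

#' Train all 12 branch networks
#'
#' Convenience wrapper: builds and trains one branch per lead with the same
#' width plan and schedule (branches are always trained separately, never
#' jointly).
#'
#' @param dataset a `beat_dataset`.
#' @param width_plan see [branch_width_plan()].
#' @param schedule see [train_schedule()].
#' @param seed base seed; lead `i` uses `seed + i`.
#' @return List of 12 trained `branch_net` objects.
#' @export
train_branches <- function(dataset, width_plan = branch_width_plan(),
                           schedule = train_schedule(), seed = 1L) {
  n_classes <- length(dataset$class_set)
  lapply(seq_len(dim(dataset$x)[1]), function(lead) {
    net <- build_branch(width_plan, n_classes, seed = seed + lead)
    sch <- schedule
    sch$seed <- as.integer(seed + 100L + lead)
    train_branch(net, lead, dataset, sch)$net
  })
}
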