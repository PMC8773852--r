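# Lead Squeeze-and-Excitation head. Each lead's pooled feature vector is
# squeezed to a scalar (second-stage mean), the 12-vector u passes through a
# two-layer gate e = sigmoid(W2 relu(W1 u)) computed per beat, each lead's
# features are rescaled by its excitation, and a fully-connected layer on the
# concatenation produces the class scores. Forcing e = 1 recovers the
# conventional MBN head (plain concatenation + fully-connected classifier),
# which is the ablation baseline.

#' LSE training configuration
#'
#' @param epochs Adam epochs (default 30; 0 returns the untrained model).
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param seed integer seed for initialization and shuffling.
#' @param class_mode `"multiclass"` (softmax over the class set) or
#'   `"binary"` (single sigmoid output for one positive class).
#' @param positive_class required in binary mode.
#' @param use_excitation `FALSE` forces e = 1, i.e. the conventional MBN
#'   head without lead attention.
#' @param r reduction factor of the excitation gate; must divide 12
#'   (default 1, hidden width 12).
#' @param class_weights optional explicit weights; default inverse-frequency
#'   via [class_weights()].
#' @return An `lse_config` list.
#' @export
lse_config <- function(epochs = 30L, lr = 1e-2, batch = 32L, seed = 1L,
                       class_mode = c("multiclass", "binary"),
                       positive_class = NULL, use_excitation = TRUE,
                       r = 1L, class_weights = NULL) {
  class_mode <- match.arg(class_mode)
  if (12L %% r != 0L) stop("reduction factor r must divide 12")
  if (class_mode == "binary" && is.null(positive_class)) {
    stop("binary mode requires positive_class")
  }
  structure(
    list(epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
         seed = as.integer(seed), class_mode = class_mode,
         positive_class = positive_class, use_excitation = use_excitation,
         r = as.integer(r), class_weights = class_weights),
    class = "lse_config"
  )
}

.new_lse <- function(feat_dims, class_set, config) {
  set.seed(config$seed)
  h <- 12L %/% config$r
  n_out <- if (config$class_mode == "binary") 1L else length(class_set)
  D <- sum(feat_dims)
  structure(
    list(W1 = .he_init(h, 12L), b1 = rep(0, h),
         W2 = .he_init(12L, h), b2 = rep(0, 12L),
         Wc = .he_init(n_out, D), bc = rep(0, n_out),
         r = config$r, feat_dims = feat_dims, class_set = class_set,
         class_mode = config$class_mode,
         positive_class = config$positive_class,
         use_excitation = config$use_excitation,
         genome = NULL, feat_center = NULL, feat_scale = NULL),
    class = "lse_model"
  )
}

#' @export
print.lse_model <- function(x, ...) {
  cat(sprintf("<lse_model> %s head, r = %d, input %d dims%s\n",
              x$class_mode, x$r, sum(x$feat_dims),
              if (is.null(x$genome)) "" else
                paste0(", genome [", paste(x$genome, collapse = ","), "]")))
  invisible(x)
}

# normalize y to a list of 12 single/multi-row matrices
.as_lead_list <- function(y) {
  if (!is.list(y) || length(y) != 12L) {
    stop("expected a list of 12 per-lead feature vectors/matrices")
  }
  lapply(y, function(v) {
    if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  })
}

#' Squeeze per-lead features to 12 scalars
#'
#' The squeeze step: each lead's pooled feature vector is averaged to a
#' single scalar, giving the 12-vector `u` the excitation gate acts on.
#'
#' @param y list of 12 per-lead feature vectors (or matrices, beats x dims).
#' @return Numeric vector of 12 squeezed values (or a beats x 12 matrix).
#' @export
#' @examples
#' lse_squeeze(rep(list(c(2, 4)), 12))[1]  # 3
lse_squeeze <- function(y) {
  y <- .as_lead_list(y)
  if (any(vapply(y, ncol, integer(1)) == 0L)) stop("empty feature vector")
  u <- vapply(y, rowMeans, numeric(nrow(y[[1]])))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  if (nrow(u) == 1L) drop(u) else u
}

#' Compute lead excitations
#'
#' The two-layer gate `e = sigmoid(W2 relu(W1 u))`; every excitation lies
#' strictly in (0, 1).
#'
#' @param u squeezed 12-vector (or beats x 12 matrix) from [lse_squeeze()].
#' @param model an `lse_model`.
#' @return Excitation values in (0, 1), same leading shape as `u`.
#' @export
lse_excite <- function(u, model) {
  um <- if (is.null(dim(u))) matrix(u, nrow = 1L) else as.matrix(u)
  if (ncol(um) != ncol(model$W1)) stop("u must have 12 entries per beat")
  h <- .relu(um %*% t(model$W1) + matrix(model$b1, nrow(um), length(model$b1), byrow = TRUE))
  e <- .sigmoid(h %*% t(model$W2) + matrix(model$b2, nrow(um), 12L, byrow = TRUE))
  if (nrow(e) == 1L && is.null(dim(u))) drop(e) else e
}

#' Scale per-lead features by their excitations
#'
#' `o_i = e_i * y_i`, elementwise per lead; shapes are preserved.
#'
#' @param y list of 12 per-lead feature vectors/matrices.
#' @param e excitation vector of 12 values (or beats x 12 matrix).
#' @return List of 12 scaled features, same shapes as `y`.
#' @export
lse_scale <- function(y, e) {
  y <- .as_lead_list(y)
  em <- if (is.null(dim(e))) matrix(e, nrow = nrow(y[[1]]), ncol = 12L, byrow = TRUE) else as.matrix(e)
  if (ncol(em) != 12L) stop("e must have 12 entries")
  lapply(seq_len(12L), function(i) y[[i]] * em[, i])
}

#' Final classification over scaled lead features
#'
#' Concatenates the 12 scaled feature vectors and applies the
#' fully-connected classifier: softmax class probabilities in multiclass
#' mode, a positive-class probability in (0, 1) in binary mode.
#'
#' @param o list of 12 scaled per-lead features (from [lse_scale()]).
#' @param model an `lse_model`.
#' @return Probability vector (multiclass: one per class, summing to 1) or
#'   scalar positive-class probability; a matrix/vector over beats for
#'   batched input.
#' @export
lse_classify <- function(o, model) {
  o <- .as_lead_list(o)
  O <- do.call(cbind, o)
  if (ncol(O) != ncol(model$Wc)) {
    stop("concatenated feature length (", ncol(O),
         ") does not match classifier input (", ncol(model$Wc), ")")
  }
  Z <- O %*% t(model$Wc) + matrix(model$bc, nrow(O), length(model$bc), byrow = TRUE)
  if (model$class_mode == "binary") {
    p <- .sigmoid(drop(Z))
    p
  } else {
    p <- t(.softmax_cols(t(Z)))
    colnames(p) <- model$class_set
    if (nrow(p) == 1L) drop(p) else p
  }
}

#' Full LSE forward pass
#'
#' Squeeze, excite, scale, classify. With `model$use_excitation = FALSE`
#' (or `force_identity = TRUE`) the excitation is fixed at 1 and the head
#' reduces exactly to the conventional concatenation + fully-connected MBN
#' summarizer.
#'
#' @param model an `lse_model`.
#' @param y list of 12 per-lead features (vectors or beats x dims matrices).
#' @param force_identity override forcing e = 1.
#' @return List with `p` (probabilities), `e` (excitations), `u` (squeezed).
#' @export
lse_forward <- function(model, y, force_identity = FALSE) {
  y <- .as_lead_list(y)
  n <- nrow(y[[1]])
  u <- lse_squeeze(y)
  um <- if (is.null(dim(u))) matrix(u, nrow = 1L) else u
  if (model$use_excitation && !force_identity) {
    e <- lse_excite(um, model)
  } else {
    e <- matrix(1, n, 12L)
  }
  em <- if (is.null(dim(e))) matrix(e, nrow = 1L) else e
  o <- lse_scale(y, em)
  list(p = lse_classify(o, model), e = e, u = u)
}

# apply a trained model's per-dimension standardization to raw bank features
.standardize_leads <- function(Y, model) {
  if (is.null(model$feat_center)) return(Y)
  lapply(seq_along(Y), function(i) {
    sweep(sweep(Y[[i]], 2, model$feat_center[[i]]), 2, model$feat_scale[[i]], "/")
  })
}

# pull the genome-selected features out of a bank: list of 12 [n x d] matrices
.bank_features <- function(bank, genome, idx = NULL) {
  stopifnot(inherits(bank, "feature_bank"))
  lapply(seq_len(12L), function(i) {
    key <- as.character(genome[i])
    f <- bank$features[[i]][[key]]
    if (is.null(f)) {
      stop("level ", key, " for lead ", i, " is not cached in the bank")
    }
    if (is.null(idx)) f else f[idx, , drop = FALSE]
  })
}

#' Train an LSE head on cached features
#'
#' For each beat, lead i's input feature is the bank entry at
#' (lead i, level `genome[i]`). Every feature dimension is standardized over
#' the training beats (the center/scale are stored on the model and re-applied
#' at prediction time), then the gate and classifier weights are trained with
#' Adam to minimize the weighted cross entropy; the bank (and hence the
#' branches) stays frozen. Deterministic given `config$seed`.
#'
#' @param bank a `feature_bank`.
#' @param genome 12-integer level vector (see [validate_genome()]).
#' @param labels per-beat labels; defaults to `bank$labels`. In binary mode
#'   any label other than `config$positive_class` counts as negative.
#' @param config an [lse_config()].
#' @param idx optional beat subset (row indices into the bank) to train on.
#' @return List with `model` (trained `lse_model`, genome recorded) and
#'   `history` (mean loss per epoch).
#' @export
train_lse <- function(bank, genome, labels = NULL, config = lse_config(),
                      idx = NULL) {
  viol <- validate_genome(genome)
  if (length(viol)) stop("invalid genome: ", paste(viol, collapse = "; "))
  labels <- labels %||% bank$labels
  Y <- .bank_features(bank, genome, idx)
  if (!is.null(idx)) labels <- labels[idx]
  labels <- as.character(labels)
  n <- nrow(Y[[1]])
  feat_dims <- vapply(Y, ncol, integer(1))
  if (config$class_mode == "binary") {
    class_set <- c(config$positive_class, "rest")
    ybin <- as.numeric(labels == config$positive_class)
    counts <- c(sum(ybin), sum(1 - ybin))
    if (any(counts == 0)) stop("binary task needs both positive and negative beats")
    w <- config$class_weights %||% class_weights(counts)
  } else {
    class_set <- bank$class_set
    counts <- table(factor(labels, levels = class_set))
    if (any(counts == 0)) {
      class_set <- names(counts)[counts > 0]
      counts <- counts[class_set]
    }
    w <- config$class_weights %||% class_weights(as.integer(counts))
    y_all <- .one_hot(labels, class_set)
  }
  model <- .new_lse(feat_dims, class_set, config)
  model$genome <- as.integer(genome)
  # standardize each feature dimension over the training beats; frozen-branch
  # GAP features are all-positive and ill-conditioned otherwise
  model$feat_center <- lapply(Y, colMeans)
  model$feat_scale <- lapply(Y, function(f) {
    s <- apply(f, 2, stats::sd)
    ifelse(s < 1e-8, 1, s)
  })
  Y <- .standardize_leads(Y, model)
  if (config$epochs == 0L) return(list(model = model, history = numeric(0)))

  U <- lse_squeeze(Y)
  if (is.null(dim(U))) U <- matrix(U, nrow = n)
  params <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
                 Wc = model$Wc, bc = model$bc)
  state <- list(m = .tree_zeros(params), v = .tree_zeros(params))
  history <- numeric(config$epochs)
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq.int(1L, n, by = config$batch)) {
      bidx <- perm[start:min(start + config$batch - 1L, n)]
      Yb <- lapply(Y, function(f) f[bidx, , drop = FALSE])
      ub <- U[bidx, , drop = FALSE]
      nb <- length(bidx)
      # forward
      if (config$use_excitation) {
        q <- ub %*% t(params$W1) + matrix(params$b1, nb, length(params$b1), byrow = TRUE)
        h <- .relu(q)
        gz <- h %*% t(params$W2) + matrix(params$b2, nb, 12L, byrow = TRUE)
        e <- .sigmoid(gz)
      } else {
        e <- matrix(1, nb, 12L)
      }
      O <- do.call(cbind, lapply(1:12, function(i) Yb[[i]] * e[, i]))
      Z <- O %*% t(params$Wc) + matrix(params$bc, nb, length(params$bc), byrow = TRUE)
      if (config$class_mode == "binary") {
        p <- .sigmoid(drop(Z))
        yb <- ybin[bidx]
        ws <- ifelse(yb == 1, w[1], w[2])
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        losses <- c(losses, mean(-ws * (yb * log(pc) + (1 - yb) * log(1 - pc))))
        dZ <- matrix(ws * (p - yb) / nb, ncol = 1L)
      } else {
        p <- t(.softmax_cols(t(Z)))
        yb <- t(y_all[, bidx, drop = FALSE])
        losses <- c(losses, weighted_ce_loss(t(p), t(yb), w))
        dZ <- t(.wce_grad_logits(t(p), t(yb), w))
      }
      # backward
      g <- list()
      g$Wc <- t(dZ) %*% O
      g$bc <- colSums(dZ)
      dO <- dZ %*% params$Wc
      if (config$use_excitation) {
        dE <- matrix(0, nb, 12L)
        pos <- 0L
        for (i in 1:12) {
          cols <- pos + seq_len(ncol(Yb[[i]]))
          dE[, i] <- rowSums(dO[, cols, drop = FALSE] * Yb[[i]])
          pos <- pos + ncol(Yb[[i]])
        }
        dG <- dE * e * (1 - e)
        g$W2 <- t(dG) %*% h
        g$b2 <- colSums(dG)
        dH <- dG %*% params$W2
        dQ <- dH * (q > 0)
        g$W1 <- t(dQ) %*% ub
        g$b1 <- colSums(dQ)
      } else {
        g$W1 <- params$W1 * 0; g$b1 <- params$b1 * 0
        g$W2 <- params$W2 * 0; g$b2 <- params$b2 * 0
      }
      g <- g[names(params)]
      t_step <- t_step + 1L
      upd <- .adam_step(params, g, state, config$lr, t_step)
      params <- upd$params
      state <- upd$state
    }
    history[epoch] <- mean(losses)
  }
  model$W1 <- params$W1; model$b1 <- params$b1
  model$W2 <- params$W2; model$b2 <- params$b2
  model$Wc <- params$Wc; model$bc <- params$bc
  list(model = model, history = history)
}

#' Predict with a trained LSE model
#'
#' @param model trained `lse_model` (with its genome recorded).
#' @param bank a `feature_bank` covering the model's genome levels.
#' @param idx optional beat subset.
#' @return Multiclass: beats x classes probability matrix. Binary: vector of
#'   positive-class probabilities.
#' @export
predict_lse <- function(model, bank, idx = NULL) {
  Y <- .standardize_leads(.bank_features(bank, model$genome, idx), model)
  lse_forward(model, Y)$p
}

#' Mean lead excitations over a beat set
#'
#' Averages the per-beat excitation vector over the given beats — the
#' quantity used to inspect which leads a trained classifier attends to for
#' a given diagnostic task.
#'
#' @param model trained `lse_model`.
#' @param bank a `feature_bank`.
#' @param idx optional beat subset; default all beats.
#' @return Named numeric vector of 12 mean excitations in (0, 1).
#' @export
mean_excitations <- function(model, bank, idx = NULL) {
  Y <- .standardize_leads(.bank_features(bank, model$genome, idx), model)
  if (nrow(Y[[1]]) == 0L) stop("empty beat set")
  e <- lse_forward(model, Y)$e
  if (is.null(dim(e))) e <- matrix(e, nrow = 1L)
  out <- colMeans(e)
  names(out) <- bank$lead_order
  out
}
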