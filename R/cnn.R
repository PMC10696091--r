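#' Classifier configuration
#'
#' The architecture is fixed to the method's shape -- exactly two
#' convolutional layers and one fully-connected hidden layer before the
#' three-way softmax output:
#' `conv(f1, w1, ReLU) -> maxpool(2) -> conv(f2, w2, ReLU) ->
#'  global maxpool -> dense(d, ReLU) -> dense(3, softmax)`,
#' trained with cross-entropy loss and Adam. Model selection keeps the
#' per-epoch checkpoint maximizing mean one-vs-all validation AUPRC.
#'
#' @param filters Integer length-2: filter counts of the two conv layers.
#' @param widths Integer length-2: filter widths (bases) of the two conv
#'   layers.
#' @param dense_units Units in the fully-connected hidden layer.
#' @param epochs Training epochs (0 returns the initialization).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param input_length Input width in bases (76 for this method).
#' @param rng_seed Seed for initialization and shuffling.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(filters = c(64L, 32L), widths = c(8L, 8L),
                              dense_units = 64L, epochs = 6L,
                              batch_size = 128L, learning_rate = 1e-3,
                              input_length = 76L, rng_seed = 1L) {
  stopifnot(length(filters) == 2, length(widths) == 2, dense_units >= 1,
            epochs >= 0, batch_size >= 1, learning_rate > 0,
            input_length > sum(widths))
  structure(list(filters = as.integer(filters), widths = as.integer(widths),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 input_length = as.integer(input_length),
                 rng_seed = as.integer(rng_seed),
                 classes = c("human", "viral", "bacterial")),
            class = "classifier_config")
}

# One-hot encode A/C/G/T sequences of equal length `len` into an
# n x len x 4 array. Sequences must be N-free.
encode_onehot <- function(sequences, len) {
  n <- length(sequences)
  idx <- match(unlist(seq_to_chars(sequences), use.names = FALSE), DNA_BASES)
  if (anyNA(idx)) stop("sequences must contain only A, C, G, T")
  X <- array(0, dim = c(n, len, 4L))
  pos <- rep(seq_len(len), n)
  samp <- rep(seq_len(n), each = len)
  X[cbind(samp, pos, idx)] <- 1
  X
}

# He-scaled initialization of all weights.
cnn_init <- function(cfg) {
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  w1 <- cfg$widths[1]; w2 <- cfg$widths[2]; d <- cfg$dense_units
  list(W1 = he(w1 * 4L, f1, w1 * 4L), b1 = rep(0, f1),
       W2 = he(w2 * f1, f2, w2 * f1), b2 = rep(0, f2),
       W3 = he(f2, d, f2), b3 = rep(0, d),
       W4 = he(d, 3L, d), b4 = rep(0, 3L))
}

# im2col: from an n x P x C array build an (n * Pout) x (w * C) matrix
# whose row (i, p) is the window of width `w` starting at position p.
# Sample index varies fastest, matching a later dim() reshape back.
im2col <- function(A, w) {
  n <- dim(A)[1]; P <- dim(A)[2]; C <- dim(A)[3]
  Pout <- P - w + 1L
  M <- matrix(0, n * Pout, w * C)
  for (k in seq_len(w)) {
    M[, ((k - 1L) * C + 1L):(k * C)] <- matrix(A[, k:(k + Pout - 1L), ],
                                               n * Pout, C)
  }
  M
}

# Scatter-accumulate the im2col gradient back onto the input array.
col2im <- function(dM, n, P, C, w) {
  Pout <- P - w + 1L
  dA <- array(0, dim = c(n, P, C))
  for (k in seq_len(w)) {
    dA[, k:(k + Pout - 1L), ] <- dA[, k:(k + Pout - 1L), ] +
      array(dM[, ((k - 1L) * C + 1L):(k * C)], dim = c(n, Pout, C))
  }
  dA
}

# Forward pass; with keep_cache = TRUE also returns the intermediates
# needed by the backward pass.
cnn_forward <- function(weights, X, cfg, keep_cache = FALSE) {
  n <- dim(X)[1]
  w1 <- cfg$widths[1]; w2 <- cfg$widths[2]
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  P1 <- cfg$input_length - w1 + 1L          # conv1 output positions
  M1 <- im2col(X, w1)
  Z1 <- sweep(M1 %*% weights$W1, 2, weights$b1, `+`)
  A1 <- pmax(Z1, 0)
  A1a <- array(A1, dim = c(n, P1, f1))
  P2 <- P1 %/% 2L                            # maxpool width-2 output
  odd <- A1a[, seq(1L, 2L * P2, by = 2L), , drop = FALSE]
  evn <- A1a[, seq(2L, 2L * P2, by = 2L), , drop = FALSE]
  take_odd <- odd >= evn                     # ties route left: deterministic
  Pool <- ifelse(take_odd, odd, evn)
  P3 <- P2 - w2 + 1L                         # conv2 output positions
  M2 <- im2col(Pool, w2)
  Z2 <- sweep(M2 %*% weights$W2, 2, weights$b2, `+`)
  A2 <- pmax(Z2, 0)
  A2a <- array(A2, dim = c(n, P3, f2))
  # global max pool over positions, tracking argmax for backprop
  G <- A2a[, 1L, , drop = TRUE]
  if (is.null(dim(G))) G <- matrix(G, n, f2)
  Garg <- matrix(1L, n, f2)
  if (P3 >= 2L) for (p in 2:P3) {
    cur <- A2a[, p, ]
    if (is.null(dim(cur))) cur <- matrix(cur, n, f2)
    upd <- cur > G
    Garg[upd] <- p
    G[upd] <- cur[upd]
  }
  Z3 <- sweep(G %*% weights$W3, 2, weights$b3, `+`)
  H <- pmax(Z3, 0)
  logits <- sweep(H %*% weights$W4, 2, weights$b4, `+`)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  colnames(probs) <- cfg$classes
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, cache = list(M1 = M1, Z1 = Z1, take_odd = take_odd,
                                   M2 = M2, Z2 = Z2, Garg = Garg, G = G,
                                   Z3 = Z3, H = H, n = n, P1 = P1, P2 = P2,
                                   P3 = P3, f1 = f1, f2 = f2))
}

# Backward pass: mean cross-entropy gradient for a one-hot label matrix Y.
cnn_backward <- function(weights, cfg, fw, Y) {
  cc <- fw$cache
  n <- cc$n
  dlogits <- (fw$probs - Y) / n
  grads <- list()
  grads$W4 <- crossprod(cc$H, dlogits)
  grads$b4 <- colSums(dlogits)
  dH <- dlogits %*% t(weights$W4)
  dH[cc$Z3 <= 0] <- 0
  grads$W3 <- crossprod(cc$G, dH)
  grads$b3 <- colSums(dH)
  dG <- dH %*% t(weights$W3)
  # route dG to the argmax position of each (sample, channel)
  dA2a <- array(0, dim = c(n, cc$P3, cc$f2))
  samp <- rep(seq_len(n), times = cc$f2)
  chan <- rep(seq_len(cc$f2), each = n)
  dA2a[cbind(samp, as.vector(cc$Garg), chan)] <- as.vector(dG)
  dZ2 <- matrix(dA2a, n * cc$P3, cc$f2)
  dZ2[cc$Z2 <= 0] <- 0
  grads$W2 <- crossprod(cc$M2, dZ2)
  grads$b2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(weights$W2)
  dPool <- col2im(dM2, n, cc$P2, cc$f1, cfg$widths[2])
  # undo width-2 max pooling
  dA1a <- array(0, dim = c(n, cc$P1, cc$f1))
  oddix <- seq(1L, 2L * cc$P2, by = 2L)
  dA1a[, oddix, ] <- dPool * cc$take_odd
  dA1a[, oddix + 1L, ] <- dPool * !cc$take_odd
  dZ1 <- matrix(dA1a, n * cc$P1, cc$f1)
  dZ1[cc$Z1 <= 0] <- 0
  grads$W1 <- crossprod(cc$M1, dZ1)
  grads$b1 <- colSums(dZ1)
  grads
}

cnn_loss <- function(probs, Y) {
  -mean(log(rowSums(probs * Y) + 1e-12))
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

onehot_labels <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  colnames(Y) <- classes
  Y
}

#' Train the read-origin classifier
#'
#' Trains the two-conv + one-dense network on labeled 76-base segments
#' and returns the per-epoch checkpoint with the highest mean one-vs-all
#' AUPRC on the validation set. With `epochs = 0` the freshly initialized
#' model is returned (and remains evaluable).
#'
#' @param datasets List from [build_dataset()] with non-empty `train` and
#'   `val` tibbles; both must contain all three classes.
#' @param config A [classifier_config()].
#' @param quiet Suppress per-epoch progress.
#' @return A `microseek_classifier` object (weights, config, training
#'   history, `val_auprc` of the selected checkpoint).
#' @export
train_classifier <- function(datasets, config = classifier_config(),
                             quiet = TRUE) {
  stopifnot(inherits(config, "classifier_config"))
  train <- datasets$train; val <- datasets$val
  if (nrow(train) == 0 || nrow(val) == 0) {
    stop("train and validation sets must be non-empty")
  }
  for (nm in c("train", "val")) {
    miss <- setdiff(config$classes, unique(datasets[[nm]]$label))
    if (length(miss) > 0) {
      stop(nm, " split is missing class(es): ", paste(miss, collapse = ", "))
    }
  }
  Xtr <- encode_onehot(train$segment, config$input_length)
  Ytr <- onehot_labels(train$label, config$classes)
  Xval <- encode_onehot(val$segment, config$input_length)

  with_seed(config$rng_seed, {
    weights <- cnn_init(config)
    state <- adam_init(weights)
    n <- nrow(train)
    best <- list(weights = weights, val_auprc = NA_real_)
    history <- list()
    val_metric <- function(w) {
      probs <- cnn_predict_array(w, Xval, config)
      mean(vapply(config$classes,
                  function(k) auprc(probs[, k], val$label == k), numeric(1)))
    }
    if (config$epochs == 0) {
      best$val_auprc <- val_metric(weights)
    }
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        fw <- cnn_forward(weights, Xtr[idx, , , drop = FALSE], config,
                          keep_cache = TRUE)
        losses <- c(losses, cnn_loss(fw$probs, Ytr[idx, , drop = FALSE]))
        grads <- cnn_backward(weights, config, fw, Ytr[idx, , drop = FALSE])
        upd <- adam_step(weights, grads, state, config$learning_rate)
        weights <- upd$weights; state <- upd$state
      }
      vm <- val_metric(weights)
      history[[ep]] <- c(epoch = ep, loss = mean(losses), val_auprc = vm)
      if (!quiet) {
        message(sprintf("epoch %d  loss %.4f  val mean AUPRC %.4f",
                        ep, mean(losses), vm))
      }
      if (is.na(best$val_auprc) || vm > best$val_auprc) {
        best <- list(weights = weights, val_auprc = vm)
      }
    }
    structure(list(weights = best$weights, config = config,
                   classes = config$classes,
                   val_auprc = best$val_auprc,
                   history = do.call(rbind, history)),
              class = "microseek_classifier")
  })
}

# Predict class probabilities for an encoded array, in batches.
cnn_predict_array <- function(weights, X, cfg, batch = 512L) {
  n <- dim(X)[1]
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, cfg$classes))
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    out[idx, ] <- cnn_forward(weights, X[idx, , , drop = FALSE], cfg)$probs
  }
  out
}

#' Predict origin probabilities for clean fixed-length sequences
#'
#' @param model A `microseek_classifier`.
#' @param sequences N-free sequences of the model's input length.
#' @return Matrix of probabilities with columns `human`, `viral`,
#'   `bacterial` (rows sum to 1).
#' @export
predict_origin <- function(model, sequences) {
  stopifnot(inherits(model, "microseek_classifier"))
  if (length(sequences) == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, model$classes)))
  }
  X <- encode_onehot(sequences, model$config$input_length)
  cnn_predict_array(model$weights, X, model$config)
}

#' Score a read set
#'
#' Normalizes reads (N rules and 3' padding, see [normalize_reads()]) and
#' assigns each retained read its origin-probability triple. The per-read
#' random draws (N replacement, padding) come from a dedicated stream
#' seeded by `rng_seed`.
#'
#' @param model A `microseek_classifier`.
#' @param reads Tibble with `read_id` and `sequence`.
#' @param rng_seed Seed for the normalization draws.
#' @return Tibble: `read_id`, `sequence`, `p_human`, `p_viral`,
#'   `p_bacterial`, `excluded`, `n_fill`. Excluded reads (more than one N)
#'   carry `NA` scores.
#' @export
score_reads <- function(model, reads, rng_seed = 1L) {
  stopifnot(inherits(model, "microseek_classifier"))
  if (nrow(reads) == 0) {
    return(tibble::tibble(read_id = character(0), sequence = character(0),
                          p_human = numeric(0), p_viral = numeric(0),
                          p_bacterial = numeric(0), excluded = logical(0),
                          n_fill = character(0)))
  }
  norm <- with_seed(rng_seed,
                    normalize_reads(reads$sequence,
                                    model$config$input_length))
  p <- matrix(NA_real_, nrow(reads), 3, dimnames = list(NULL, model$classes))
  keep <- !norm$excluded
  if (any(keep)) {
    p[keep, ] <- predict_origin(model, norm$scoring_sequence[keep])
  }
  tibble::tibble(read_id = reads$read_id, sequence = reads$sequence,
                 p_human = p[, "human"], p_viral = p[, "viral"],
                 p_bacterial = p[, "bacterial"], excluded = norm$excluded,
                 n_fill = norm$n_fill)
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model A `microseek_classifier`.
#' @param test Tibble with `segment` and `label` columns.
#' @return See [evaluate_classifier_scores()].
#' @export
evaluate_classifier <- function(model, test) {
  if (nrow(test) == 0) stop("test set must be non-empty")
  probs <- predict_origin(model, test$segment)
  evaluate_classifier_scores(probs, test$label)
}
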