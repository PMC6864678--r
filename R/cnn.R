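#' Width of a valid convolution output
#'
#' No-padding ("valid") convolution: `floor((input_width - filter_width) /
#' stride) + 1` filter placements. For the default 7 x 837 input and 7 x 7
#' filters sliding horizontally at stride 1 this is 831.
#'
#' @param input_width,filter_width,stride Positive integers;
#'   `filter_width <= input_width`.
#' @return Integer output length.
#' @export
conv_output_length <- function(input_width, filter_width, stride = 1) {
  if (stride < 1) stop("stride must be >= 1")
  if (filter_width > input_width) {
    stop("filter is wider than the input; valid convolution impossible")
  }
  as.integer((input_width - filter_width) %/% stride) + 1L
}

#' CNN architecture and training specification
#'
#' The network is: conv(`n_filters` full-height `filter_rows` x `filter_cols`
#' filters, valid, stride `stride`) -> ReLU -> flatten -> FC(`hidden_fc`)
#' -> ReLU -> FC(`n_classes`) -> softmax, trained with plain SGD on the
#' cross-entropy loss. Because the filters span the full input height, each
#' slides horizontally only and yields a 1-D feature map; there is no pooling
#' layer -- spectral features are amplitude relations between exact
#' wavelengths, so their precise location must be preserved.
#'
#' @param input_rows,input_cols Input matrix shape (default 7 x 837).
#' @param n_filters Convolution kernels (default 32).
#' @param filter_rows,filter_cols Kernel shape (default 7 x 7);
#'   `filter_rows` must equal `input_rows`.
#' @param stride Horizontal stride (default 1).
#' @param hidden_fc Width of the hidden fully connected layer (default 64).
#' @param n_classes Output classes (default 9).
#' @param learning_rate SGD learning rate (default 0.1).
#' @param momentum SGD momentum (default 0; plain SGD).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size (default 32); a value >= the training-set
#'   size gives deterministic full-batch gradient descent.
#' @param seed Seed for parameter initialization and batch shuffling.
#' @return Object of class `cnn_spec` with the derived fields `conv_len`
#'   (feature-map length) and `flat_size` (`n_filters * conv_len`).
#' @export
cnn_spec <- function(input_rows = 7, input_cols = 837, n_filters = 32,
                     filter_rows = 7, filter_cols = 7, stride = 1,
                     hidden_fc = 64, n_classes = 9,
                     learning_rate = 0.1, momentum = 0, epochs = 500,
                     batch_size = 32, seed = 1) {
  if (filter_rows != input_rows) {
    stop("filter_rows must equal input_rows: the kernel spans the full height ",
         "and slides horizontally only")
  }
  if (momentum != 0) stop("plain SGD only: momentum must be 0")
  conv_len <- conv_output_length(input_cols, filter_cols, stride)
  structure(
    list(
      input_rows = as.integer(input_rows), input_cols = as.integer(input_cols),
      n_filters = as.integer(n_filters),
      filter_rows = as.integer(filter_rows), filter_cols = as.integer(filter_cols),
      stride = as.integer(stride), hidden_fc = as.integer(hidden_fc),
      n_classes = as.integer(n_classes),
      learning_rate = learning_rate, momentum = momentum,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      seed = as.integer(seed),
      conv_len = conv_len, flat_size = as.integer(n_filters) * conv_len
    ),
    class = "cnn_spec"
  )
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialize) a CNN model
#'
#' Allocates the network parameters with seeded Glorot (fan-average) uniform
#' initialization; for the convolution kernels the fans follow the usual
#' receptive-field convention (fan_in = kernel size, fan_out = kernel size
#' times filter count). The architecture arithmetic (feature-map length,
#' flatten size) is validated at build time.
#'
#' @param spec A [cnn_spec()].
#' @return Object of class `tea_cnn`: the parameter matrices (`Wc`, `bc`,
#'   `W1`, `b1`, `W2`, `b2`), the spec, and empty training state.
#' @export
build_cnn <- function(spec = cnn_spec()) {
  stopifnot(inherits(spec, "cnn_spec"))
  k <- spec$filter_rows * spec$filter_cols
  stopifnot(spec$flat_size == spec$n_filters * spec$conv_len)
  withr::with_seed(spec$seed, {
    model <- list(
      spec = spec,
      Wc = glorot_uniform(spec$n_filters, k,
                          fan_in = k, fan_out = k * spec$n_filters),
      bc = numeric(spec$n_filters),
      W1 = glorot_uniform(spec$flat_size, spec$hidden_fc,
                          fan_in = spec$flat_size, fan_out = spec$hidden_fc),
      b1 = numeric(spec$hidden_fc),
      W2 = glorot_uniform(spec$hidden_fc, spec$n_classes,
                          fan_in = spec$hidden_fc, fan_out = spec$n_classes),
      b2 = numeric(spec$n_classes),
      classes = NULL, trained = FALSE, trace = NULL
    )
  })
  class(model) <- "tea_cnn"
  model
}

#' @export
print.tea_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<tea_cnn> conv(%d x %dx%d) -> %d maps of %d -> flatten %d -> FC %d -> FC %d%s\n",
    s$n_filters, s$filter_rows, s$filter_cols, s$n_filters, s$conv_len,
    s$flat_size, s$hidden_fc, s$n_classes,
    if (x$trained) " [trained]" else " [untrained]"
  ))
  invisible(x)
}

# Linear indices of all filter patches in one column-major input matrix:
# a (filter_rows*filter_cols) x conv_len matrix.
im2col_index <- function(spec) {
  ir <- spec$input_rows
  base <- as.vector(outer(seq_len(ir), (seq_len(spec$filter_cols) - 1L) * ir, "+"))
  pos <- (seq_len(spec$conv_len) - 1L) * spec$stride * ir
  outer(base, pos, "+")
}

# Stack a list of input matrices into the im2col design matrix.
# Rows are position-major: row (p-1)*n + i holds patch p of sample i. With
# this layout, flattening the ReLU conv maps of a batch into per-sample
# feature vectors (and the reverse, in the backward pass) is a zero-copy
# dim reinterpretation rather than an aperm.
cnn_im2col <- function(matrices, spec) {
  idx <- im2col_index(spec)
  L <- spec$conv_len
  K <- nrow(idx)
  n <- length(matrices)
  out <- matrix(0, n * L, K)
  for (i in seq_len(n)) {
    m <- matrices[[i]]
    if (nrow(m) != spec$input_rows || ncol(m) != spec$input_cols) {
      stop(sprintf("input %d is %d x %d, expected %d x %d",
                   i, nrow(m), ncol(m), spec$input_rows, spec$input_cols))
    }
    out[i + n * (seq_len(L) - 1L), ] <- t(matrix(m[idx], K, L))
  }
  out
}

# Rows of the position-major im2col matrix (built over n samples) that
# belong to the batch sample indices bi, again position-major.
im2col_batch_rows <- function(bi, n, L) {
  as.vector(outer(bi, (seq_len(L) - 1L) * n, "+"))
}

cnn_inputs <- function(x) {
  if (inherits(x, "processed_dataset")) x$matrices
  else if (inherits(x, "processed_matrix")) list(x)
  else if (is.list(x)) x
  else stop("expected a processed_dataset, a processed_matrix, or a list of matrices")
}

# Forward pass over a position-major im2col block of n samples. Returns the
# activations needed for the backward pass. Flattening maps sample i to the
# vector (map 1, map 2, ...), each map of length conv_len: with the
# position-major layout this is a dim reinterpretation, not a copy.
cnn_forward <- function(model, Xc, n) {
  s <- model$spec
  Zc <- tcrossprod(Xc, model$Wc)                            # (n*L) x nf, pre-bias
  Zc <- Zc + rep(model$bc, each = nrow(Zc))
  A <- pmax(Zc, 0)
  Fl <- A
  dim(Fl) <- c(n, s$flat_size)                              # n x (L * nf)
  Z1 <- Fl %*% model$W1
  Z1 <- Z1 + rep(model$b1, each = n)
  H <- pmax(Z1, 0)
  logits <- H %*% model$W2
  logits <- logits + rep(model$b2, each = n)
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  list(Zc = Zc, Fl = Fl, Z1 = Z1, H = H, P = P)
}

# Backward pass: mean cross-entropy gradient for a batch with one-hot Y.
cnn_backward <- function(model, Xc, n, fwd, Y) {
  G <- (fwd$P - Y) / n
  dW2 <- crossprod(fwd$H, G)
  db2 <- colSums(G)
  dH <- tcrossprod(G, model$W2)
  dH[fwd$Z1 <= 0] <- 0
  dW1 <- crossprod(fwd$Fl, dH)
  db1 <- colSums(dH)
  dZc <- tcrossprod(dH, model$W1)                           # n x flat_size
  dim(dZc) <- c(n * model$spec$conv_len, model$spec$n_filters)
  dZc[fwd$Zc <= 0] <- 0
  dWc <- crossprod(dZc, Xc)                                 # nf x K
  dbc <- colSums(dZc)
  list(dWc = dWc, dbc = dbc, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

cnn_loss <- function(P, yidx) {
  -mean(log(pmax(P[cbind(seq_along(yidx), yidx)], 1e-300)))
}

# Worst per-sample loss in a batch; a value near the clamp ceiling
# (-log(1e-300) ~ 690) means some true class has numerically zero
# probability, i.e. the optimization has diverged.
cnn_worst_loss <- function(P, yidx) {
  max(-log(pmax(P[cbind(seq_along(yidx), yidx)], 1e-300)))
}

# Predicted class indices for a (possibly large) im2col block, chunked to
# bound transient memory.
cnn_predict_idx <- function(model, Xc, n, chunk = 256L) {
  L <- model$spec$conv_len
  if (n <= chunk) {
    fwd <- cnn_forward(model, Xc, n)
    return(max.col(fwd$P, ties.method = "first"))
  }
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    rows <- im2col_batch_rows(start:end, n, L)
    fwd <- cnn_forward(model, Xc[rows, , drop = FALSE], end - start + 1L)
    out[start:end] <- max.col(fwd$P, ties.method = "first")
  }
  out
}

#' Train the CNN with stochastic gradient descent
#'
#' Minimizes the multiclass cross-entropy by plain SGD (learning rate from
#' the spec, no momentum) for `epochs` epochs, recording per epoch the
#' running training accuracy, the test accuracy (full forward pass at epoch
#' end) and the mean training loss. Shuffling and initialization are seeded,
#' so a run is fully reproducible; with `batch_size >=` the training-set size
#' the method is deterministic full-batch gradient descent over the samples
#' in canonical order.
#'
#' @param model A [build_cnn()] model.
#' @param train,test `processed_dataset`s (or lists of matrices plus `labels`
#'   supplied as factors via `train_labels`/`test_labels`).
#' @param train_labels,test_labels Labels; taken from the datasets when
#'   omitted.
#' @param epochs,batch_size,learning_rate Override the spec values.
#' @param seed Seed for batch shuffling (default: the spec seed).
#' @return The trained `tea_cnn`, with `$trace` a data.frame
#'   (`epoch`, `train_acc`, `test_acc`, `loss`) of length `epochs`.
#' @export
train_cnn <- function(model, train, test,
                      train_labels = NULL, test_labels = NULL,
                      epochs = NULL, batch_size = NULL, learning_rate = NULL,
                      seed = NULL) {
  stopifnot(inherits(model, "tea_cnn"))
  s <- model$spec
  epochs <- if (is.null(epochs)) s$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) s$batch_size else as.integer(batch_size)
  lr <- if (is.null(learning_rate)) s$learning_rate else learning_rate
  seed <- if (is.null(seed)) s$seed else as.integer(seed)

  if (is.null(train_labels)) train_labels <- train$labels
  if (is.null(test_labels)) test_labels <- test$labels
  train_labels <- as.factor(train_labels)
  lev <- levels(train_labels)
  if (length(lev) != s$n_classes) {
    stop(sprintf("training labels cover %d classes, spec expects %d",
                 length(lev), s$n_classes))
  }
  test_labels <- factor(test_labels, levels = lev)

  Xtr <- cnn_im2col(cnn_inputs(train), s)
  Xte <- cnn_im2col(cnn_inputs(test), s)
  n <- length(train_labels)
  n_te <- length(test_labels)
  ytr <- as.integer(train_labels)
  L <- s$conv_len
  Y_full <- diag(s$n_classes)

  trace <- data.frame(
    epoch = seq_len(epochs),
    train_acc = NA_real_, test_acc = NA_real_, loss = NA_real_
  )
  full_batch <- batch_size >= n
  # pre-draw every epoch's shuffle so the training loop itself is RNG-free
  orders <- withr::with_seed(seed, {
    if (full_batch) NULL else
      vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
  })

  {
    for (ep in seq_len(epochs)) {
      order_ep <- if (full_batch) seq_len(n) else orders[, ep]
      starts <- seq(1L, n, by = batch_size)
      correct <- 0L
      loss_sum <- 0
      for (b in starts) {
        bi <- order_ep[b:min(b + batch_size - 1L, n)]
        nb <- length(bi)
        Xb <- if (full_batch) Xtr else
          Xtr[im2col_batch_rows(bi, n, L), , drop = FALSE]
        fwd <- cnn_forward(model, Xb, nb)
        yb <- ytr[bi]
        loss_b <- cnn_loss(fwd$P, yb)
        if (!is.finite(loss_b) || cnn_worst_loss(fwd$P, yb) > 600) {
          stop("training diverged (non-finite or exploding loss); ",
               "the learning rate (", lr, ") is the likely cause")
        }
        correct <- correct + sum(max.col(fwd$P, ties.method = "first") == yb)
        loss_sum <- loss_sum + loss_b * nb
        g <- cnn_backward(model, Xb, nb, fwd, Y_full[yb, , drop = FALSE])
        model$Wc <- model$Wc - lr * g$dWc
        model$bc <- model$bc - lr * g$dbc
        model$W1 <- model$W1 - lr * g$dW1
        model$b1 <- model$b1 - lr * g$db1
        model$W2 <- model$W2 - lr * g$dW2
        model$b2 <- model$b2 - lr * g$db2
      }
      trace$train_acc[ep] <- correct / n
      trace$loss[ep] <- loss_sum / n
      trace$test_acc[ep] <-
        mean(cnn_predict_idx(model, Xte, n_te) == as.integer(test_labels))
    }
  }
  model$classes <- lev
  model$trained <- TRUE
  model$trace <- trace
  model
}

#' Predict classes and probabilities with a trained CNN
#'
#' @param object A trained `tea_cnn`.
#' @param newdata A `processed_dataset`, a single `processed_matrix`, or a
#'   list of input matrices.
#' @param ... Unused.
#' @return List with `class` (factor of predicted labels) and `prob`
#'   (observations x classes softmax probabilities; rows sum to 1).
#' @export
predict.tea_cnn <- function(object, newdata, ...) {
  if (!object$trained) warning("predicting with an untrained model")
  mats <- cnn_inputs(newdata)
  s <- object$spec
  Xc <- cnn_im2col(mats, s)
  n <- length(mats)
  L <- s$conv_len
  P <- matrix(0, n, s$n_classes)
  for (start in seq(1L, n, by = 256L)) {
    end <- min(start + 255L, n)
    idx <- if (n <= 256L) seq_len(nrow(Xc)) else im2col_batch_rows(start:end, n, L)
    fwd <- cnn_forward(object, Xc[idx, , drop = FALSE], end - start + 1L)
    P[start:end, ] <- fwd$P
  }
  lev <- if (!is.null(object$classes)) object$classes else
    as.character(seq_len(s$n_classes))
  colnames(P) <- lev
  list(class = factor(lev[max.col(P, ties.method = "first")], levels = lev),
       prob = P)
}

#' Activations of the last hidden layer
#'
#' Returns the post-ReLU activations of the hidden fully connected layer
#' (the layer before the softmax output), one feature vector per input --
#' the representation whose PCA projection visualizes what the network has
#' learned.
#'
#' @param model A `tea_cnn`.
#' @param data Inputs as in [predict.tea_cnn()].
#' @return Observations x `hidden_fc` matrix.
#' @export
penultimate_features <- function(model, data) {
  stopifnot(inherits(model, "tea_cnn"))
  if (!model$trained) warning("extracting features from an untrained model")
  mats <- cnn_inputs(data)
  s <- model$spec
  Xc <- cnn_im2col(mats, s)
  n <- length(mats)
  L <- s$conv_len
  H <- matrix(0, n, s$hidden_fc)
  for (start in seq(1L, n, by = 256L)) {
    end <- min(start + 255L, n)
    idx <- if (n <= 256L) seq_len(nrow(Xc)) else im2col_batch_rows(start:end, n, L)
    fwd <- cnn_forward(model, Xc[idx, , drop = FALSE], end - start + 1L)
    H[start:end, ] <- fwd$H
  }
  H
}
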