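test_that("valid-convolution output length follows the placement count", {
  expect_identical(conv_output_length(837, 7, 1), 831L)
  expect_identical(conv_output_length(7, 7, 1), 1L)
  # oracle: enumerate valid placements
  enum <- function(w, f, s) length(seq(1, w - f + 1, by = s))
  for (case in list(c(10, 3, 2), c(15, 4, 3), c(9, 9, 1), c(20, 5, 1))) {
    expect_identical(conv_output_length(case[1], case[2], case[3]),
                     as.integer(enum(case[1], case[2], case[3])))
  }
  expect_error(conv_output_length(5, 7, 1), "wider")
})

test_that("default architecture arithmetic: 32 maps of 831, flatten 26592", {
  spec <- cnn_spec()
  expect_equal(spec$conv_len, 831L)
  expect_equal(spec$n_filters, 32L)
  expect_equal(spec$flat_size, 26592L)
  model <- build_cnn(spec)
  expect_equal(dim(model$Wc), c(32L, 49L))
  expect_equal(dim(model$W1), c(26592L, spec$hidden_fc))
  expect_equal(dim(model$W2), c(spec$hidden_fc, 9L))
  expect_error(cnn_spec(filter_rows = 5), "full height")
  expect_error(cnn_spec(momentum = 0.9), "momentum")
})

test_that("im2col extracts exactly the sliding full-height patches", {
  spec <- tiny_cnn_spec()
  m <- matrix(seq_len(spec$input_rows * spec$input_cols),
              spec$input_rows, spec$input_cols)
  Xc <- teafluor:::cnn_im2col(list(m), spec)
  for (p in c(1, 7, spec$conv_len)) {
    patch <- m[, p:(p + spec$filter_cols - 1)]
    expect_equal(unname(Xc[p, ]), as.vector(patch))
  }
})

test_that("softmax probabilities are normalized for any input", {
  spec <- tiny_cnn_spec()
  model <- build_cnn(spec)
  Xc <- teafluor:::cnn_im2col(tiny_inputs(4, spec), spec)
  fwd <- teafluor:::cnn_forward(model, Xc, 4)
  expect_equal(rowSums(fwd$P), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fwd$P >= 0))
})

test_that("a zero learning rate leaves parameters untouched and the trace flat", {
  spec <- tiny_cnn_spec(epochs = 4)
  model <- build_cnn(spec)
  inputs <- tiny_inputs(8, spec)
  labels <- factor(rep(c("p", "q"), 4))
  trained <- train_cnn(model, inputs, inputs,
                       train_labels = labels, test_labels = labels,
                       learning_rate = 0)
  expect_identical(trained$Wc, model$Wc)
  expect_identical(trained$W1, model$W1)
  expect_identical(trained$W2, model$W2)
  expect_length(unique(trained$trace$train_acc), 1L)
  expect_length(unique(trained$trace$loss), 1L)
})

test_that("analytic gradients match central finite differences", {
  spec <- tiny_cnn_spec()
  model <- build_cnn(spec)
  n <- 6
  inputs <- tiny_inputs(n, spec, seed = 21)
  yidx <- rep(1:2, 3)
  Y <- diag(2)[yidx, ]
  Xc <- teafluor:::cnn_im2col(inputs, spec)
  fwd <- teafluor:::cnn_forward(model, Xc, n)
  grad <- teafluor:::cnn_backward(model, Xc, n, fwd, Y)
  loss_at <- function(m) {
    teafluor:::cnn_loss(teafluor:::cnn_forward(m, Xc, n)$P, yidx)
  }
  h <- 1e-6
  set.seed(33)
  for (par in c("Wc", "W1", "W2", "bc", "b1", "b2")) {
    g <- grad[[paste0("d", par)]]
    idx <- sample(length(model[[par]]), min(12, length(model[[par]])))
    for (i in idx) {
      mp <- model; mp[[par]][i] <- mp[[par]][i] + h
      mm <- model; mm[[par]][i] <- mm[[par]][i] - h
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      denom <- max(abs(fd), abs(g[i]), 1e-4)
      expect_lt(abs(fd - g[i]) / denom, 1e-4,
                label = sprintf("grad %s[%d] (fd %.3e vs analytic %.3e)",
                                par, i, fd, g[i]))
    }
  }
})

test_that("full-batch training is invariant to sample order", {
  spec <- tiny_cnn_spec(epochs = 5)
  inputs <- tiny_inputs(10, spec, seed = 4)
  labels <- factor(rep(c("p", "q"), 5))
  perm <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  m1 <- train_cnn(build_cnn(spec), inputs, inputs,
                  train_labels = labels, test_labels = labels)
  m2 <- train_cnn(build_cnn(spec), inputs[perm], inputs,
                  train_labels = labels[perm], test_labels = labels)
  expect_equal(m1$W1, m2$W1, tolerance = 1e-8)
  expect_equal(m1$trace$loss, m2$trace$loss, tolerance = 1e-8)
})

test_that("training is reproducible and the loss decreases on separable data", {
  pd <- preprocess_dataset(generate_dataset(20, seed = 3, overlap = 0))
  sp <- split_dataset(pd, 0.5, seed = 3)
  spec <- cnn_spec(hidden_fc = 64, epochs = 100, seed = 5)
  model <- train_cnn(build_cnn(spec), sp$train, sp$test)
  tr <- model$trace
  expect_equal(nrow(tr), 100L)
  expect_true(all(tr$train_acc >= 0 & tr$train_acc <= 1))
  # the trained model fits the separable training set essentially perfectly
  # (the trace's running accuracy lags the end-of-epoch model slightly)
  pred_tr <- predict(model, sp$train)
  expect_gte(accuracy(sp$train$labels, pred_tr$class), 0.99)
  expect_lt(mean(tail(tr$loss, 20)), mean(head(tr$loss, 20)))

  pred <- predict(model, sp$test)
  expect_equal(rowSums(pred$prob), rep(1, length(sp$test$labels)),
               tolerance = 1e-6)
  expect_gte(accuracy(sp$test$labels, pred$class), 0.99)
  # duplicated inputs give identical predictions
  dup <- predict(model, sp$test$matrices[c(1, 1)])
  expect_identical(dup$class[1], dup$class[2])

  # reproducibility of a short run
  short <- function() {
    m <- train_cnn(build_cnn(cnn_spec(hidden_fc = 64, epochs = 3, seed = 5)),
                   sp$train, sp$test)
    m$W2
  }
  expect_identical(short(), short())
})

test_that("penultimate features equal ReLU of the bias path for zero input", {
  spec <- tiny_cnn_spec()
  model <- build_cnn(spec)
  model$trained <- TRUE
  zero <- list(matrix(0, spec$input_rows, spec$input_cols))
  H <- penultimate_features(model, zero)
  A <- pmax(model$bc, 0)
  Fl <- rep(A, each = spec$conv_len)
  expected <- pmax(drop(crossprod(model$W1, Fl)) + model$b1, 0)
  expect_equal(as.vector(H), expected)
  expect_equal(ncol(H), spec$hidden_fc)
})

test_that("a wildly excessive learning rate raises a divergence error", {
  spec <- tiny_cnn_spec(epochs = 50)
  inputs <- tiny_inputs(8, spec)
  labels <- factor(rep(c("p", "q"), 4))
  expect_error(
    train_cnn(build_cnn(spec), inputs, inputs,
              train_labels = labels, test_labels = labels,
              learning_rate = 1e8),
    "learning rate"
  )
})
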