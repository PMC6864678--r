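#' Default per-LED principal-component counts
#'
#' The component counts used by the per-LED PCA+kNN baselines, channel 1-7.
#' @return Integer vector of length 7: 11, 6, 3, 3, 3, 4, 11.
#' @export
default_pc_numbers <- function() c(11L, 6L, 3L, 3L, 3L, 4L, 11L)

baseline_result <- function(mode, pc_numbers, accuracy, scores, scores_labels,
                            predicted, truth) {
  structure(
    list(
      mode = mode, pc_numbers = pc_numbers, accuracy = accuracy,
      scores = scores, scores_labels = scores_labels,
      predicted = predicted, truth = truth,
      confusion = confusion_matrix(truth, predicted, levels(truth))
    ),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> %s: accuracy %.3f (PCs: %s)\n",
              x$mode, x$accuracy, paste(x$pc_numbers, collapse = "+")))
  invisible(x)
}

#' PCA+kNN on a single LED channel
#'
#' Fits PCA on the training spectra of one LED row only, projects train and
#' test onto the leading components, and classifies the test set by kNN.
#'
#' @param train,test `processed_dataset`s from [split_dataset()].
#' @param led_index LED channel, 1-7.
#' @param pc_number Components to keep; default the channel's entry of
#'   [default_pc_numbers()].
#' @param k,metric kNN configuration, see [knn_predict()].
#' @return A `baseline_result`: mode, pc numbers, test accuracy, the test-set
#'   PC1 x PC2 scores (for score plots), predictions and confusion matrix.
#' @export
run_per_led <- function(train, test, led_index,
                        pc_number = default_pc_numbers()[led_index],
                        k = 5, metric = "euclidean") {
  stopifnot(led_index %in% 1:7)
  Xtr <- as_feature_matrix(train, led = led_index)
  Xte <- as_feature_matrix(test, led = led_index)
  pca <- fit_pca(Xtr, pc_number)
  Str <- project_pca(pca, Xtr)
  Ste <- project_pca(pca, Xte)
  pred <- knn_predict(Str, train$labels, Ste, k = k, metric = metric)
  baseline_result(
    mode = sprintf("per-LED %d", led_index), pc_numbers = pc_number,
    accuracy = accuracy(test$labels, pred),
    scores = Ste[, 1:2, drop = FALSE], scores_labels = test$labels,
    predicted = pred, truth = test$labels
  )
}

#' PCA+kNN on concatenated spectra ("1~7")
#'
#' Every 7 x 837 matrix is flattened row-major (LED1 block first) to one
#' 5859-feature vector before a single PCA and kNN.
#'
#' @param train,test `processed_dataset`s.
#' @param pc_number Components to keep (default 9).
#' @param k,metric kNN configuration.
#' @return A `baseline_result` (mode `"concatenated-spectra"`).
#' @export
run_concatenated_spectra <- function(train, test, pc_number = 9,
                                     k = 5, metric = "euclidean") {
  Xtr <- as_feature_matrix(train)
  Xte <- as_feature_matrix(test)
  pca <- fit_pca(Xtr, pc_number)
  Str <- project_pca(pca, Xtr)
  Ste <- project_pca(pca, Xte)
  pred <- knn_predict(Str, train$labels, Ste, k = k, metric = metric)
  baseline_result(
    mode = "concatenated-spectra", pc_numbers = pc_number,
    accuracy = accuracy(test$labels, pred),
    scores = Ste[, 1:2, drop = FALSE], scores_labels = test$labels,
    predicted = pred, truth = test$labels
  )
}

#' PCA+kNN on concatenated per-LED components ("1+...+7")
#'
#' Seven per-LED PCA models are fitted on the training data; the per-LED
#' scores are concatenated (default 11+6+3+3+3+4+11 = 41 features) and
#' passed to kNN.
#'
#' @param train,test `processed_dataset`s.
#' @param per_led_pc_numbers Components per LED (length 7; default
#'   [default_pc_numbers()]).
#' @param k,metric kNN configuration.
#' @return A `baseline_result` (mode `"concatenated-PCs"`).
#' @export
run_concatenated_pcs <- function(train, test,
                                 per_led_pc_numbers = default_pc_numbers(),
                                 k = 5, metric = "euclidean") {
  if (length(per_led_pc_numbers) != 7L) {
    stop("per_led_pc_numbers must give one component count per LED (length 7)")
  }
  Str <- NULL
  Ste <- NULL
  for (led in 1:7) {
    Xtr <- as_feature_matrix(train, led = led)
    Xte <- as_feature_matrix(test, led = led)
    pca <- fit_pca(Xtr, per_led_pc_numbers[led])
    Str <- cbind(Str, project_pca(pca, Xtr))
    Ste <- cbind(Ste, project_pca(pca, Xte))
  }
  pred <- knn_predict(Str, train$labels, Ste, k = k, metric = metric)
  baseline_result(
    mode = "concatenated-PCs", pc_numbers = per_led_pc_numbers,
    accuracy = accuracy(test$labels, pred),
    scores = Ste[, 1:2, drop = FALSE], scores_labels = test$labels,
    predicted = pred, truth = test$labels
  )
}
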