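#' Classification accuracy
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted have different lengths")
  }
  if (length(truth) == 0L) stop("empty label vectors")
  mean(as.character(truth) == as.character(predicted))
}

#' Confusion matrix
#'
#' @param truth,predicted Label vectors.
#' @param labels Label order for rows/columns; defaults to the union of
#'   factor levels.
#' @return Square count matrix: entry (i, j) = number of class-i items
#'   predicted as class j.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), labels)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  tab <- table(
    factor(truth, levels = labels),
    factor(predicted, levels = labels),
    dnn = c("truth", "predicted")
  )
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' Centroid separation of a class in a 2-D score plot
#'
#' Measures how far one class's centroid sits from every other class
#' centroid, in units of the mean within-class spread (root-mean-square
#' distance of points to their own centroid, averaged over classes). A value
#' above 2 means the class forms a visibly separate cluster in the score
#' plot.
#'
#' @param scores Observations x 2 score matrix (e.g. PC1 x PC2).
#' @param labels Class labels.
#' @param target Class whose separation is measured.
#' @return Numeric: min over other classes of the centroid distance, divided
#'   by the mean within-class spread.
#' @export
class_separation <- function(scores, labels, target) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.factor(labels)
  stopifnot(target %in% levels(labels))
  cent <- t(vapply(levels(labels), function(l) {
    colMeans(scores[labels == l, , drop = FALSE])
  }, numeric(2)))
  spread <- mean(vapply(levels(labels), function(l) {
    pts <- scores[labels == l, , drop = FALSE]
    sqrt(mean(rowSums(sweep(pts, 2, cent[l, ], "-")^2)))
  }, numeric(1)))
  others <- setdiff(levels(labels), target)
  d <- vapply(others, function(l) {
    sqrt(sum((cent[target, ] - cent[l, ])^2))
  }, numeric(1))
  min(d) / spread
}

#' Configuration for the full model comparison
#'
#' Defaults define the package's standard evaluation: 60 measurements per
#' class, a 50/50 stratified split, the calibrated-overlap generator, the
#' fixed per-LED component counts, kNN with k = 5, and a 200-epoch CNN,
#' repeated over 3 seeds.
#'
#' @param n_per_class,overlap,seeds Generator scale, overlap dial and the
#'   seeds the comparison is repeated over.
#' @param split_fraction Training fraction.
#' @param sg_window,sg_poly Savitzky--Golay parameters.
#' @param k,metric kNN configuration.
#' @param per_led_pcs,concat_pcs PCA component counts.
#' @param epochs,batch_size,hidden_fc,learning_rate CNN training parameters.
#' @return Named list.
#' @export
comparison_config <- function(n_per_class = 60, overlap = 1, seeds = c(1, 2, 3),
                              split_fraction = 0.5, sg_window = 11, sg_poly = 2,
                              k = 5, metric = "euclidean",
                              per_led_pcs = default_pc_numbers(), concat_pcs = 9,
                              epochs = 200, batch_size = 32, hidden_fc = 64,
                              learning_rate = 0.1) {
  list(
    n_per_class = n_per_class, overlap = overlap, seeds = seeds,
    split_fraction = split_fraction, sg_window = sg_window, sg_poly = sg_poly,
    k = k, metric = metric,
    per_led_pcs = per_led_pcs, concat_pcs = concat_pcs,
    epochs = epochs, batch_size = batch_size, hidden_fc = hidden_fc,
    learning_rate = learning_rate
  )
}

model_names <- function() {
  c(paste0("per_led_", 1:7), "concat_spectra", "concat_pcs", "cnn")
}

run_comparison_once <- function(config, seed, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("[seed %d] generating %d x 9 measurements (overlap %.3g)",
      seed, config$n_per_class, config$overlap)
  ds <- generate_dataset(config$n_per_class, seed = seed, overlap = config$overlap)
  pd <- preprocess_dataset(ds, config$sg_window, config$sg_poly)
  sp <- split_dataset(pd, fraction = config$split_fraction, seed = seed)

  results <- list()
  for (led in 1:7) {
    results[[paste0("per_led_", led)]] <- run_per_led(
      sp$train, sp$test, led, pc_number = config$per_led_pcs[led],
      k = config$k, metric = config$metric
    )
  }
  results$concat_spectra <- run_concatenated_spectra(
    sp$train, sp$test, pc_number = config$concat_pcs,
    k = config$k, metric = config$metric
  )
  results$concat_pcs <- run_concatenated_pcs(
    sp$train, sp$test, per_led_pc_numbers = config$per_led_pcs,
    k = config$k, metric = config$metric
  )
  say("[seed %d] baselines done (best %.3f); training CNN (%d epochs)",
      seed, max(vapply(results, function(r) r$accuracy, numeric(1))),
      config$epochs)

  spec <- cnn_spec(
    hidden_fc = config$hidden_fc, epochs = config$epochs,
    batch_size = config$batch_size, learning_rate = config$learning_rate,
    seed = seed
  )
  model <- build_cnn(spec)
  model <- train_cnn(model, sp$train, sp$test)
  pred <- predict(model, sp$test)
  cnn_acc <- accuracy(sp$test$labels, pred$class)
  say("[seed %d] CNN test accuracy %.3f", seed, cnn_acc)

  accs <- c(
    vapply(results, function(r) r$accuracy, numeric(1)),
    cnn = cnn_acc
  )
  confusions <- c(
    lapply(results, function(r) r$confusion),
    list(cnn = confusion_matrix(sp$test$labels, pred$class, levels(sp$test$labels)))
  )
  list(
    seed = seed, accuracies = accs, confusions = confusions,
    trace = model$trace,
    scores_led1 = results$per_led_1$scores,
    scores_labels = as.character(results$per_led_1$scores_labels),
    model = model, split = sp
  )
}

#' Run the full baseline-vs-CNN comparison
#'
#' For each seed: generate a synthetic dataset, pre-process, split 50/50,
#' run the seven per-LED PCA+kNN baselines, the two fused baselines
#' (concatenated spectra, concatenated per-LED components) and the CNN on
#' the identical split, and record accuracies, confusion matrices, the CNN
#' training trace and the LED1 PC1 x PC2 scores. Accuracies are averaged
#' over seeds.
#'
#' @param config A [comparison_config()].
#' @param verbose Log stage progress via [message()].
#' @param keep_models Keep the trained CNN objects in the result (large).
#' @return Object of class `evaluation_report`: list with `config`, `runs`
#'   (one entry per seed) and `mean_accuracies` (named, one per model).
#' @export
run_full_comparison <- function(config = comparison_config(), verbose = TRUE,
                                keep_models = FALSE) {
  runs <- lapply(config$seeds, function(s) {
    run <- run_comparison_once(config, s, verbose = verbose)
    if (!keep_models) run$model <- NULL
    run$split <- NULL
    run
  })
  acc_mat <- t(vapply(runs, function(r) r$accuracies,
                      numeric(length(model_names()))))
  mean_acc <- colMeans(acc_mat)
  if (config$overlap >= 1 &&
      mean_acc[["cnn"]] < max(mean_acc[names(mean_acc) != "cnn"])) {
    warning("calibrated-overlap regime: mean CNN accuracy (",
            sprintf("%.3f", mean_acc[["cnn"]]),
            ") did not exceed the best baseline (",
            sprintf("%.3f", max(mean_acc[names(mean_acc) != "cnn"])), ")")
  }
  structure(
    list(config = config, runs = runs, mean_accuracies = mean_acc),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d seed(s), overlap %.3g, n_per_class %d\n",
              length(x$runs), x$config$overlap, x$config$n_per_class))
  acc <- x$mean_accuracies
  best_base <- max(acc[names(acc) != "cnn"])
  cat(sprintf("  mean accuracies: CNN %.3f | best baseline %.3f (%s)\n",
              acc[["cnn"]], best_base,
              names(acc)[names(acc) != "cnn"][which.max(acc[names(acc) != "cnn"])]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (config, per-seed and mean accuracies, confusion
#' matrices), `table1_mirror.csv` (accuracy of each model variant, one row
#' per seed plus the mean), `trace.csv` (per-epoch CNN training curves) and
#' `scores_led1.csv` (test-set PC1 x PC2 scores of the LED1 baseline).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    config = report$config,
    mean_accuracies = as.list(report$mean_accuracies),
    runs = lapply(report$runs, function(r) {
      list(seed = r$seed, accuracies = as.list(r$accuracies),
           confusions = r$confusions)
    })
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  acc_tab <- do.call(rbind, lapply(report$runs, function(r) {
    data.frame(seed = r$seed, t(r$accuracies))
  }))
  acc_tab <- rbind(acc_tab, data.frame(seed = NA, t(report$mean_accuracies)))
  data.table::fwrite(acc_tab, file.path(dir, "table1_mirror.csv"))
  traces <- do.call(rbind, lapply(report$runs, function(r) {
    cbind(seed = r$seed, r$trace)
  }))
  data.table::fwrite(traces, file.path(dir, "trace.csv"))
  scores <- do.call(rbind, lapply(report$runs, function(r) {
    data.frame(seed = r$seed, pc1 = r$scores_led1[, 1], pc2 = r$scores_led1[, 2],
               label = r$scores_labels)
  }))
  data.table::fwrite(scores, file.path(dir, "scores_led1.csv"))
  invisible(dir)
}

#' Read back a written report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return List with `config`, `mean_accuracies` and `runs`.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
}
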