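test_that("accuracy counts exact matches", {
  y <- rep(tea_class_labels(), 3)
  expect_equal(accuracy(y, y), 1.0)
  expect_equal(accuracy(y, rep("G-LJ1", length(y))), 1 / 9)
  set.seed(19)
  a <- sample(letters[1:4], 30, replace = TRUE)
  b <- sample(letters[1:4], 30, replace = TRUE)
  expect_equal(accuracy(a, b), sum(a == b) / 30)
  expect_error(accuracy(a, b[1:10]), "length")
})

test_that("confusion matrix tallies truth rows against prediction columns", {
  labs <- tea_class_labels()
  y <- rep(labs, each = 2)
  cm <- confusion_matrix(y, y, labs)
  expect_equal(unname(diag(cm)), rep(2L, 9), ignore_attr = TRUE)
  expect_equal(sum(cm), 18)

  cm2 <- confusion_matrix(y, rep("B-KM", 18), labs)
  expect_equal(sum(cm2[, "B-KM"]), 18)
  expect_equal(sum(cm2[, setdiff(labs, "B-KM")]), 0)

  set.seed(23)
  a <- sample(labs, 40, replace = TRUE)
  b <- sample(labs, 40, replace = TRUE)
  cm3 <- confusion_matrix(a, b, labs)
  for (i in labs) for (j in labs) {
    expect_equal(cm3[i, j], sum(a == i & b == j))
  }
  expect_equal(sum(diag(cm3)) / 40, accuracy(a, b))
  expect_error(confusion_matrix(a, c(b[-1], "oolong"), labs), "unknown")
})

test_that("class separation statistic behaves on constructed clusters", {
  set.seed(31)
  centers <- rbind(c(0, 0), c(10, 0), c(0.5, 0.2))
  scores <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(stats::rnorm(40, sd = 0.3), 20, 2), 2, centers[i, ], "+")
  }))
  labels <- rep(c("far", "isolated", "near"), each = 20)
  expect_gt(class_separation(scores, labels, "isolated"), 2)
  expect_lt(class_separation(scores, labels, "near"), 2)
})

test_that("evaluation report serializes and round-trips", {
  report <- separable_report()
  dir <- withr::local_tempdir()
  write_report(report, dir)
  expect_true(all(file.exists(file.path(
    dir, c("report.json", "table1_mirror.csv", "trace.csv", "scores_led1.csv")
  ))))
  back <- read_report_json(file.path(dir, "report.json"))
  expect_equal(unlist(back$mean_accuracies),
               report$mean_accuracies, tolerance = 1e-12)
  expect_equal(back$config$n_per_class, report$config$n_per_class)
  # write -> read -> write is a fixed point
  dir2 <- withr::local_tempdir()
  jsonlite::write_json(back, file.path(dir2, "again.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  back2 <- read_report_json(file.path(dir2, "again.json"))
  expect_equal(back2, back)
})

test_that("fusing all seven LEDs gives no large gain over the best single LED", {
  report <- calibrated_report()
  acc <- report$mean_accuracies
  best_single <- max(acc[paste0("per_led_", 1:7)])
  expect_lt(abs(acc[["concat_spectra"]] - best_single), 0.05)
  expect_lt(abs(acc[["concat_pcs"]] - best_single), 0.05)
})

test_that("confusion matrices in each run sum to the per-class test counts", {
  report <- separable_report()
  n_test <- report$config$n_per_class * (1 - report$config$split_fraction)
  for (cm in report$runs[[1]]$confusions) {
    expect_equal(unname(rowSums(cm)), rep(n_test, 9), ignore_attr = TRUE)
  }
})
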