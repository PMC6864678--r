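#' Subtract the background row
#'
#' Removes the no-LED background frame (row 8) from each of the seven
#' LED-excited frames. Negative values are permitted; smoothing and
#' normalization follow in the pipeline.
#'
#' @param raw A [raw_measurement()] (or an 8-row matrix).
#' @return 7 x n matrix of background-corrected spectra on the full grid.
#' @export
subtract_background <- function(raw) {
  rows <- if (inherits(raw, "raw_measurement")) raw$rows else raw
  if (!is.matrix(rows) || nrow(rows) != 8L) {
    stop("a raw measurement must have exactly 8 rows (7 LED frames + background)")
  }
  sweep(rows[1:7, , drop = FALSE], 2, rows[8, ], "-")
}

#' Savitzky--Golay smoothing
#'
#' Sliding-window least-squares polynomial smoothing (the classical
#' Savitzky--Golay filter): each point is replaced by the value at the window
#' center of the degree-`poly_order` polynomial fitted to the surrounding
#' `window_length` points. A degree-p filter reproduces polynomial signals of
#' degree <= p exactly. Backed by [signal::sgolayfilt()]; at the two edges the
#' polynomial is fitted to the nearest full-length window and evaluated
#' off-center (the edge points lie outside the 500-900 nm analysis window on
#' the default grid, so the edge policy never reaches the classifier).
#'
#' @param spectrum Numeric vector.
#' @param window_length Odd window size > `poly_order` (points). Default 11.
#' @param poly_order Polynomial degree. Default 2 (a 2nd-order filter).
#' @return Smoothed vector of the same length.
#' @export
smooth_sg <- function(spectrum, window_length = 11, poly_order = 2) {
  if (window_length %% 2 != 1) stop("window_length must be odd")
  if (window_length <= poly_order) stop("window_length must exceed poly_order")
  if (length(spectrum) < window_length) {
    stop("spectrum shorter than the smoothing window")
  }
  as.numeric(signal::sgolayfilt(spectrum, p = poly_order, n = window_length))
}

#' Normalize to the red chlorophyll peak
#'
#' Divides a spectrum by its maximum over the closed 650-700 nm region, where
#' the first (red) chlorophyll-a peak lies, so the peak amplitude becomes 1
#' and the far-red amplitude becomes the far-red/red ratio.
#'
#' @param spectrum Full-grid numeric vector.
#' @param grid The [wavelength_grid()] it is sampled on.
#' @param id Optional measurement identifier, used in the error message for
#'   degenerate spectra.
#' @return Normalized spectrum.
#' @export
normalize_to_chl_peak <- function(spectrum, grid, id = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  idx <- which(grid$wavelengths >= 650 - 1e-9 & grid$wavelengths <= 700 + 1e-9)
  m <- max(spectrum[idx])
  if (!is.finite(m) || m <= 0) {
    stop(
      "degenerate spectrum", if (!is.null(id)) paste0(" (", id, ")"),
      ": non-positive maximum in the 650-700 nm normalization region"
    )
  }
  spectrum / m
}

#' Truncate to the 500-900 nm analysis window
#'
#' Keeps exactly the 837 samples with wavelength in \[500, 900\] nm; below
#' 500 nm the signal is dominated by scattered LED light and above 900 nm by
#' noise.
#'
#' @param spectrum Full-grid numeric vector.
#' @param grid The [wavelength_grid()].
#' @return Numeric vector of length 837, order preserved.
#' @export
truncate_to_window <- function(spectrum, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(grid$window_idx) != 837L) {
    stop("grid analysis window must hold exactly 837 points")
  }
  spectrum[grid$window_idx]
}

#' Pre-process one measurement into a 7 x 837 matrix
#'
#' The full chain, in order: background subtraction, Savitzky--Golay
#' smoothing, per-row normalization to the 650-700 nm chlorophyll peak, and
#' truncation to the 500-900 nm window. The 8 acquired rows become the 7 rows
#' of the excitation--emission matrix fed to the classifiers.
#'
#' @param raw A [raw_measurement()].
#' @param window_length,poly_order Savitzky--Golay parameters, see
#'   [smooth_sg()].
#' @return An object of class `processed_matrix`: a 7 x 837 numeric matrix
#'   with attributes `wavelengths` (the 837 window wavelengths) and `label`.
#' @export
preprocess_measurement <- function(raw, window_length = 11, poly_order = 2) {
  stopifnot(inherits(raw, "raw_measurement"))
  grid <- raw$grid
  corrected <- subtract_background(raw)
  out <- matrix(0, nrow = 7L, ncol = length(grid$window_idx))
  for (r in 1:7) {
    s <- smooth_sg(corrected[r, ], window_length, poly_order)
    s <- normalize_to_chl_peak(s, grid, id = paste0(raw$label, "/LED", r))
    out[r, ] <- truncate_to_window(s, grid)
  }
  rownames(out) <- paste0("LED", 1:7)
  structure(out,
    wavelengths = grid$wavelengths[grid$window_idx],
    label = raw$label,
    class = c("processed_matrix", "matrix", "array")
  )
}

#' Pre-process a whole raw dataset
#'
#' @param dataset A `raw_dataset` from [generate_dataset()] or
#'   [read_dataset_csv()].
#' @param window_length,poly_order Savitzky--Golay parameters.
#' @return An object of class `processed_dataset`: list with `matrices` (list
#'   of [preprocess_measurement()] outputs), `labels` and `wavelengths`.
#' @export
preprocess_dataset <- function(dataset, window_length = 11, poly_order = 2) {
  stopifnot(inherits(dataset, "raw_dataset"))
  matrices <- lapply(dataset$measurements, preprocess_measurement,
                     window_length = window_length, poly_order = poly_order)
  structure(
    list(
      matrices = matrices,
      labels = dataset$labels,
      wavelengths = attr(matrices[[1]], "wavelengths")
    ),
    class = "processed_dataset"
  )
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat(sprintf(
    "<processed_dataset> %d matrices of 7 x %d (%d classes)\n",
    length(x$matrices), ncol(x$matrices[[1]]), nlevels(x$labels)
  ))
  invisible(x)
}

#' Stratified train/test split
#'
#' Random stratified split: within every class, `round(fraction * n_class)`
#' matrices go to the training set and the remainder to the test set.
#' Deterministic given `seed`.
#'
#' @param processed A `processed_dataset`.
#' @param fraction Training fraction (default 0.5, the 50/50 protocol).
#' @param seed Integer seed for the stratified shuffle.
#' @return List with `train` and `test`, each a `processed_dataset`.
#' @export
split_dataset <- function(processed, fraction = 0.5, seed = 1) {
  stopifnot(inherits(processed, "processed_dataset"),
            fraction > 0, fraction < 1)
  labels <- processed$labels
  counts <- table(labels)
  n_train <- round(as.numeric(counts) * fraction)
  if (any(n_train < 1) || any(as.numeric(counts) - n_train < 1)) {
    stop("stratified split impossible: a class would have an empty train or test set")
  }
  train_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (j in seq_along(counts)) {
      idx <- which(labels == names(counts)[j])
      train_idx <- c(train_idx, sample(idx, n_train[j]))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  subset_pd <- function(idx) {
    structure(
      list(
        matrices = processed$matrices[idx],
        labels = factor(labels[idx], levels = levels(labels)),
        wavelengths = processed$wavelengths
      ),
      class = "processed_dataset"
    )
  }
  list(train = subset_pd(train_idx), test = subset_pd(test_idx))
}

#' Feature matrix view of a processed dataset
#'
#' Extracts per-measurement feature vectors: either one LED row (837
#' features) or the whole matrix flattened row-major, LED1 block first
#' (7 x 837 = 5859 features).
#'
#' @param processed A `processed_dataset`.
#' @param led LED channel 1-7, or `NULL` for the flattened matrix.
#' @return Numeric matrix, one row per measurement.
#' @export
as_feature_matrix <- function(processed, led = NULL) {
  stopifnot(inherits(processed, "processed_dataset"))
  if (is.null(led)) {
    t(vapply(processed$matrices, function(m) as.vector(t(m)),
             numeric(7L * ncol(processed$matrices[[1]]))))
  } else {
    stopifnot(led %in% 1:7)
    t(vapply(processed$matrices, function(m) m[led, ],
             numeric(ncol(processed$matrices[[1]]))))
  }
}
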