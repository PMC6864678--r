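#' Write one measurement in the spectral CSV dialect
#'
#' First column `wavelength_nm` (5 decimals), then the 8 acquisition rows as
#' columns `LED1`...`LED7`, `BACKGROUND`; one file per measurement.
#'
#' @param measurement A [raw_measurement()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(measurement, path) {
  stopifnot(inherits(measurement, "raw_measurement"))
  df <- data.table::data.table(
    wavelength_nm = sprintf("%.5f", measurement$grid$wavelengths)
  )
  for (r in 1:8) df[[rownames(measurement$rows)[r]]] <- measurement$rows[r, ]
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read one measurement from the spectral CSV dialect
#'
#' Wavelengths in the file are snapped to the supplied grid (they are written
#' with 5 decimals) and must agree with it to within 1e-4 nm.
#'
#' @param path CSV file written by [write_measurement_csv()].
#' @param grid The [wavelength_grid()] the file is expected to be on.
#' @param label Tea class label to attach.
#' @return A [raw_measurement()].
#' @export
read_measurement_csv <- function(path, grid = wavelength_grid(), label = NA) {
  df <- data.table::fread(path)
  expected <- c("wavelength_nm", paste0("LED", 1:7), "BACKGROUND")
  if (!identical(names(df), expected)) {
    stop("not a spectral CSV: expected columns ", paste(expected, collapse = ", "))
  }
  wl <- as.numeric(df$wavelength_nm)
  if (length(wl) != length(grid$wavelengths) ||
      max(abs(wl - grid$wavelengths)) > 1e-4) {
    stop("wavelength axis of ", path, " does not match the supplied grid")
  }
  rows <- t(as.matrix(df[, -1]))
  raw_measurement(rows, grid, label)
}

#' Write a raw dataset as a CSV directory with a JSON manifest
#'
#' One spectral CSV per measurement plus `manifest.json` recording files,
#' labels, seed, overlap and the grid parameters.
#'
#' @param dataset A `raw_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "raw_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("meas_%04d.csv", seq_along(dataset$measurements))
  for (i in seq_along(dataset$measurements)) {
    write_measurement_csv(dataset$measurements[[i]], file.path(dir, files[i]))
  }
  grid <- dataset$measurements[[1]]$grid
  manifest <- list(
    files = files,
    labels = as.character(dataset$labels),
    label_levels = levels(dataset$labels),
    seed = dataset$seed,
    overlap = dataset$overlap,
    grid = list(start_nm = grid$start_nm, end_nm = grid$end_nm,
                step_nm = grid$step_nm)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a raw dataset from a CSV directory
#'
#' @param dir Directory written by [write_dataset_csv()].
#' @return A `raw_dataset`.
#' @export
read_dataset_csv <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(manifest_path)
  grid <- wavelength_grid(manifest$grid$start_nm,
                          manifest$grid$end_nm + manifest$grid$step_nm / 2,
                          manifest$grid$step_nm)
  measurements <- Map(function(f, l) {
    read_measurement_csv(file.path(dir, f), grid, l)
  }, manifest$files, manifest$labels)
  names(measurements) <- NULL
  structure(
    list(
      measurements = measurements,
      labels = factor(manifest$labels, levels = manifest$label_levels),
      seed = manifest$seed, overlap = manifest$overlap
    ),
    class = "raw_dataset"
  )
}

#' Write a processed matrix as CSV
#'
#' 7 rows (LED1...LED7) by 837 columns; the header row carries the window
#' wavelengths.
#'
#' @param processed A `processed_matrix` from [preprocess_measurement()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_processed_csv <- function(processed, path) {
  stopifnot(inherits(processed, "processed_matrix"))
  m <- unclass(processed)
  dt <- data.table::as.data.table(cbind(row = rownames(m), as.data.frame(m)))
  names(dt) <- c("row", sprintf("%.5f", attr(processed, "wavelengths")))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write a processed dataset as a CSV directory with a JSON manifest
#'
#' @param processed A `processed_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_processed_dataset_csv <- function(processed, dir) {
  stopifnot(inherits(processed, "processed_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("matrix_%04d.csv", seq_along(processed$matrices))
  for (i in seq_along(processed$matrices)) {
    write_processed_csv(processed$matrices[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    files = files,
    labels = as.character(processed$labels),
    label_levels = levels(processed$labels),
    wavelengths = processed$wavelengths
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a processed dataset from a CSV directory
#'
#' @param dir Directory written by [write_processed_dataset_csv()].
#' @return A `processed_dataset`.
#' @export
read_processed_dataset_csv <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  wavelengths <- as.numeric(manifest$wavelengths)
  matrices <- Map(function(f, l) {
    # header cells are numeric wavelengths, so auto-detection must be overridden
    dt <- data.table::fread(file.path(dir, f), header = TRUE)
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt$row
    dimnames(m) <- list(dt$row, NULL)
    structure(m, wavelengths = wavelengths, label = l,
              class = c("processed_matrix", "matrix", "array"))
  }, manifest$files, manifest$labels)
  names(matrices) <- NULL
  structure(
    list(
      matrices = matrices,
      labels = factor(manifest$labels, levels = manifest$label_levels),
      wavelengths = wavelengths
    ),
    class = "processed_dataset"
  )
}
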