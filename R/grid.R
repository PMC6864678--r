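#' Spectrometer wavelength grid
#'
#' Builds the uniform wavelength axis of the simulated spectrometer. The grid
#' is window-aligned: the step is chosen as 400/836 nm so that the closed
#' analysis window \[500, 900\] nm contains exactly 837 grid points, the
#' emission-axis length of the excitation--emission matrices produced by
#' [preprocess_measurement()].
#'
#' @param start_nm First wavelength of the grid (nm). Must be <= 500 and lie an
#'   integer number of steps below 500 nm so the window endpoints fall on the
#'   grid (the default 200 nm does).
#' @param end_nm Last wavelength of the grid (nm). Must be >= 900; rounded down
#'   to the nearest grid point.
#' @param step_nm Grid spacing (nm). The default `400/836` is the only spacing
#'   for which the window holds exactly 837 points on a window-aligned grid.
#'
#' @return An object of class `wavelength_grid`: a list with elements
#'   `start_nm`, `end_nm`, `step_nm`, `wavelengths` (the full axis),
#'   and `window_idx` (indices of the 837 points with wavelength in
#'   \[500, 900\] nm).
#' @examples
#' g <- wavelength_grid()
#' length(g$window_idx)         # 837
#' range(g$wavelengths[g$window_idx])
#' @export
wavelength_grid <- function(start_nm = 200, end_nm = 1100, step_nm = 400 / 836) {
  if (start_nm > 500 || end_nm < 900) {
    stop("grid must cover the [500, 900] nm analysis window (start_nm <= 500, end_nm >= 900)")
  }
  k0 <- (500 - start_nm) / step_nm
  if (abs(k0 - round(k0)) > 1e-9) {
    stop("start_nm must be an integer number of steps below 500 nm (window-aligned grid)")
  }
  n <- floor((end_nm - start_nm) / step_nm + 1e-9) + 1L
  wl <- start_nm + step_nm * (seq_len(n) - 1L)
  window_idx <- which(wl >= 500 - 1e-9 & wl <= 900 + 1e-9)
  if (length(window_idx) != 837L) {
    stop(sprintf(
      "window [500, 900] nm holds %d grid points, expected 837; use step_nm = 400/836",
      length(window_idx)
    ))
  }
  structure(
    list(
      start_nm = start_nm, end_nm = wl[n], step_nm = step_nm,
      wavelengths = wl, window_idx = window_idx
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %.5g-%.5g nm, step %.5f nm, %d points (%d in [500, 900] nm)\n",
    x$start_nm, x$end_nm, x$step_nm, length(x$wavelengths), length(x$window_idx)
  ))
  invisible(x)
}

#' Index of the grid point nearest a wavelength
#'
#' @param grid A [wavelength_grid()].
#' @param nm Wavelength(s) in nm.
#' @return Integer index (or vector of indices) into `grid$wavelengths`.
#' @export
nearest_index <- function(grid, nm) {
  stopifnot(inherits(grid, "wavelength_grid"))
  idx <- round((nm - grid$start_nm) / grid$step_nm) + 1L
  pmin(pmax(as.integer(idx), 1L), length(grid$wavelengths))
}
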