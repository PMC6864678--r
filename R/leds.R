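#' LED excitation profile
#'
#' One narrow-band excitation LED, modelled with a Gaussian line-shape. The
#' instrument uses UV-to-blue LEDs whose spectral wings must stay below
#' 500 nm, where leaf fluorescence begins; with the default 15 nm FWHM every
#' default LED emits < 1% of its peak at 500 nm.
#'
#' @param center_nm Central wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm).
#' @param peak_intensity Peak relative radiant intensity (arbitrary units).
#' @return An object of class `led_profile`.
#' @seealso [default_led_profiles()], [led_emission()]
#' @export
led_profile <- function(center_nm, fwhm_nm = 15, peak_intensity = 1) {
  stopifnot(fwhm_nm > 0, peak_intensity >= 0)
  structure(
    list(center_nm = center_nm, fwhm_nm = fwhm_nm, peak_intensity = peak_intensity),
    class = "led_profile"
  )
}

#' The seven excitation LEDs of the instrument
#'
#' Central wavelengths 371, 381, 394, 404, 412, 423 and 431 nm, as mounted in
#' the acquisition head. Channel 1 (371 nm, UV-A) is the one that efficiently
#' excites the green-orange emission band; all seven excite chlorophyll-a.
#'
#' @param fwhm_nm FWHM applied to every LED (nm).
#' @return List of 7 `led_profile` objects, in channel order.
#' @export
default_led_profiles <- function(fwhm_nm = 15) {
  centers <- c(371, 381, 394, 404, 412, 423, 431)
  lapply(centers, led_profile, fwhm_nm = fwhm_nm)
}

#' Evaluate an LED emission spectrum
#'
#' Gaussian line-shape `peak * exp(-(wl - center)^2 / (2 * sd^2))` with
#' `sd = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param led An `led_profile`.
#' @param wavelengths_nm Wavelengths at which to evaluate (nm).
#' @return Numeric vector of relative intensities.
#' @export
led_emission <- function(led, wavelengths_nm) {
  stopifnot(inherits(led, "led_profile"))
  sd <- led$fwhm_nm / (2 * sqrt(2 * log(2)))
  led$peak_intensity * exp(-(wavelengths_nm - led$center_nm)^2 / (2 * sd^2))
}

#' Fluorophore emission band
#'
#' A Gaussian emission band of the leaf. The defaults used by the generator
#' are the broad green-orange band (center 540 nm), the red chlorophyll-a
#' band (680 nm) and the far-red chlorophyll-a band (740 nm).
#'
#' @param name Band label.
#' @param center_nm Emission maximum (nm).
#' @param width_nm Band standard deviation (nm).
#' @return An object of class `fluorophore_band`.
#' @export
fluorophore_band <- function(name, center_nm, width_nm) {
  stopifnot(width_nm > 0)
  structure(
    list(name = name, center_nm = center_nm, width_nm = width_nm),
    class = "fluorophore_band"
  )
}

#' Default emission bands of tea-leaf fluorescence
#'
#' @return Named list of three `fluorophore_band` objects:
#'   `green_orange` (540 nm, sd 35 nm), `chl_red` (680 nm, sd 11 nm) and
#'   `chl_far_red` (740 nm, sd 18 nm).
#' @export
default_bands <- function() {
  list(
    green_orange = fluorophore_band("green_orange", 540, 35),
    chl_red      = fluorophore_band("chl_red", 680, 11),
    chl_far_red  = fluorophore_band("chl_far_red", 740, 18)
  )
}

#' Evaluate a fluorophore band line-shape (unit peak)
#'
#' @param band A `fluorophore_band`.
#' @param wavelengths_nm Wavelengths (nm).
#' @return Numeric vector, 1 at the band center.
#' @export
band_lineshape <- function(band, wavelengths_nm) {
  stopifnot(inherits(band, "fluorophore_band"))
  exp(-(wavelengths_nm - band$center_nm)^2 / (2 * band$width_nm^2))
}
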