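#' Tea class generator profile
#'
#' Generative parameters for one tea class. Band amplitudes are expressed
#' relative to the red chlorophyll-a peak (whose amplitude is fixed at 1), so
#' `band_mean_amplitude["chl_far_red"]` is the class-mean far-red/red ratio --
#' the quantity whose >0.6 / <0.6 split separates green/white from black teas
#' after normalization. The excitation-efficiency map is derived from three
#' physical parameters:
#'
#' * `go_opt_nm`, `go_sigma_nm` -- excitation optimum and width of the
#'   green-orange band. With optima near 368 nm and widths of a few nm, LED 1
#'   (371 nm) excites the band strongly while LEDs 2-7 barely do.
#' * `chl_opt_nm` -- chlorophyll-a (Soret) absorption optimum, shared by the
#'   red and far-red bands; broad (sd 60 nm), so all seven LEDs excite
#'   chlorophyll.
#' * `reabs_slope` -- a small class-specific re-absorption slope: the
#'   far-red/red fluorescence ratio of leaf tissue varies weakly with
#'   excitation wavelength (penetration depth and re-absorption of the red
#'   band), modelled as `eff_far_red = eff_chl * (1 + reabs_slope *
#'   (center - 400)/100)`, capped to \[0, 1\].
#'
#' Emission shape also carries class identity: the center and width of the
#' green-orange band and the width of the far-red band differ between teas
#' (different fluorophore mixtures and re-absorption), so a class is
#' characterized by band shape as well as by amplitude. The two chlorophyll
#' amplitudes are drawn with correlated logs (`chl_corr`): both bands emit
#' from the same fluorophore pool, so their common concentration fluctuates
#' together and the far-red/red ratio varies less than independent draws
#' would imply.
#'
#' @param label Class label (one of the nine tea classes).
#' @param band_mean_amplitude Named numeric: mean amplitude per band
#'   (`green_orange`, `chl_red`, `chl_far_red`), relative to the red peak.
#' @param band_cv Named numeric: per-band coefficient of variation of the
#'   measurement-to-measurement lognormal amplitude draws.
#' @param go_opt_nm,go_sigma_nm,chl_opt_nm,reabs_slope Physical parameters,
#'   see Details.
#' @param go_center_nm,go_width_nm Emission center and standard deviation of
#'   the class's green-orange band (nm); center must lie in \[500, 600\].
#' @param fr_width_nm Emission standard deviation of the far-red band (nm).
#' @param chl_corr Correlation of the log-amplitude draws of the red and
#'   far-red chlorophyll bands (default 0.9).
#' @param leds LED profiles used to tabulate the efficiency map.
#' @return An object of class `tea_class_profile` with fields `label`,
#'   `band_mean_amplitude`, `band_cv`, `bands` (the class's
#'   [fluorophore_band()] objects) and `excitation_efficiency`
#'   (a 3 x 7 matrix, bands x LED channels, values in \[0, 1\]).
#' @export
tea_class_profile <- function(label, band_mean_amplitude, band_cv,
                              go_opt_nm = 368, go_sigma_nm = 7,
                              chl_opt_nm = 430, reabs_slope = 0,
                              go_center_nm = 540, go_width_nm = 35,
                              fr_width_nm = 18, chl_corr = 0.9,
                              leds = default_led_profiles()) {
  bands <- c("green_orange", "chl_red", "chl_far_red")
  stopifnot(
    all(bands %in% names(band_mean_amplitude)),
    all(bands %in% names(band_cv)),
    all(band_mean_amplitude >= 0), all(band_cv >= 0),
    go_center_nm >= 500, go_center_nm <= 600,
    chl_corr >= -1, chl_corr <= 1,
    length(leds) == 7L
  )
  centers <- vapply(leds, function(l) l$center_nm, numeric(1))
  eff_go  <- exp(-(centers - go_opt_nm)^2 / (2 * go_sigma_nm^2))
  # chlorophyll efficiency scaled to 0.9 so the re-absorption factor never
  # saturates the [0, 1] bound (which would flatten the cross-LED slope)
  eff_chl <- 0.9 * exp(-(centers - chl_opt_nm)^2 / (2 * 60^2))
  eff_fr  <- pmin(1, pmax(0, eff_chl * (1 + reabs_slope * (centers - 400) / 100)))
  eff <- rbind(green_orange = eff_go, chl_red = eff_chl, chl_far_red = eff_fr)
  colnames(eff) <- paste0("LED", seq_len(7))
  structure(
    list(
      label = label,
      band_mean_amplitude = band_mean_amplitude[bands],
      band_cv = band_cv[bands],
      bands = list(
        green_orange = fluorophore_band("green_orange", go_center_nm, go_width_nm),
        chl_red      = fluorophore_band("chl_red", 680, 11),
        chl_far_red  = fluorophore_band("chl_far_red", 740, fr_width_nm)
      ),
      excitation_efficiency = eff,
      go_opt_nm = go_opt_nm, go_sigma_nm = go_sigma_nm,
      chl_opt_nm = chl_opt_nm, reabs_slope = reabs_slope,
      chl_corr = chl_corr
    ),
    class = "tea_class_profile"
  )
}

#' The nine class labels
#'
#' Six green teas, one white tea and two black teas, in the fixed order used
#' throughout the package.
#' @return Character vector of length 9.
#' @export
tea_class_labels <- function() {
  c("G-LJ1", "G-LJ2", "G-LJ3", "W-MC", "G-V", "G-HM", "B-KM", "B-L", "G-WNZ")
}

#' Default generator profiles for the nine tea classes
#'
#' Calibrated so that, after pre-processing, the class-mean normalized
#' far-red amplitude exceeds 0.6 for the six green classes and the white tea
#' and falls below 0.6 for both black teas (fermentation degrades
#' chlorophyll); the green-orange band is strongest for G-LJ2 and elevated
#' for G-LJ1, G-LJ3 and B-KM; and G-HM (green) and B-L (black) sit on either
#' side of, and close to, the 0.6 boundary, so the two classes overlap under
#' measurement fluctuation.
#'
#' @param overlap Class-overlap dial in \[0, 1\]. Scales the per-band
#'   amplitude coefficients of variation (base 0.15). At 0 the generator is
#'   deterministic up to detector noise and every classifier separates the
#'   classes; at 1 (the committed calibrated regime) amplitude fluctuation
#'   makes neighbouring classes overlap in any single spectral feature.
#' @param leds LED profiles used to tabulate efficiency maps.
#' @return List of 9 `tea_class_profile` objects, in [tea_class_labels()]
#'   order.
#' @export
default_class_profiles <- function(overlap = 1, leds = default_led_profiles()) {
  stopifnot(overlap >= 0)
  pars <- data.frame(
    label     = tea_class_labels(),
    far_red   = c(0.78, 0.82, 0.75, 0.66, 0.72, 0.63, 0.45, 0.55, 0.69),
    go        = c(0.42, 0.58, 0.40, 0.18, 0.22, 0.15, 0.44, 0.14, 0.20),
    go_opt    = c(367, 368, 369, 368, 366, 368, 370, 367, 369),
    go_sigma  = c(7.0, 7.5, 6.5, 7.0, 7.0, 7.0, 7.5, 6.5, 7.5),
    go_center = c(536, 545, 533, 528, 550, 541, 555, 537, 531),
    go_width  = c(34, 36, 32, 33, 37, 35, 38, 34, 36),
    fr_width  = c(17, 20, 14.5, 18.5, 16, 19, 14, 21.5, 15),
    reabs     = c(0.06, 0.12, 0.00, -0.06, 0.03, -0.12, -0.15, -0.09, 0.09),
    stringsAsFactors = FALSE
  )
  cv <- 0.15 * overlap
  lapply(seq_len(nrow(pars)), function(i) {
    tea_class_profile(
      label = pars$label[i],
      band_mean_amplitude = c(
        green_orange = pars$go[i], chl_red = 1, chl_far_red = pars$far_red[i]
      ),
      band_cv = c(green_orange = cv, chl_red = cv, chl_far_red = cv),
      go_opt_nm = pars$go_opt[i], go_sigma_nm = pars$go_sigma[i],
      go_center_nm = pars$go_center[i], go_width_nm = pars$go_width[i],
      fr_width_nm = pars$fr_width[i],
      reabs_slope = pars$reabs[i],
      leds = leds
    )
  })
}

#' Far-red/red amplitude ratio of a class profile
#'
#' The generator-side mean of the quantity displayed at 740 nm after
#' chlorophyll-peak normalization.
#' @param profile A `tea_class_profile`.
#' @return Numeric scalar.
#' @export
far_red_ratio <- function(profile) {
  stopifnot(inherits(profile, "tea_class_profile"))
  unname(profile$band_mean_amplitude["chl_far_red"] /
    profile$band_mean_amplitude["chl_red"])
}
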