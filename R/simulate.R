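#' Detector and background noise model
#'
#' Additive detector noise, a fixed smooth background shape, and a smooth
#' per-row baseline drift. The background shape (a slowly varying low-order
#' polynomial plus constant level) is recorded identically in distribution
#' in all 8 rows of a measurement; subtracting the background row therefore
#' removes it up to the drift and detector-noise terms. The drift models the
#' residual difference between rows acquired at different instants (LED
#' frames vs the background frame): an independent smooth low-order curve per
#' row, drawn on a cubic Legendre basis.
#'
#' @param additive_sd Standard deviation of zero-mean Gaussian detector noise
#'   (counts). Default 10 = 1% of the red chlorophyll peak at the default
#'   signal scale.
#' @param background_level Constant background offset (counts).
#' @param background_shape Function of wavelength (nm) returning the smooth
#'   nonnegative structured part of the background (counts), added to
#'   `background_level`.
#' @param drift_sd Amplitude (counts) of the per-row smooth baseline drift;
#'   0 disables drift.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 10, background_level = 100,
                        background_shape = NULL, drift_sd = 0) {
  stopifnot(additive_sd >= 0, background_level >= 0, drift_sd >= 0)
  if (is.null(background_shape)) {
    # gentle broad hump peaking near the middle of the spectrometer range
    background_shape <- function(wl) 30 * exp(-(wl - 650)^2 / (2 * 250^2))
  }
  stopifnot(is.function(background_shape))
  structure(
    list(
      additive_sd = additive_sd, background_level = background_level,
      background_shape = background_shape, drift_sd = drift_sd
    ),
    class = "noise_model"
  )
}

#' Default noise model of the calibrated regime
#'
#' @param overlap Class-overlap dial, as in [default_class_profiles()];
#'   scales the baseline-drift amplitude (base 17 counts).
#' @return A [noise_model()].
#' @export
default_noise_model <- function(overlap = 1) {
  noise_model(additive_sd = 10, background_level = 100, drift_sd = 17 * overlap)
}

# First four Legendre polynomials on u in [-1, 1], as columns.
legendre_basis <- function(u) {
  cbind(1, u, 0.5 * (3 * u^2 - 1), 0.5 * (5 * u^3 - 3 * u))
}

#' One raw acquisition
#'
#' @param rows 8 x n matrix of intensities in counts: rows 1-7 are the
#'   LED-excited frames in channel order, row 8 the background frame.
#' @param grid The [wavelength_grid()] the columns are sampled on.
#' @param label Tea class label.
#' @return An object of class `raw_measurement`.
#' @export
raw_measurement <- function(rows, grid, label) {
  stopifnot(
    inherits(grid, "wavelength_grid"),
    is.matrix(rows), nrow(rows) == 8L,
    ncol(rows) == length(grid$wavelengths),
    all(is.finite(rows)), all(rows >= 0)
  )
  rownames(rows) <- c(paste0("LED", 1:7), "BACKGROUND")
  structure(list(rows = rows, grid = grid, label = label),
            class = "raw_measurement")
}

#' @export
print.raw_measurement <- function(x, ...) {
  cat(sprintf(
    "<raw_measurement> class %s, 8 x %d counts on %.5g-%.5g nm\n",
    x$label, ncol(x$rows), x$grid$start_nm, x$grid$end_nm
  ))
  invisible(x)
}

#' Simulate one multi-channel acquisition
#'
#' Forward model of the sequential acquisition: for each LED channel r the
#' recorded spectrum is
#'
#' background + drift_r + scale * sum_b A_b * eff(b, r) * band_b(wl)
#'            + scatter * LED_r(wl) + detector noise,
#'
#' clipped at zero counts; the 8th row records background + drift + noise
#' with no LED on. The per-band amplitudes `A_b` are one lognormal draw each
#' per measurement (mean = the profile's mean amplitude, CV = the profile's
#' band CV), shared across the 7 LED rows -- leaf-to-leaf variability, not
#' frame noise. The scatter term is elastically scattered excitation light,
#' confined below 500 nm by the LED wing constraint and discarded by the
#' 500-900 nm truncation.
#'
#' @param profile A [tea_class_profile()].
#' @param leds List of exactly 7 [led_profile()] objects.
#' @param grid A [wavelength_grid()].
#' @param noise A [noise_model()].
#' @param signal_scale Counts corresponding to unit band amplitude at unit
#'   excitation efficiency (default 1000).
#' @param scatter_scale Peak counts of the scattered-excitation term per unit
#'   LED peak intensity (default 2000).
#' @param seed Optional integer; if given, the draw is made reproducible with
#'   a local RNG seed, otherwise the current RNG stream is consumed.
#' @return A [raw_measurement()].
#' @export
simulate_measurement <- function(profile, leds = default_led_profiles(),
                                 grid = wavelength_grid(),
                                 noise = default_noise_model(),
                                 signal_scale = 1000, scatter_scale = 2000,
                                 seed = NULL) {
  stopifnot(
    inherits(profile, "tea_class_profile"),
    inherits(grid, "wavelength_grid"),
    inherits(noise, "noise_model")
  )
  if (length(leds) != 7L) {
    stop("exactly 7 LED profiles are required (got ", length(leds), ")")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_measurement(
      profile, leds, grid, noise, signal_scale, scatter_scale, seed = NULL
    )))
  }
  wl <- grid$wavelengths
  n <- length(wl)
  bands <- if (!is.null(profile$bands)) profile$bands else default_bands()
  band_names <- names(bands)

  # One lognormal amplitude draw per band, shared across the 7 LED rows.
  # The two chlorophyll bands emit from the same fluorophore pool, so their
  # log-amplitudes are drawn with correlation chl_corr; the green-orange
  # band is independent.
  sdlog <- sqrt(log(1 + profile$band_cv^2))
  rho <- if (!is.null(profile$chl_corr)) profile$chl_corr else 0
  z <- stats::rnorm(3)  # green_orange, chl_red, chl_far_red (standard normals)
  z[3] <- rho * z[2] + sqrt(1 - rho^2) * z[3]
  amp <- vapply(seq_along(band_names), function(j) {
    b <- band_names[j]
    mu <- profile$band_mean_amplitude[[b]]
    s <- sdlog[[b]]
    if (mu == 0 || s == 0) return(mu)
    mu * exp(-s^2 / 2 + s * z[j])
  }, numeric(1))
  names(amp) <- band_names

  shapes <- vapply(band_names, function(b) band_lineshape(bands[[b]], wl),
                   numeric(n))                      # n x 3
  bg <- noise$background_level + noise$background_shape(wl)
  u <- 2 * (wl - wl[1]) / (wl[n] - wl[1]) - 1
  P <- legendre_basis(u)                            # n x 4

  rows <- matrix(0, nrow = 8L, ncol = n)
  for (r in 1:8) {
    drift <- if (noise$drift_sd > 0) {
      drop(P %*% stats::rnorm(4)) * noise$drift_sd
    } else 0
    sig <- 0
    if (r <= 7) {
      eff <- profile$excitation_efficiency[band_names, r]
      sig <- signal_scale * drop(shapes %*% (amp * eff)) +
        scatter_scale * led_emission(leds[[r]], wl)
    }
    eps <- if (noise$additive_sd > 0) stats::rnorm(n, sd = noise$additive_sd) else 0
    rows[r, ] <- pmax(0, bg + drift + sig + eps)
  }
  raw_measurement(rows, grid, profile$label)
}

#' Generate a full synthetic dataset
#'
#' `n_per_class` acquisitions for each of the nine tea classes, in class-major
#' order, fully reproducible from `seed`.
#'
#' @param n_per_class Measurements per class (>= 2, so a split is possible).
#' @param seed Integer RNG seed.
#' @param overlap Class-overlap dial passed to [default_class_profiles()] and
#'   [default_noise_model()]; ignored for components passed explicitly.
#' @param profiles,leds,grid,noise Optional explicit generator components.
#' @param signal_scale,scatter_scale As in [simulate_measurement()].
#' @return An object of class `raw_dataset`: list with `measurements` (list of
#'   [raw_measurement()]), `labels` (factor in [tea_class_labels()] order),
#'   `seed` and `overlap`.
#' @export
generate_dataset <- function(n_per_class, seed, overlap = 1,
                             profiles = NULL, leds = default_led_profiles(),
                             grid = wavelength_grid(), noise = NULL,
                             signal_scale = 1000, scatter_scale = 2000) {
  if (n_per_class < 2) stop("n_per_class must be >= 2 (train/test split impossible)")
  if (is.null(profiles)) profiles <- default_class_profiles(overlap, leds = leds)
  if (is.null(noise)) noise <- default_noise_model(overlap)
  labels <- vapply(profiles, function(p) p$label, character(1))
  withr::with_seed(as.integer(seed), {
    measurements <- vector("list", length(profiles) * n_per_class)
    k <- 0L
    for (p in profiles) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        measurements[[k]] <- simulate_measurement(
          p, leds = leds, grid = grid, noise = noise,
          signal_scale = signal_scale, scatter_scale = scatter_scale
        )
      }
    }
    structure(
      list(
        measurements = measurements,
        labels = factor(rep(labels, each = n_per_class), levels = labels),
        seed = as.integer(seed), overlap = overlap
      ),
      class = "raw_dataset"
    )
  })
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf(
    "<raw_dataset> %d measurements (%d classes), seed %d, overlap %.3g\n",
    length(x$measurements), nlevels(x$labels), x$seed, x$overlap
  ))
  invisible(x)
}
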