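test_that("zero-amplitude, noise-free measurement reduces to the background shape", {
  g <- wavelength_grid()
  nm <- noise_free_model()
  m <- simulate_measurement(silent_profile(), grid = g, noise = nm,
                            scatter_scale = 0, seed = 1)
  bg <- nm$background_level + nm$background_shape(g$wavelengths)
  for (r in 1:8) expect_equal(unname(m$rows[r, ]), bg)
})

test_that("noise-free forward model peaks at the red chlorophyll band", {
  g <- wavelength_grid()
  m <- simulate_measurement(deterministic_profiles()[[1]], grid = g,
                            noise = noise_free_model(), seed = 1)
  signal <- m$rows[1, ] - m$rows[8, ]
  region <- which(g$wavelengths >= 650 & g$wavelengths <= 700)
  peak_idx <- region[which.max(signal[region])]
  # overlapping band tails can move the apex of the sum by one grid point
  expect_lte(abs(peak_idx - nearest_index(g, 680)), 1L)
})

test_that("each LED row has local maxima at the configured band centers (noise off)", {
  g <- wavelength_grid()
  profiles <- deterministic_profiles()
  m <- simulate_measurement(profiles[[2]], grid = g, noise = noise_free_model(),
                            seed = 1)
  go_center <- profiles[[2]]$bands$green_orange$center_nm
  for (r in c(1L, 4L, 7L)) {
    signal <- m$rows[r, ] - m$rows[8, ]
    # the green-orange band is only excited appreciably by LED 1
    centers <- if (r == 1L) c(go_center, 680, 740) else c(680, 740)
    for (center in centers) {
      region <- which(abs(g$wavelengths - center) <= 15)
      peak_idx <- region[which.max(signal[region])]
      # superposed band tails shift the apex by at most one 0.48 nm step
      expect_lte(abs(peak_idx - nearest_index(g, center)), 1L)
    }
  }
})

test_that("increasing a band amplitude strictly increases its center intensity", {
  g <- wavelength_grid()
  base <- deterministic_profiles()[[5]]
  raise <- function(delta) {
    amp <- base$band_mean_amplitude
    amp["chl_far_red"] <- amp["chl_far_red"] + delta
    tea_class_profile(base$label, amp, base$band_cv,
                      go_opt_nm = base$go_opt_nm, go_sigma_nm = base$go_sigma_nm,
                      reabs_slope = base$reabs_slope)
  }
  at740 <- vapply(c(0, 0.2, 0.4), function(d) {
    m <- simulate_measurement(raise(d), grid = g, noise = noise_free_model(),
                              seed = 1)
    m$rows[1, nearest_index(g, 740)]
  }, numeric(1))
  expect_true(all(diff(at740) > 0))
})

test_that("identical seeds give bit-identical measurements and datasets", {
  p <- default_class_profiles()[[3]]
  m1 <- simulate_measurement(p, seed = 31)
  m2 <- simulate_measurement(p, seed = 31)
  expect_identical(m1$rows, m2$rows)

  d1 <- generate_dataset(4, seed = 5)
  d2 <- generate_dataset(4, seed = 5)
  expect_identical(
    lapply(d1$measurements, `[[`, "rows"),
    lapply(d2$measurements, `[[`, "rows")
  )
  expect_identical(d1$labels, d2$labels)
})

test_that("generate_dataset sizes and guards", {
  d <- generate_dataset(3, seed = 1)
  expect_length(d$measurements, 27L)
  expect_equal(as.vector(table(d$labels)), rep(3L, 9))
  expect_error(generate_dataset(1, seed = 1), "n_per_class")
  expect_error(
    simulate_measurement(default_class_profiles()[[1]],
                         leds = default_led_profiles()[1:5]),
    "7 LED"
  )
})

test_that("sample mean of the far-red ratio matches the generator parameters", {
  # Monte-Carlo check against the generator's own lognormal amplitude model:
  # E[A_fr / A_red] = ratio * exp(sdlog^2 * (1 - corr)), and the LED1 row
  # carries the class's re-absorption factor.
  n <- 100
  p <- default_class_profiles()[[5]]  # G-V
  g <- wavelength_grid()
  ds <- generate_dataset(n, seed = 11, profiles = list(p),
                         noise = default_noise_model())
  pd <- preprocess_dataset(ds)
  i740 <- which.min(abs(pd$wavelengths - 740))
  vals <- vapply(pd$matrices, function(m) m[1, i740], numeric(1))

  sdlog <- sqrt(log(1 + 0.15^2))
  expected <- far_red_ratio(p) * exp(sdlog^2 * (1 - p$chl_corr)) *
    (1 + p$reabs_slope * (371 - 400) / 100)
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - expected), 3 * se + 0.01)
})
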