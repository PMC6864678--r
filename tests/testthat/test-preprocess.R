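test_that("background subtraction is exact elementwise", {
  g <- wavelength_grid()
  n <- length(g$wavelengths)
  rows <- matrix(5, 8, n)
  m <- raw_measurement(rows, g, "G-V")
  expect_equal(subtract_background(m), matrix(0, 7, n), ignore_attr = TRUE)

  rows2 <- matrix(stats::runif(8 * n), 8, n)
  rows2[8, ] <- 0
  m2 <- raw_measurement(rows2, g, "G-V")
  expect_equal(unname(subtract_background(m2)), rows2[1:7, ])

  spike <- numeric(n); spike[nearest_index(g, 680)] <- 1
  rows3 <- matrix(rep(rows2[8, ], 8), 8, n, byrow = TRUE)
  rows3 <- matrix(stats::runif(n), 8, n, byrow = TRUE)
  rows3[1, ] <- rows3[8, ] + spike
  m3 <- raw_measurement(rows3, g, "G-V")
  expect_equal(unname(subtract_background(m3)[1, ]), spike)

  expect_error(subtract_background(matrix(0, 7, n)), "8 rows")
})

test_that("Savitzky-Golay reproduces quadratics exactly and preserves constants", {
  i <- 1:80
  quad <- 0.3 * i^2 - 2 * i + 7
  expect_equal(smooth_sg(quad, 11, 2), quad)
  expect_equal(smooth_sg(rep(4.2, 50), 11, 2), rep(4.2, 50))
  expect_error(smooth_sg(quad, 10, 2), "odd")
  expect_error(smooth_sg(quad, 3, 3), "exceed")
  expect_error(smooth_sg(quad[1:5], 11, 2), "shorter")
})

test_that("Savitzky-Golay matches a brute-force local polynomial regression", {
  set.seed(42)
  x <- stats::rnorm(101)
  for (w in c(7, 11)) {
    h <- (w - 1) / 2
    sm <- smooth_sg(x, w, 2)
    oracle <- vapply(seq_along(x), function(i) {
      win <- if (i <= h) 1:w else if (i > 101 - h) (101 - w + 1):101 else (i - h):(i + h)
      fit <- stats::lm(x[win] ~ win + I(win^2))
      unname(stats::predict(fit, newdata = data.frame(win = i)))
    }, numeric(1))
    expect_lt(max(abs(sm - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("chlorophyll-peak normalization: definition, scale invariance, idempotence", {
  g <- wavelength_grid()
  x <- rep(1, length(g$wavelengths))
  x[nearest_index(g, 680)] <- 5
  nx <- normalize_to_chl_peak(x, g)
  expect_equal(max(nx[g$wavelengths >= 650 & g$wavelengths <= 700]), 1)
  expect_equal(nx, x / 5)

  set.seed(3)
  y <- abs(stats::rnorm(length(g$wavelengths))) + 0.1
  expect_equal(normalize_to_chl_peak(7.3 * y, g), normalize_to_chl_peak(y, g))
  expect_equal(normalize_to_chl_peak(normalize_to_chl_peak(y, g), g),
               normalize_to_chl_peak(y, g))
  expect_error(normalize_to_chl_peak(-y, g, id = "m17"), "m17")
})

test_that("truncation keeps exactly the 837-point window with consistent slicing", {
  g <- wavelength_grid()
  x <- seq_along(g$wavelengths)
  tr <- truncate_to_window(x, g)
  expect_length(tr, 837L)
  expect_equal(g$wavelengths[tr[1]], 500)
  expect_equal(g$wavelengths[tr[837]], 900)
  expect_equal(tr, x[g$window_idx])
})

test_that("the full pipeline yields a valid 7 x 837 matrix with unit chlorophyll peaks", {
  m <- simulate_measurement(default_class_profiles()[[4]], seed = 8)
  pm <- preprocess_measurement(m)
  expect_equal(dim(pm), c(7L, 837L))
  wl <- attr(pm, "wavelengths")
  for (r in 1:7) {
    expect_equal(max(pm[r, wl >= 650 & wl <= 700]), 1, tolerance = 1e-12)
  }
  expect_equal(attr(pm, "label"), "W-MC")
})

test_that("noise-free green-class matrix shows far-red amplitude above 0.6", {
  m <- simulate_measurement(deterministic_profiles()[[1]], # G-LJ1
                            noise = noise_free_model(), seed = 1)
  pm <- preprocess_measurement(m)
  wl <- attr(pm, "wavelengths")
  expect_gt(pm[1, which.min(abs(wl - 740))], 0.6)
})

test_that("pipeline applies normalization after smoothing and subtraction", {
  # A narrow 3-point spike survives differently if normalized before
  # smoothing: smoothing spreads the spike, lowering the 650-700 nm maximum,
  # so normalize-then-smooth leaves max < 1 while the correct order gives
  # max = 1 on the smoothed signal.
  g <- wavelength_grid()
  n <- length(g$wavelengths)
  rows <- matrix(10, 8, n)
  i680 <- nearest_index(g, 680)
  rows[1:7, i680] <- 1010
  m <- raw_measurement(rows, g, "G-V")
  pm <- preprocess_measurement(m, window_length = 11, poly_order = 2)
  wl <- attr(pm, "wavelengths")
  win <- wl >= 650 & wl <= 700
  expect_equal(max(pm[1, win]), 1, tolerance = 1e-12)
  # the wrong order (normalize raw, then smooth) would flatten the spike:
  wrong <- smooth_sg(normalize_to_chl_peak(rows[1, ] - rows[8, ], g), 11, 2)
  expect_lt(max(truncate_to_window(wrong, g)[win]), 0.5)
})

test_that("stratified split halves every class deterministically", {
  pd <- preprocess_dataset(generate_dataset(4, seed = 2))
  sp <- split_dataset(pd, fraction = 0.5, seed = 9)
  expect_equal(as.vector(table(sp$train$labels)), rep(2L, 9))
  expect_equal(as.vector(table(sp$test$labels)), rep(2L, 9))
  expect_length(intersect(
    vapply(sp$train$matrices, function(m) digest_matrix(m), character(1)),
    vapply(sp$test$matrices, function(m) digest_matrix(m), character(1))
  ), 0L)
  sp2 <- split_dataset(pd, fraction = 0.5, seed = 9)
  expect_identical(sp$train$matrices, sp2$train$matrices)
  expect_error(split_dataset(pd, fraction = 0.05, seed = 1), "impossible")
})
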