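# Shared fixtures. Heavy end-to-end runs are computed lazily and cached so
# several test files can assert on the same evaluation without re-running it.

.teafluor_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .teafluor_cache)) {
    assign(key, force(expr), envir = .teafluor_cache)
  }
  get(key, envir = .teafluor_cache)
}

# Noise-free generator components for deterministic forward-model checks.
noise_free_model <- function() noise_model(additive_sd = 0, drift_sd = 0)

silent_profile <- function(label = "G-LJ1") {
  tea_class_profile(
    label,
    band_mean_amplitude = c(green_orange = 0, chl_red = 0, chl_far_red = 0),
    band_cv = c(green_orange = 0, chl_red = 0, chl_far_red = 0)
  )
}

deterministic_profiles <- function() default_class_profiles(overlap = 0)

# The package's standard calibrated-regime comparison: 60 per class,
# 200-epoch CNN, three seeds.
calibrated_report <- function() {
  cached("calibrated_report", {
    run_full_comparison(
      comparison_config(n_per_class = 60, overlap = 1, epochs = 200,
                        seeds = c(1, 2, 3)),
      verbose = FALSE
    )
  })
}

# Separable-regime comparison (overlap dial at 0); the CNN converges fast,
# so fewer epochs suffice.
separable_report <- function() {
  cached("separable_report", {
    run_full_comparison(
      comparison_config(n_per_class = 60, overlap = 0, epochs = 100,
                        seeds = 42),
      verbose = FALSE
    )
  })
}

# 100 measurements per class under the default calibrated generator,
# pre-processed; used for the far-red calibration and score-plot checks.
calibration_dataset <- function() {
  cached("calibration_dataset", {
    preprocess_dataset(generate_dataset(100, seed = 7, overlap = 1))
  })
}

# Cheap fingerprint to compare matrix identity across collections.
digest_matrix <- function(m) {
  paste(format(c(sum(m), m[1, 1], m[7, 837], m[4, 419]), digits = 17),
        collapse = "|")
}

# Tiny CNN spec for gradient and architecture tests.
tiny_cnn_spec <- function(epochs = 5, batch_size = 1000, seed = 99, ...) {
  cnn_spec(input_rows = 3, input_cols = 20, n_filters = 2,
           filter_rows = 3, filter_cols = 5, hidden_fc = 6, n_classes = 2,
           epochs = epochs, batch_size = batch_size, seed = seed, ...)
}

tiny_inputs <- function(n, spec, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      matrix(stats::runif(spec$input_rows * spec$input_cols),
             spec$input_rows, spec$input_cols)
    })
  })
}
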