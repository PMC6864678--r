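#' Default pipeline configuration
#'
#' One structured list driving every stage of [run_pipeline()]: generator
#' scale and overlap dial, Savitzky--Golay parameters, split, kNN and PCA
#' settings, and CNN training parameters. Serializable to YAML with exact
#' round-trip via [save_config()] / [load_config()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    generator = list(n_per_class = 60L, overlap = 1, seed = 1L),
    preprocess = list(sg_window = 11L, sg_poly = 2L),
    split = list(fraction = 0.5, seed = 1L),
    knn = list(k = 5L, metric = "euclidean"),
    pca = list(per_led_pcs = default_pc_numbers(), concat_pcs = 9L),
    cnn = list(epochs = 200L, batch_size = 32L, hidden_fc = 64L,
               learning_rate = 0.1, seed = 1L),
    seeds = c(1L, 2L, 3L),
    out_dir = "teafluor-out"
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, ".", key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  chk <- function(ok, key, constraint) {
    if (!ok) stop("invalid config value for '", key, "': ", constraint)
  }
  config$generator$n_per_class <- as.integer(config$generator$n_per_class)
  chk(config$generator$n_per_class >= 2, "generator.n_per_class", "must be >= 2")
  chk(config$generator$overlap >= 0, "generator.overlap", "must be >= 0")
  config$preprocess$sg_window <- as.integer(config$preprocess$sg_window)
  chk(config$preprocess$sg_window %% 2 == 1, "preprocess.sg_window", "must be odd")
  chk(config$preprocess$sg_window > config$preprocess$sg_poly,
      "preprocess.sg_window", "must exceed preprocess.sg_poly")
  chk(config$split$fraction > 0 && config$split$fraction < 1,
      "split.fraction", "must lie in (0, 1)")
  config$knn$k <- as.integer(config$knn$k)
  chk(config$knn$k >= 1, "knn.k", "must be >= 1")
  chk(config$knn$metric %in% c("euclidean", "manhattan"),
      "knn.metric", "must be 'euclidean' or 'manhattan'")
  config$pca$per_led_pcs <- as.integer(config$pca$per_led_pcs)
  chk(length(config$pca$per_led_pcs) == 7L, "pca.per_led_pcs",
      "must give one count per LED (length 7)")
  chk(all(config$pca$per_led_pcs >= 1), "pca.per_led_pcs", "counts must be >= 1")
  config$pca$concat_pcs <- as.integer(config$pca$concat_pcs)
  for (key in c("epochs", "batch_size", "hidden_fc", "seed")) {
    config$cnn[[key]] <- as.integer(config$cnn[[key]])
    chk(config$cnn[[key]] >= 1, paste0("cnn.", key), "must be >= 1")
  }
  chk(config$cnn$learning_rate > 0, "cnn.learning_rate", "must be > 0")
  config$seeds <- as.integer(config$seeds)
  config$generator$seed <- as.integer(config$generator$seed)
  config$split$seed <- as.integer(config$split$seed)
  chk(length(config$seeds) >= 1, "seeds", "need at least one seed")
  config
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys are filled with the committed defaults; unknown keys are
#' rejected with a message naming them; values are validated (for instance
#' the Savitzky--Golay window must be odd). An empty file yields exactly
#' [default_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  validate_config(merge_config(default_config(), user))
}

#' Save a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' generate -> preprocess -> baselines -> CNN -> report, with per-stage
#' logging of seeds, sizes and durations. The comparison is repeated over
#' `config$seeds` and the report written to `out_dir` (see [write_report()]).
#' With `write_raw = TRUE` the generated raw dataset of the first seed is
#' also exported in the spectral CSV dialect under `out_dir/raw/`, and a
#' rerun with `resume = TRUE` reloads it instead of regenerating.
#'
#' @param config A configuration list from [default_config()] or
#'   [load_config()].
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @param write_raw Export the first seed's raw dataset as CSV.
#' @param resume Reuse a previously exported raw dataset if its manifest
#'   matches the config (first seed only).
#' @param verbose Log progress via [message()].
#' @return The `evaluation_report`, invisibly; side effect: report files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         write_raw = FALSE, resume = FALSE, verbose = TRUE) {
  config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cmp <- comparison_config(
    n_per_class = config$generator$n_per_class,
    overlap = config$generator$overlap,
    seeds = config$seeds,
    split_fraction = config$split$fraction,
    sg_window = config$preprocess$sg_window,
    sg_poly = config$preprocess$sg_poly,
    k = config$knn$k, metric = config$knn$metric,
    per_led_pcs = config$pca$per_led_pcs, concat_pcs = config$pca$concat_pcs,
    epochs = config$cnn$epochs, batch_size = config$cnn$batch_size,
    hidden_fc = config$cnn$hidden_fc, learning_rate = config$cnn$learning_rate
  )
  if (write_raw || resume) {
    raw_dir <- file.path(out_dir, "raw")
    manifest_path <- file.path(raw_dir, "manifest.json")
    reuse <- FALSE
    if (resume && file.exists(manifest_path)) {
      m <- jsonlite::fromJSON(manifest_path)
      reuse <- isTRUE(m$seed == config$seeds[1]) &&
        isTRUE(all.equal(m$overlap, config$generator$overlap)) &&
        length(m$files) == 9L * config$generator$n_per_class
      if (resume && !reuse) say("raw stage outputs do not match config; regenerating")
    } else if (resume && !dir.exists(raw_dir)) {
      stop("cannot resume: missing raw dataset directory ", raw_dir)
    }
    if (!reuse && write_raw) {
      say("exporting raw dataset (seed %d) to %s", config$seeds[1], raw_dir)
      ds <- generate_dataset(config$generator$n_per_class,
                             seed = config$seeds[1],
                             overlap = config$generator$overlap)
      write_dataset_csv(ds, raw_dir)
    }
  }
  report <- run_full_comparison(cmp, verbose = verbose)
  write_report(report, out_dir)
  say("pipeline finished in %.1f s; report written to %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), out_dir)
  invisible(report)
}
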