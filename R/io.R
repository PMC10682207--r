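#' Read and write spectra CSV files
#'
#' The interchange format is plain CSV: a `sample_id` column, any metadata
#' columns, and one column per wavelength named by its integer nanometre
#' value.  The reader validates numeric content and the `[0, 1]` reflectance
#' bounds (for non-derivative spectra), sorts shuffled wavelength columns
#' ascending with a warning, and rejects duplicate wavelength columns.
#'
#' @param path file path.
#' @param validate_range check reflectance bounds (disable for derivative
#'   spectra).
#' @return `read_spectra_csv()` returns a spectra tibble.
#' @export
read_spectra_csv <- function(path, validate_range = TRUE) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  wl_cols <- names(x)[is_wavelength_name(names(x))]
  for (cc in wl_cols) {
    if (!is.numeric(x[[cc]])) {
      stop(sprintf("non-numeric values in wavelength column %s", cc), call. = FALSE)
    }
  }
  x <- as_spectra(x)
  if (validate_range) {
    m <- spectra_matrix(x)
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "reflectance out of [0, 1] at row %d, wavelength %s nm (value %.4g)",
        bad[1, 1], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]
      ), call. = FALSE)
    }
  }
  x
}

#' @rdname read_spectra_csv
#' @param x a spectra tibble.
#' @param processing optional character vector of provenance lines written as
#'   `#`-prefixed header comments.
#' @export
write_spectra_csv <- function(x, path, processing = NULL) {
  x <- as_spectra(x)
  if (!is.null(processing)) {
    writeLines(paste0("# ", processing), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

config_known_keys <- c(
  "dataset", "target", "seed", "grid", "geometry", "field",
  "preprocess", "selection", "svr", "split", "outdir"
)

#' Read and validate a pipeline configuration
#'
#' YAML configuration with top-level keys `dataset` ("simulated" or "field"),
#' `target`, `seed`, `grid`, `geometry`, `field`, `preprocess`, `selection`,
#' `svr`, `split`, `outdir`.  Unknown keys raise a schema error naming the
#' key.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  if (is.null(cfg$dataset)) cfg$dataset <- "simulated"
  if (!cfg$dataset %in% c("simulated", "field")) {
    stop("dataset must be 'simulated' or 'field'", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

cfg_get <- function(cfg, key, default) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate/field-generation, preprocessing, band selection, SVR
#' fitting and evaluation, writing all artifacts (dataset CSV, summary
#' statistics, selected-band tables, the nine-model report and a run manifest)
#' to the output directory.
#'
#' @param cfg a `run_config` from [read_run_config()] (or an equivalent list).
#' @param outdir output directory (overrides `cfg$outdir`).
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_from_config <- function(cfg, outdir = NULL) {
  if (!inherits(cfg, "run_config")) {
    cfg <- structure(cfg, class = "run_config")
  }
  outdir <- outdir %||% cfg_get(cfg, "outdir", "lcc-run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg_get(cfg, "seed", 1L))

  message("stage: dataset")
  if (cfg$dataset == "simulated") {
    g <- cfg_get(cfg, "grid", list())
    grid <- parameter_grid(
      cab = cfg_get(g, "cab", c(25, 50, 5)),
      n_structure = cfg_get(g, "n_structure", c(1, 1.5, 0.5)),
      lai = cfg_get(g, "lai", c(1, 7, 1)),
      soil_scale = cfg_get(g, "soil_scale", c(0.6, 1, 0.1)),
      ala = cfg_get(g, "ala", c(0, 60, 15))
    )
    data <- simulate_dataset(grid)
    target <- cfg_get(cfg, "target", "cab")
    smooth <- FALSE
    # the printed 1569/531 split is pinned only for the full 2100-scene grid
    default_counts <- if (nrow(data) == 2100) c(1569, 531) else NULL
    split_counts <- cfg_get(cfg$split, "counts", default_counts)
  } else {
    f <- cfg_get(cfg, "field", list())
    data <- generate_field_campaign(
      n = cfg_get(f, "n", 69),
      noise = noise_model(
        multiplicative_sd = cfg_get(f, "multiplicative_sd", 0.02),
        additive_sd = cfg_get(f, "additive_sd", 0.002),
        replicates = cfg_get(f, "replicates", 5)
      ),
      seed = seed
    )
    target <- cfg_get(cfg, "target", "spad")
    smooth <- FALSE # campaign spectra are already smoothed on generation
    split_counts <- cfg_get(cfg$split, "counts", NULL)
  }
  write_spectra_csv(data, file.path(outdir, "dataset.csv"),
    processing = sprintf("dataset=%s seed=%d", cfg$dataset, seed)
  )
  readr::write_csv(
    describe_target(data[[target]]),
    file.path(outdir, "target_statistics.csv")
  )

  message("stage: experiment")
  sel <- cfg_get(cfg, "selection", list())
  svr_cfg_in <- cfg_get(cfg, "svr", list())
  config <- experiment_config(
    target = target,
    split_fraction = cfg_get(cfg$split, "fraction", 0.75),
    split_counts = split_counts,
    seed = seed, smooth = smooth,
    selection_folds = cfg_get(sel, "folds", 10),
    alpha_grid = cfg_get(sel, "alpha_grid", seq(0.01, 0.99, by = 0.01)),
    nlambda = cfg_get(sel, "nlambda", 100),
    lambda_min_ratio = cfg_get(sel, "lambda_min_ratio", 1e-4),
    svr = svr_config(
      c_grid = cfg_get(svr_cfg_in, "c_grid", 2^seq(-5, 15, by = 2)),
      gamma_grid = cfg_get(svr_cfg_in, "gamma_grid", 2^seq(-15, 3, by = 2)),
      epsilon = cfg_get(svr_cfg_in, "epsilon", 0.1),
      k_folds = cfg_get(svr_cfg_in, "k_folds", 5),
      seed = seed
    )
  )
  report <- run_experiment(data, config)
  readr::write_csv(tibble::as_tibble(report), file.path(outdir, "report.csv"))
  writeLines(
    utils::capture.output(format_eval_table(report)),
    file.path(outdir, "report.txt")
  )

  fits <- attr(report, "fits")
  bands <- purrr::imap_dfr(fits[setdiff(names(fits), "split")], function(f, nm) {
    if (is.null(f$selection) || inherits(f$selection, "error")) {
      return(tibble::tibble())
    }
    dplyr::mutate(selected_band_report(f$selection), model = nm, .before = 1)
  })
  if (nrow(bands) > 0) {
    readr::write_csv(bands, file.path(outdir, "selected_bands.csv"))
  }

  manifest <- list(
    dataset = cfg$dataset, target = target, seed = seed,
    n_samples = nrow(data),
    n_train = length(attr(report, "fits")$split$train),
    n_validation = length(attr(report, "fits")$split$validation),
    chosen = purrr::map(
      fits[setdiff(names(fits), "split")],
      function(f) {
        list(
          C = f$svr$C, gamma = f$svr$gamma,
          alpha = if (!is.null(f$selection)) f$selection$alpha else NULL,
          lambda = if (!is.null(f$selection)) f$selection$lambda else NULL,
          n_bands = length(f$bands)
        )
      }
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  message("artifacts written to ", outdir)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
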