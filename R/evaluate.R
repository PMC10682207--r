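#' Coefficient of determination (squared-correlation form)
#'
#' Implements the squared Pearson correlation between observed and predicted
#' values.  Note the documented consequence of this form: any affine
#' transformation of the predictions (`a * pred + b`, `a != 0`) leaves the
#' value unchanged, and it is bounded in `[0, 1]`.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  stats::cor(observed, predicted)^2
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the target.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Experiment configuration for the nine-model comparison
#'
#' Controls the full pipeline: one shared train/validation split, derivative
#' preprocessing, LASSO / elastic-net band selection on the training partition
#' and RBF-SVR with grid search for each of the nine model combinations
#' (3 derivative orders x {full spectrum, LASSO bands, EN bands}).
#'
#' @param target metadata column holding the response (e.g. `"cab"` or
#'   `"spad"`).
#' @param split_fraction training fraction (default 0.75).
#' @param split_counts optional `c(n_train, n_validation)` overriding the
#'   fraction.
#' @param seed root seed for split, fold assignments and any other draw.
#' @param smooth apply Savitzky-Golay smoothing (window 5, order 2) before
#'   derivatives; used for noisy measured-style spectra, off for noiseless
#'   simulated spectra.
#' @param selection_folds,alpha_grid,nlambda,lambda_min_ratio band-selection
#'   controls (see [fit_elastic_net_cv()]).
#' @param svr an [svr_config()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(target = "cab", split_fraction = 0.75,
                              split_counts = NULL, seed = 1, smooth = FALSE,
                              selection_folds = 10,
                              alpha_grid = seq(0.01, 0.99, by = 0.01),
                              nlambda = 100, lambda_min_ratio = 1e-4,
                              svr = svr_config(seed = seed)) {
  structure(
    list(
      target = target, split_fraction = split_fraction,
      split_counts = split_counts, seed = seed, smooth = smooth,
      selection_folds = selection_folds, alpha_grid = alpha_grid,
      nlambda = nlambda, lambda_min_ratio = lambda_min_ratio, svr = svr
    ),
    class = "experiment_config"
  )
}

model_label <- function(order, selection) {
  prefix <- c("OS", "FD", "SD")[order + 1]
  if (selection == "full") paste0(prefix, "-SVR") else paste0(prefix, "-", selection, "-SVR")
}

#' Run the nine-model estimation experiment
#'
#' For each derivative order (original, first, second derivative) fits three
#' SVR models: on the full spectrum, on LASSO-selected bands and on
#' elastic-net-selected bands.  Band selection and hyperparameter tuning use
#' the training partition only; R-squared (squared-correlation form) and RMSE
#' are reported for both partitions.  Row order mirrors the canonical
#' comparison table: OS-SVR, FD-SVR, SD-SVR, OS-LASSO-SVR, ..., SD-EN-SVR.
#'
#' @param data a spectra tibble with the target metadata column.
#' @param config an [experiment_config()].
#' @return A tibble of class `lcc_eval_report` with one row per model:
#'   `model`, `derivative`, `selection`, `n_bands`, `alpha`, `lambda`, `C`,
#'   `gamma`, `r2_train`, `r2_validation`, `rmse_train`, `rmse_validation`.
#'   Attribute `fits` keeps the underlying selection fits, SVR models and the
#'   split for inspection.
#' @export
run_experiment <- function(data, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  data <- as_spectra(data)
  n <- nrow(data)
  if (n < 8) stop("dataset too small for a meaningful split", call. = FALSE)

  split <- split_dataset(n, config$split_fraction, config$seed,
    explicit_counts = config$split_counts
  )
  k_sel <- config$selection_folds
  if (min(length(split$train), length(split$validation)) < k_sel) {
    k_sel <- max(2, min(length(split$train) %/% 2, k_sel))
    warning(sprintf("small training set: selection CV reduced to %d folds", k_sel),
      call. = FALSE
    )
  }

  pre <- if (config$smooth) savgol_smooth(data) else data
  by_order <- list(
    `0` = pre,
    `1` = spectral_derivative(pre, 1),
    `2` = spectral_derivative(pre, 2)
  )

  rows <- list()
  fits <- list(split = split)
  for (order in 0:2) {
    d <- design_matrix(by_order[[as.character(order)]], config$target)
    X_tr <- d$X[split$train, , drop = FALSE]
    y_tr <- d$y[split$train]
    X_va <- d$X[split$validation, , drop = FALSE]
    y_va <- d$y[split$validation]

    selections <- list(full = NULL)
    selections$LASSO <- tryCatch(
      fit_lasso_cv(X_tr, y_tr,
        k_folds = k_sel, seed = config$seed,
        nlambda = config$nlambda, lambda_min_ratio = config$lambda_min_ratio
      ),
      error = function(e) e
    )
    selections$EN <- tryCatch(
      fit_elastic_net_cv(X_tr, y_tr,
        alpha_grid = config$alpha_grid,
        k_folds = k_sel, seed = config$seed, nlambda = config$nlambda,
        lambda_min_ratio = config$lambda_min_ratio
      ),
      error = function(e) e
    )

    for (sel_name in names(selections)) {
      label <- model_label(order, sel_name)
      sel <- selections[[sel_name]]
      row <- tibble::tibble(
        model = label, derivative = order, selection = sel_name,
        n_bands = NA_integer_, alpha = NA_real_, lambda = NA_real_,
        C = NA_real_, gamma = NA_real_,
        r2_train = NA_real_, r2_validation = NA_real_,
        rmse_train = NA_real_, rmse_validation = NA_real_
      )
      result <- tryCatch(
        {
          if (inherits(sel, "error")) stop(sel)
          if (is.null(sel)) {
            keep <- seq_len(ncol(X_tr))
          } else {
            if (sel$n_selected == 0) stop("no bands selected")
            keep <- match(sel$selected_bands, d$wavelengths)
            row$n_bands <- sel$n_selected
            row$alpha <- sel$alpha
            row$lambda <- sel$lambda
          }
          if (is.null(sel)) row$n_bands <- length(keep)
          svr <- fit_svr(X_tr[, keep, drop = FALSE], y_tr, config$svr)
          pr_tr <- predict(svr, X_tr[, keep, drop = FALSE])
          pr_va <- predict(svr, X_va[, keep, drop = FALSE])
          row$C <- svr$C
          row$gamma <- svr$gamma
          row$r2_train <- r_squared(y_tr, pr_tr)
          row$r2_validation <- r_squared(y_va, pr_va)
          row$rmse_train <- rmse(y_tr, pr_tr)
          row$rmse_validation <- rmse(y_va, pr_va)
          fits[[label]] <- list(selection = sel, svr = svr, bands = d$wavelengths[keep])
          row
        },
        error = function(e) {
          warning(sprintf("model %s failed: %s", label, conditionMessage(e)),
            call. = FALSE
          )
          row
        }
      )
      rows[[label]] <- result
    }
  }

  order_labels <- c(
    "OS-SVR", "FD-SVR", "SD-SVR",
    "OS-LASSO-SVR", "FD-LASSO-SVR", "SD-LASSO-SVR",
    "OS-EN-SVR", "FD-EN-SVR", "SD-EN-SVR"
  )
  report <- dplyr::bind_rows(rows[order_labels])
  attr(report, "fits") <- fits
  attr(report, "seed") <- config$seed
  class(report) <- c("lcc_eval_report", class(report))
  report
}

#' Plot an evaluation report
#'
#' Dot plot of training vs validation R-squared per model, mirroring the
#' nine-model comparison.
#'
#' @param object an `lcc_eval_report` from [run_experiment()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lcc_eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("model", "r2_train", "r2_validation")],
    cols = c("r2_train", "r2_validation"),
    names_to = "partition", values_to = "r2"
  )
  df$model <- factor(df$model, levels = unique(object$model))
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$r2, colour = .data$partition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = expression(R^2))
}

#' Format an evaluation report as a comparison table
#'
#' @param report an `lcc_eval_report`.
#' @return Character vector of formatted lines (also printed).
#' @export
format_eval_table <- function(report) {
  lines <- c(
    sprintf(
      "%-14s %6s %6s %8s %8s %6s %7s %9s %9s",
      "Model", "R2_T", "R2_V", "RMSE_T", "RMSE_V", "bands", "alpha", "C", "gamma"
    ),
    purrr::pmap_chr(report, function(model, derivative, selection, n_bands,
                                     alpha, lambda, C, gamma, r2_train,
                                     r2_validation, rmse_train,
                                     rmse_validation, ...) {
      sprintf(
        "%-14s %6.2f %6.2f %8.2f %8.2f %6d %7s %9.3g %9.3g",
        model, r2_train, r2_validation, rmse_train, rmse_validation,
        n_bands, ifelse(is.na(alpha), "-", sprintf("%.2f", alpha)), C, gamma
      )
    })
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
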