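#' SVR hyperparameter search configuration
#'
#' Grids for the RBF-kernel support vector regression grid search.  Defaults
#' follow common libsvm practice: powers of two spanning `C` in `2^-5..2^15`
#' and `gamma` in `2^-15..2^3` (step 2 in the exponent), epsilon-tube 0.1,
#' 5-fold cross-validation.
#'
#' @param c_grid penalty values (> 0).
#' @param gamma_grid kernel width values (> 0).
#' @param epsilon tube width (in response-sd units; the response is
#'   standardized internally).
#' @param k_folds CV folds.
#' @param seed fold-assignment / subsample seed.
#' @param search_max_n grid-search subsample cap: when the training set is
#'   larger, the (C, gamma) search cross-validates on a seeded random subset
#'   of this size and the winner is refit on the full training set (the usual
#'   libsvm-guide practice for large n); `Inf` disables.
#' @param search_tolerance libsvm termination tolerance during the grid
#'   search; the final refit always uses the standard 1e-3.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(c_grid = 2^seq(-2, 12, by = 2),
                       gamma_grid = 2^seq(-14, 0, by = 2),
                       epsilon = 0.1, k_folds = 5, seed = 1,
                       search_max_n = 800, search_tolerance = 0.01) {
  if (any(c_grid <= 0) || any(gamma_grid <= 0) || epsilon < 0) {
    stop("all grid values must be > 0", call. = FALSE)
  }
  structure(
    list(
      c_grid = c_grid, gamma_grid = gamma_grid, epsilon = epsilon,
      k_folds = k_folds, seed = seed, search_max_n = search_max_n,
      search_tolerance = search_tolerance
    ),
    class = "svr_config"
  )
}

scale_apply <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Fit an RBF support vector regression with cross-validated grid search
#'
#' Exhaustive search over the `(C, gamma)` grid by k-fold cross-validation
#' MSE; the winner is refit on the full training set.  Features are
#' standardized with constants fitted on the training folds only (and, for the
#' final model, on the full training set), so no information leaks from
#' held-out folds into the tuning.
#'
#' @param X samples-by-features matrix.
#' @param y response vector.
#' @param config an [svr_config()].
#' @return An object of class `lcc_svr`: the fitted `e1071::svm` model plus
#'   chosen `C`, `gamma`, scaling constants, the CV grid results and
#'   provenance.
#' @export
fit_svr <- function(X, y, config = svr_config()) {
  stopifnot(inherits(config, "svr_config"))
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (nrow(X) < config$k_folds) stop("need at least k_folds samples", call. = FALSE)

  if (stats::var(y) == 0) {
    warning("constant response: fitting a constant predictor", call. = FALSE)
    return(structure(
      list(
        constant = y[1], model = NULL, C = NA_real_, gamma = NA_real_,
        center = colMeans(X), scale = rep(1, ncol(X)),
        cv = NULL, config = config, n_features = ncol(X),
        feature_names = colnames(X)
      ),
      class = "lcc_svr"
    ))
  }

  # the response is standardized for fitting (the usual libsvm practice, and
  # what e1071 itself does when scale = TRUE), so the epsilon tube is in
  # response-sd units; predictions are transformed back
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  # the (C, gamma) search runs on a seeded subsample when n is large; the
  # winning pair is refit below on the complete training set
  search_idx <- seq_len(nrow(X))
  if (nrow(X) > config$search_max_n) {
    search_idx <- withr::with_seed(
      config$seed,
      sort(sample.int(nrow(X), config$search_max_n))
    )
  }
  Xg <- X[search_idx, , drop = FALSE]
  yg <- ys[search_idx]

  folds <- cv_folds(nrow(Xg), config$k_folds, config$seed)
  grid <- tidyr::expand_grid(C = config$c_grid, gamma = config$gamma_grid)

  fold_sets <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    ctr <- colMeans(Xg[tr, , drop = FALSE])
    sc <- apply(Xg[tr, , drop = FALSE], 2, stats::sd)
    sc[sc == 0] <- 1
    list(
      Xtr = scale_apply(Xg[tr, , drop = FALSE], ctr, sc), ytr = yg[tr],
      Xte = scale_apply(Xg[!tr, , drop = FALSE], ctr, sc), yte = yg[!tr]
    )
  })

  grid$cv_mse <- purrr::pmap_dbl(grid[, c("C", "gamma")], function(C, gamma) {
    mean(purrr::map_dbl(fold_sets, function(fs) {
      m <- e1071::svm(
        x = fs$Xtr, y = fs$ytr, type = "eps-regression",
        kernel = "radial", cost = C, gamma = gamma,
        epsilon = config$epsilon, scale = FALSE,
        tolerance = config$search_tolerance
      )
      mean((fs$yte - stats::predict(m, fs$Xte))^2)
    }))
  })

  best <- grid[order(grid$cv_mse, grid$C, grid$gamma), ][1, ]
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0] <- 1
  model <- e1071::svm(
    x = scale_apply(X, ctr, sc), y = ys, type = "eps-regression",
    kernel = "radial", cost = best$C, gamma = best$gamma,
    epsilon = config$epsilon, scale = FALSE
  )
  structure(
    list(
      model = model, C = best$C, gamma = best$gamma, center = ctr, scale = sc,
      y_center = y_center, y_scale = y_scale,
      cv = grid, config = config, n_features = ncol(X),
      feature_names = colnames(X), constant = NULL
    ),
    class = "lcc_svr"
  )
}

#' Predict from a fitted SVR
#'
#' Applies the stored feature standardization and evaluates the kernel
#' expansion; deterministic and row-equivariant.
#'
#' @param object an `lcc_svr` from [fit_svr()].
#' @param newdata matrix with the features the model was trained on.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lcc_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf(
      "feature count mismatch: model has %d, newdata has %d",
      object$n_features, ncol(newdata)
    ), call. = FALSE)
  }
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  raw <- stats::predict(
    object$model,
    scale_apply(newdata, object$center, object$scale)
  )
  unname(object$y_center + object$y_scale * raw)
}

#' @export
print.lcc_svr <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<lcc_svr> constant predictor (%.4g)\n", x$constant))
  } else {
    cat(sprintf(
      "<lcc_svr> RBF SVR: C = %.4g, gamma = %.4g (%d features, %d-fold CV)\n",
      x$C, x$gamma, x$n_features, x$config$k_folds
    ))
  }
  invisible(x)
}

#' One-row summary of a fitted SVR
#'
#' @param x an `lcc_svr`.
#' @param ... unused.
#' @export
glance.lcc_svr <- function(x, ...) {
  tibble::tibble(
    C = x$C, gamma = x$gamma, epsilon = x$config$epsilon,
    n_features = x$n_features,
    n_support_vectors = if (is.null(x$model)) NA_integer_ else x$model$tot.nSV,
    cv_mse_min = if (is.null(x$cv)) NA_real_ else min(x$cv$cv_mse)
  )
}
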