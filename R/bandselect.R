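#' Build a design matrix from a spectra tibble
#'
#' Extracts the predictor matrix (one column per band) and the target vector,
#' dropping zero-variance bands with a warning (they carry no information and
#' cannot be standardized).
#'
#' @param x a spectra tibble.
#' @param target name of the metadata column holding the response.
#' @return List with `X` (samples x bands), `y`, `wavelengths`.
#' @export
design_matrix <- function(x, target) {
  x <- as_spectra(x)
  if (!target %in% names(x)) {
    stop(sprintf("target column '%s' not found", target), call. = FALSE)
  }
  X <- spectra_matrix(x)
  y <- x[[target]]
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in predictors or target", call. = FALSE)
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance band(s)", sum(v == 0)),
      call. = FALSE
    )
    X <- X[, v > 0, drop = FALSE]
  }
  list(X = X, y = y, wavelengths = as.numeric(colnames(X)))
}

# center columns of X and scale to unit 1/n-variance; center y
standardize_design <- function(X, y) {
  n <- nrow(X)
  cx <- colMeans(X)
  Xc <- sweep(X, 2, cx)
  sx <- sqrt(colSums(Xc^2) / n)
  if (any(sx == 0)) stop("zero-variance predictor", call. = FALSE)
  Xs <- sweep(Xc, 2, sx, "/")
  cy <- mean(y)
  list(Xs = Xs, ys = y - cy, center_x = cx, scale_x = sx, center_y = cy)
}

# default descending log-spaced lambda grid from the all-zero threshold
lambda_grid <- function(Xs, ys, alpha, nlambda = 100, lambda_min_ratio = 1e-4) {
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, ys))) / n / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Elastic-net / LASSO coefficient path
#'
#' Minimizes `(1/(2n)) * sum((y - Xb)^2) + lambda * (alpha*|b|_1 +
#' (1-alpha)/2*|b|_2^2)` over a descending lambda path by cyclic coordinate
#' descent with warm starts and covariance (Gram) updating, on standardized
#' predictors and a centered response; coefficients are reported back on the
#' original scale.  `alpha = 1` is the LASSO.
#'
#' @param X samples-by-bands predictor matrix (column names = wavelengths).
#' @param y response vector.
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param lambda optional descending lambda vector; default 100 log-spaced
#'   values from the all-zero threshold `max|x_j'y|/n / alpha` down by 1e-4.
#' @param nlambda,lambda_min_ratio grid shape when `lambda` is `NULL`.
#' @param tol coordinate-change convergence tolerance.
#' @param trace_objective record the penalized objective after every sweep
#'   (testing aid; the sequence is non-increasing).
#' @return An object of class `lcc_enet_path`: list with `lambda`, `alpha`,
#'   `beta` (bands x nlambda, original scale), `intercept` (per lambda), `df`
#'   (nonzero count per lambda), `wavelengths`, and optionally `objective`.
#' @export
lasso_path <- function(X, y, alpha = 1, lambda = NULL, nlambda = 100,
                       lambda_min_ratio = 1e-4, tol = 1e-7,
                       trace_objective = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  std <- standardize_design(X, y)
  n <- nrow(X)
  if (is.null(lambda)) {
    lambda <- lambda_grid(std$Xs, std$ys, alpha, nlambda, lambda_min_ratio)
  }
  G <- crossprod(std$Xs) / n
  cvec <- drop(crossprod(std$Xs, std$ys)) / n
  fit <- .enet_path_gram(G, cvec, sum(std$ys^2) / n, lambda, alpha,
    tol = tol, trace_objective = trace_objective
  )
  beta_std <- fit$beta
  beta <- beta_std / std$scale_x
  intercept <- std$center_y - drop(crossprod(std$center_x, beta))
  out <- list(
    lambda = lambda, alpha = alpha, beta = beta, intercept = intercept,
    df = colSums(beta_std != 0), wavelengths = as.numeric(colnames(X)),
    iterations = fit$iterations
  )
  if (trace_objective) out$objective <- fit$objective
  structure(out, class = "lcc_enet_path")
}

# deterministic fold assignment: shuffled modulo split
cv_folds <- function(n, k, seed) {
  if (k < 2) stop("k_folds must be >= 2", call. = FALSE)
  withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# CV curve for one alpha: mean held-out MSE per lambda over precomputed folds.
# `fold_data` carries per-fold standardized Gram systems so the (expensive)
# Gram products are shared across alphas.
cv_curve_enet <- function(fold_data, lambda, alpha, tol = 1e-7) {
  mse <- matrix(
    NA_real_, length(lambda),
    length(fold_data)
  )
  for (f in seq_along(fold_data)) {
    fd <- fold_data[[f]]
    fit <- .enet_path_gram(fd$G, fd$c, fd$yty_n, lambda, alpha, tol = tol)
    beta_std <- fit$beta
    beta <- beta_std / fd$scale_x
    intercept <- fd$center_y - drop(crossprod(fd$center_x, beta))
    pred <- fd$X_test %*% beta +
      matrix(intercept, nrow(fd$X_test), length(lambda), byrow = TRUE)
    mse[, f] <- colMeans((fd$y_test - pred)^2)
  }
  rowMeans(mse)
}

prepare_fold_data <- function(X, y, folds) {
  lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    std <- standardize_design(X[tr, , drop = FALSE], y[tr])
    n_tr <- sum(tr)
    list(
      G = crossprod(std$Xs) / n_tr,
      c = drop(crossprod(std$Xs, std$ys)) / n_tr,
      yty_n = sum(std$ys^2) / n_tr,
      center_x = std$center_x, scale_x = std$scale_x, center_y = std$center_y,
      X_test = X[!tr, , drop = FALSE], y_test = y[!tr]
    )
  })
}

new_regfit <- function(X, y, alpha, lambda_sel, lambda_grid, cv_mse, seed,
                       k_folds, alpha_cv = NULL) {
  path <- lasso_path(X, y, alpha = alpha, lambda = lambda_grid)
  i <- which(path$lambda == lambda_sel)[1]
  beta <- path$beta[, i]
  nz <- beta != 0
  structure(
    list(
      beta = beta, intercept = path$intercept[i],
      lambda = lambda_sel, alpha = alpha,
      lambda_grid = lambda_grid, cv_mse = cv_mse,
      alpha_cv = alpha_cv,
      wavelengths = path$wavelengths,
      selected_bands = path$wavelengths[nz],
      n_selected = sum(nz), seed = seed, k_folds = k_folds
    ),
    class = "lcc_regfit"
  )
}

# lambda with minimal CV MSE; ties broken toward the largest (sparsest) lambda
pick_lambda_min <- function(lambda, mse) {
  best <- min(mse)
  lambda[which(mse <= best + 1e-15)[1]] # lambda is descending
}

#' Cross-validated LASSO band selection
#'
#' Fits the LASSO path, selects lambda at the minimum of the mean k-fold
#' cross-validation MSE (the lambda-min rule, not the one-standard-error
#' rule), and refits on all data at the chosen lambda.  Bands with nonzero
#' coefficients are the selected bands.
#'
#' @inheritParams lasso_path
#' @param k_folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `lcc_regfit` with elements `beta`, `intercept`
#'   (original scale), `lambda`, `alpha`, `lambda_grid`, `cv_mse`,
#'   `selected_bands`, `n_selected`, `seed`, `k_folds`.
#' @export
fit_lasso_cv <- function(X, y, k_folds = 10, seed = 1, nlambda = 100,
                         lambda_min_ratio = 1e-4) {
  std <- standardize_design(X, y)
  lambda <- lambda_grid(std$Xs, std$ys, 1, nlambda, lambda_min_ratio)
  folds <- cv_folds(nrow(X), k_folds, seed)
  if (min(table(folds)) < 2) stop("a CV fold has fewer than 2 samples", call. = FALSE)
  fd <- prepare_fold_data(X, y, folds)
  mse <- cv_curve_enet(fd, lambda, alpha = 1)
  lam <- pick_lambda_min(lambda, mse)
  new_regfit(X, y,
    alpha = 1, lambda_sel = lam, lambda_grid = lambda,
    cv_mse = mse, seed = seed, k_folds = k_folds
  )
}

#' Cross-validated elastic-net band selection
#'
#' For every mixing value alpha in `alpha_grid`, cross-validates the lambda
#' path and returns the (alpha, lambda) pair minimizing the mean CV MSE.  The
#' default grid divides (0, 1) into 100 parts, i.e. the 99 interior values
#' 0.01, 0.02, ..., 0.99.
#'
#' @inheritParams fit_lasso_cv
#' @param alpha_grid vector of mixing values strictly inside (0, 1).
#' @return An `lcc_regfit`; `alpha_cv` holds the per-alpha CV minima.
#' @export
fit_elastic_net_cv <- function(X, y, alpha_grid = seq(0.01, 0.99, by = 0.01),
                               k_folds = 10, seed = 1, nlambda = 100,
                               lambda_min_ratio = 1e-4) {
  if (length(alpha_grid) == 0) stop("alpha_grid is empty", call. = FALSE)
  if (any(alpha_grid <= 0 | alpha_grid >= 1)) {
    stop("every alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  std <- standardize_design(X, y)
  folds <- cv_folds(nrow(X), k_folds, seed)
  if (min(table(folds)) < 2) stop("a CV fold has fewer than 2 samples", call. = FALSE)
  fd <- prepare_fold_data(X, y, folds)

  per_alpha <- purrr::map(alpha_grid, function(a) {
    lambda <- lambda_grid(std$Xs, std$ys, a, nlambda, lambda_min_ratio)
    mse <- cv_curve_enet(fd, lambda, alpha = a)
    list(
      alpha = a, lambda = pick_lambda_min(lambda, mse),
      mse_min = min(mse), lambda_grid = lambda, cv_mse = mse
    )
  })
  mins <- purrr::map_dbl(per_alpha, "mse_min")
  best <- per_alpha[[which.min(mins)]]
  alpha_cv <- tibble::tibble(
    alpha = alpha_grid, cv_mse_min = mins,
    lambda_min = purrr::map_dbl(per_alpha, "lambda")
  )
  new_regfit(X, y,
    alpha = best$alpha, lambda_sel = best$lambda,
    lambda_grid = best$lambda_grid, cv_mse = best$cv_mse,
    seed = seed, k_folds = k_folds, alpha_cv = alpha_cv
  )
}

#' Selected-band report
#'
#' Table of the bands with nonzero coefficients, sorted by wavelength, with a
#' red-edge (670-760 nm) membership flag.
#'
#' @param fit an `lcc_regfit`.
#' @return Tibble with `wavelength`, `coefficient`, `red_edge`.
#' @export
selected_band_report <- function(fit) {
  stopifnot(inherits(fit, "lcc_regfit"))
  nz <- fit$beta != 0
  tibble::tibble(
    wavelength = fit$wavelengths[nz],
    coefficient = unname(fit$beta[nz]),
    red_edge = fit$wavelengths[nz] >= 670 & fit$wavelengths[nz] <= 760
  ) |>
    dplyr::arrange(.data$wavelength)
}

#' @export
print.lcc_regfit <- function(x, ...) {
  kind <- if (x$alpha == 1) "LASSO" else sprintf("elastic net (alpha = %.2f)", x$alpha)
  cat(sprintf(
    "<lcc_regfit> %s: lambda = %.5g, %d band(s) selected (%d-fold CV, seed %d)\n",
    kind, x$lambda, x$n_selected, x$k_folds, x$seed
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a regularized band-selection fit
#'
#' @param x an `lcc_regfit`.
#' @param ... unused.
#' @return [selected_band_report()] output.
#' @export
tidy.lcc_regfit <- function(x, ...) selected_band_report(x)

#' One-row summary of a regularized band-selection fit
#'
#' @param x an `lcc_regfit`.
#' @param ... unused.
#' @export
glance.lcc_regfit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, lambda = x$lambda, n_selected = x$n_selected,
    cv_mse_min = min(x$cv_mse), k_folds = x$k_folds, seed = x$seed
  )
}

#' Plot a band-selection fit
#'
#' Left panel: cross-validation curve over lambda; right panel: selected-band
#' distribution over wavelength (coefficient magnitude as stem height).
#'
#' @param object an `lcc_regfit`.
#' @param ... unused.
#' @return A ggplot object (band distribution); the CV curve is available via
#'   `plot_cv_curve()`.
#' @export
autoplot.lcc_regfit <- function(object, ...) {
  bands <- selected_band_report(object)
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$wavelength, xend = .data$wavelength,
    y = 0, yend = .data$coefficient, colour = .data$red_edge
  )) +
    ggplot2::geom_segment() +
    ggplot2::labs(
      x = "wavelength (nm)", y = "coefficient",
      title = sprintf(
        "%d selected bands (alpha = %.2f, lambda = %.3g)",
        object$n_selected, object$alpha, object$lambda
      )
    )
}

#' @rdname autoplot.lcc_regfit
#' @export
plot_cv_curve <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda_grid, cv_mse = object$cv_mse)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$cv_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lambda (log scale)", y = "mean CV MSE")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
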