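std_unit <- function(X, y) {
  # standardized design with unit 1/n-variance response: on this scale the
  # package objective and glmnet's internally-rescaled objective coincide
  std <- canopylcc:::standardize_design(X, y)
  sdy <- sqrt(mean(std$ys^2))
  Xs <- std$Xs
  colnames(Xs) <- colnames(X)
  list(X = Xs, y = std$ys / sdy)
}

test_that("the all-zero threshold and soft-threshold closed form hold", {
  set.seed(3)
  n <- 25
  p <- 5
  # zero-mean orthonormal design in the 1/n inner product: (1/n) X'X = I,
  # built orthogonal to the constant vector so internal centering is a no-op
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1]
  X <- sqrt(n) * Q
  colnames(X) <- 700 + 1:p
  beta_true <- c(2, -1, 0.5, 0, 0)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.1)

  yc <- y - mean(y)
  b_ols <- drop(crossprod(X, yc)) / n
  lam_max <- max(abs(b_ols))

  # at lambda >= lambda_max every coefficient is zero
  path <- lasso_path(X, y, lambda = c(lam_max * 1.0001, lam_max * 0.5), tol = 1e-12)
  expect_true(all(path$beta[, 1] == 0))
  expect_gt(sum(path$beta[, 2] != 0), 0)

  # orthonormal design: coefficients are soft-thresholded OLS coefficients
  lam <- 0.3
  fit <- lasso_path(X, y, lambda = c(lam_max, lam), tol = 1e-13)
  soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  # X is standardized already, so original-scale and standardized coincide
  expect_equal(unname(fit$beta[, 2]), unname(soft), tolerance = 1e-6)
})

test_that("coordinate descent never increases the penalized objective", {
  set.seed(8)
  X <- matrix(rnorm(60 * 12), 60, 12)
  colnames(X) <- 500 + 1:12
  y <- X[, 2] - 2 * X[, 7] + rnorm(60, 0, 0.4)
  for (a in c(1, 0.5, 0.1)) {
    tr <- lasso_path(X, y, alpha = a, nlambda = 30, trace_objective = TRUE)
    expect_true(all(diff(tr$objective) <= 1e-10))
  }
})

test_that("coefficients at fixed (alpha, lambda) match an independent solver", {
  skip_if_not_installed("glmnet")
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 8), 20, 8)
    colnames(X) <- 400 + 1:8
    y <- X[, 1] * 1.5 - X[, 5] + rnorm(20, 0, 0.3)
    su <- std_unit(X, y)
    for (a in c(1, 0.6, 0.25)) {
      lams <- c(0.8, 0.3, 0.1, 0.03)
      mine <- lasso_path(su$X, su$y, alpha = a, lambda = lams, tol = 1e-13)
      g <- glmnet::glmnet(su$X, su$y,
        alpha = a, lambda = lams,
        standardize = FALSE, intercept = FALSE, thresh = 1e-15
      )
      expect_equal(unname(mine$beta), unname(as.matrix(g$beta)),
        tolerance = 1e-6, ignore_attr = TRUE
      )
    }
  }
})

test_that("cross-validated LASSO recovers a single informative band", {
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    wl <- 690:710
    n <- 60
    X <- matrix(rnorm(n * length(wl)), n)
    colnames(X) <- wl
    y <- 3 * X[, wl == 700] + rnorm(n, 0, 0.01)
    fit <- fit_lasso_cv(X, y, k_folds = 5, seed = seed)
    700 %in% fit$selected_bands
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure-noise responses select few or no bands", {
  counts <- vapply(1:50, function(seed) {
    set.seed(seed + 100)
    X <- matrix(rnorm(50 * 20), 50, 20)
    colnames(X) <- 600 + 1:20
    y <- rnorm(50)
    fit_lasso_cv(X, y, k_folds = 5, seed = seed)$n_selected
  }, numeric(1))
  expect_gte(mean(counts <= 5), 0.90)
})

test_that("selection is a deterministic function of data and seed", {
  set.seed(2)
  X <- matrix(rnorm(40 * 10), 40, 10)
  colnames(X) <- 500 + 1:10
  y <- X[, 3] + rnorm(40, 0, 0.2)
  f1 <- fit_lasso_cv(X, y, k_folds = 5, seed = 11)
  f2 <- fit_lasso_cv(X, y, k_folds = 5, seed = 11)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$beta, f2$beta)
})

test_that("response rescaling scales coefficients and the chosen lambda alike", {
  set.seed(5)
  X <- matrix(rnorm(50 * 8), 50, 8)
  colnames(X) <- 450 + 1:8
  y <- X[, 2] - X[, 6] + rnorm(50, 0.3)
  c_mult <- 4
  f1 <- fit_lasso_cv(X, y, k_folds = 5, seed = 3)
  f2 <- fit_lasso_cv(X, c_mult * y, k_folds = 5, seed = 3)
  expect_equal(f2$lambda, c_mult * f1$lambda, tolerance = 1e-10)
  expect_equal(f2$beta, c_mult * f1$beta, tolerance = 1e-6)
  expect_equal(f2$selected_bands, f1$selected_bands)
})

test_that("elastic net approaches the LASSO as alpha approaches 1", {
  set.seed(4)
  X <- matrix(rnorm(60 * 10), 60, 10)
  colnames(X) <- 520 + 1:10
  y <- 0.5 * X[, 4] + rnorm(60, 0, 0.1)
  lams <- c(0.5, 0.2, 0.08)
  b_la <- lasso_path(X, y, alpha = 1, lambda = lams, tol = 1e-13)$beta
  # penalty continuity: the gap shrinks linearly in (1 - alpha)
  b_en3 <- lasso_path(X, y, alpha = 0.999, lambda = lams, tol = 1e-13)$beta
  expect_lt(max(abs(b_en3 - b_la)), 1e-3)
  b_en4 <- lasso_path(X, y, alpha = 0.9999, lambda = lams, tol = 1e-13)$beta
  expect_lt(max(abs(b_en4 - b_la)), 1e-4)
  expect_lt(max(abs(b_en4 - b_la)), max(abs(b_en3 - b_la)))
})

test_that("the elastic net groups duplicate informative bands, LASSO splits them", {
  res <- vapply(1:50, function(seed) {
    set.seed(seed + 500)
    n <- 60
    x0 <- rnorm(n)
    # two identical informative bands; coefficients below the numerical-dust
    # level of the soft-threshold boundary do not count as selected
    X <- cbind(x0, x0, matrix(rnorm(n * 6), n, 6))
    colnames(X) <- 700 + 1:8
    y <- 2 * x0 + rnorm(n, 0, 0.3)
    lam <- 0.25
    en <- lasso_path(X, y, alpha = 0.5, lambda = c(1, lam), tol = 1e-12)$beta[, 2]
    la <- lasso_path(X, y, alpha = 1, lambda = c(1, lam), tol = 1e-12)$beta[, 2]
    en_groups <- en[1] != 0 && en[2] != 0 &&
      abs(en[1] - en[2]) < 0.05 * max(abs(en[1:2]))
    lasso_splits <- sum(abs(la[1:2]) > 1e-6 * max(abs(la))) <= 1
    c(en_groups, lasso_splits)
  }, logical(2))
  expect_gte(mean(res[1, ]), 0.90)
  expect_gte(mean(res[2, ]), 0.90)
})

test_that("elastic-net CV accepts the 99-point alpha grid and validates input", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- 480 + 1:6
  y <- X[, 1] + rnorm(40, 0, 0.2)
  fit <- fit_elastic_net_cv(X, y,
    alpha_grid = seq(0.01, 0.99, by = 0.01),
    k_folds = 5, seed = 1
  )
  expect_true(fit$alpha %in% seq(0.01, 0.99, by = 0.01))
  expect_equal(fit$alpha, round(fit$alpha, 2))
  expect_equal(nrow(fit$alpha_cv), 99)
  expect_equal(min(fit$cv_mse), fit$alpha_cv$cv_mse_min[fit$alpha_cv$alpha == fit$alpha])

  expect_error(fit_elastic_net_cv(X, y, alpha_grid = numeric(0)), "empty")
  expect_error(fit_elastic_net_cv(X, y, alpha_grid = c(0.5, 1)), "strictly inside")
  expect_error(lasso_path(X * NA, y), "non-finite")
})

test_that("band reports are sorted, consistent and flag the red edge", {
  set.seed(7)
  X <- matrix(rnorm(50 * 12), 50, 12)
  colnames(X) <- seq(660, 770, by = 10)
  y <- X[, 5] - X[, 9] + rnorm(50, 0, 0.1)
  fit <- fit_lasso_cv(X, y, k_folds = 5, seed = 1)
  rep <- selected_band_report(fit)
  expect_equal(nrow(rep), fit$n_selected)
  expect_equal(nrow(rep), sum(fit$beta != 0))
  expect_false(is.unsorted(rep$wavelength))
  expect_equal(rep$red_edge, rep$wavelength >= 670 & rep$wavelength <= 760)
  expect_identical(tidy(fit), rep)
  expect_equal(glance(fit)$n_selected, fit$n_selected)

  # all-zero fit -> empty table
  zero_fit <- fit
  zero_fit$beta <- fit$beta * 0
  zero_fit$selected_bands <- numeric(0)
  expect_equal(nrow(selected_band_report(zero_fit)), 0)
})
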