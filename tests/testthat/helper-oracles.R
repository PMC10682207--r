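# Independent oracles used across the suite.  These are deliberately naive
# (plain loops, direct formula transliterations) so they share no code with
# the implementation they check.

# plain-loop generalized-plate leaf optics: one wavelength at a time,
# no vectorization, independent transliteration of the model equations
oracle_prospect_one <- function(k, nr, n_structure) {
  tav_o <- function(theta_deg, n) {
    if (theta_deg == 0) {
      return(4 * n / (n + 1)^2)
    }
    th <- theta_deg * pi / 180
    r2 <- n^2
    rp <- r2 + 1
    rm <- r2 - 1
    a <- (n + 1)^2 / 2
    k2 <- -(r2 - 1)^2 / 4
    ds <- sin(th)
    b1 <- if (abs(th - pi / 2) < 1e-12) 0 else sqrt((ds^2 - rp / 2)^2 + k2)
    b <- b1 - (ds^2 - rp / 2)
    ts <- (k2^2 / (6 * b^3) + k2 / b - b / 2) -
      (k2^2 / (6 * a^3) + k2 / a - a / 2)
    tp <- -2 * r2 * (b - a) / rp^2 -
      2 * r2 * rp * log(b / a) / rm^2 +
      r2 * (1 / b - 1 / a) / 2 +
      16 * r2^2 * (r2^2 + 1) * log((2 * rp * b - rm^2) / (2 * rp * a - rm^2)) /
        (rp^3 * rm^2) +
      16 * r2^3 * (1 / (2 * rp * b - rm^2) - 1 / (2 * rp * a - rm^2)) / rp^3
    (ts + tp) / (2 * ds^2)
  }
  trans <- if (k <= 0) 1 else (1 - k) * exp(-k) + k^2 * pracma::expint_E1(k)
  talf <- tav_o(40, nr)
  ralf <- 1 - talf
  t12 <- tav_o(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * trans^2
  Ta <- talf * trans * t21 / denom
  Ra <- ralf + r21 * trans * Ta
  tt <- t12 * trans * t21 / denom
  rr <- r12 + r21 * trans * tt
  D <- sqrt((1 + rr + tt) * (1 + rr - tt) * (1 - rr + tt) * (1 - rr - tt))
  a <- (1 + rr^2 - tt^2 + D) / (2 * rr)
  b <- (1 - rr^2 + tt^2 + D) / (2 * tt)
  bNm1 <- b^(n_structure - 1)
  Rsub <- a * (bNm1^2 - 1) / (a^2 * bNm1^2 - 1)
  Tsub <- bNm1 * (a^2 - 1) / (a^2 * bNm1^2 - 1)
  den <- 1 - Rsub * rr
  c(
    reflectance = Ra + Ta * Rsub * tt / den,
    transmittance = Ta * Tsub / den
  )
}

# per-window least-squares Savitzky-Golay oracle: fit a polynomial to each
# window and evaluate at its centre (edges: truncated evaluation position)
oracle_savgol <- function(x, window = 5, polyorder = 2) {
  half <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, min(i - half, n - window + 1))
    idx <- lo:(lo + window - 1)
    fit <- stats::lm(y ~ poly(t, polyorder, raw = TRUE),
      data = data.frame(t = idx - i, y = x[idx])
    )
    out[i] <- unname(stats::coef(fit)[1])
  }
  out
}

# brute-force elementwise central-difference oracle
oracle_first_derivative <- function(values, wavelengths) {
  p <- length(wavelengths)
  out <- numeric(p - 2)
  for (i in 2:(p - 1)) {
    out[i - 1] <- (values[i + 1] - values[i - 1]) /
      (wavelengths[i + 1] - wavelengths[i - 1])
  }
  out
}

# explicit dual-form RBF-SVR evaluation: sum_i coef_i K(sv_i, x) - rho
oracle_svr_predict <- function(svm_model, X_scaled) {
  sv <- svm_model$SV
  co <- svm_model$coefs
  g <- svm_model$gamma
  out <- numeric(nrow(X_scaled))
  for (i in seq_len(nrow(X_scaled))) {
    kv <- exp(-g * colSums((t(sv) - X_scaled[i, ])^2))
    out[i] <- sum(co * kv) - svm_model$rho
  }
  out
}

# total variation of a vector
total_variation <- function(x) sum(abs(diff(x)))

# small random spectra tibble for plumbing tests
make_random_spectra <- function(n = 6, wavelengths = 500:520, seed = 1,
                                target = NULL) {
  m <- withr::with_seed(seed, matrix(stats::runif(n * length(wavelengths)),
    nrow = n
  ))
  colnames(m) <- as.character(wavelengths)
  meta <- tibble::tibble(sample_id = seq_len(n))
  if (!is.null(target)) meta$cab <- target
  dplyr::bind_cols(meta, tibble::as_tibble(m))
}
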