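#' Truncated-normal SPAD draws
#'
#' Draws SPAD readings from a normal distribution truncated to `[lo, hi]` by
#' inverse-CDF sampling (exact, no rejection).  Defaults emulate the measured
#' orchard campaign: mean 36.00, sd 2.69, range 29.50-42.00.
#'
#' @param n number of trees.
#' @param mean,sd untruncated normal parameters (sd > 0).
#' @param lo,hi truncation bounds (lo < hi).
#' @param seed integer seed.
#' @return Numeric vector of length `n` inside `[lo, hi]`.
#' @export
#' @examples
#' summary(sample_spad(69, seed = 1))
sample_spad <- function(n, mean = 36, sd = 2.69, lo = 29.5, hi = 42, seed = 1) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-12) stop("infeasible truncation window", call. = FALSE)
  u <- withr::with_seed(seed, stats::runif(n, p_lo, p_hi))
  stats::qnorm(u, mean, sd)
}

# closed-form mean and sd of the truncated normal (testing oracle)
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  m <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  v <- sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z -
    ((stats::dnorm(a) - stats::dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

#' Measurement noise model for synthetic field spectra
#'
#' Multiplicative Gaussian noise (relative sd `multiplicative_sd`) plus an
#' additive Gaussian floor (`additive_sd`), applied to each of `replicates`
#' repeated scans which are then averaged - emulating the field protocol of
#' measuring each tree five times and averaging.  Field spectroradiometers
#' resample an optical bandwidth of several nanometres onto the 1 nm output
#' grid, so per-scan noise is spectrally correlated, not white at 1 nm;
#' `spectral_correlation_nm` is the Gaussian correlation scale (sd, in nm)
#' applied to the noise while preserving its per-band sd.  Set it to 0 for
#' white noise.
#'
#' @param multiplicative_sd relative noise sd per scan (default 0.02).
#' @param additive_sd additive reflectance noise floor per scan (default 0.002).
#' @param replicates scans averaged per tree (default 5).
#' @param spectral_correlation_nm correlation scale of the per-scan noise in
#'   nm (default 3.5, a typical VNIR optical bandwidth).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.02, additive_sd = 0.002,
                        replicates = 5, spectral_correlation_nm = 3.5) {
  if (multiplicative_sd < 0 || additive_sd < 0 || replicates < 1 ||
    spectral_correlation_nm < 0) {
    stop("invalid noise model", call. = FALSE)
  }
  structure(
    list(
      multiplicative_sd = multiplicative_sd, additive_sd = additive_sd,
      replicates = replicates,
      spectral_correlation_nm = spectral_correlation_nm
    ),
    class = "noise_model"
  )
}

# band-correlated unit-sd Gaussian noise: white draws convolved with a
# Gaussian kernel and renormalized so the per-band sd stays 1
correlated_noise <- function(p, corr_nm) {
  e <- stats::rnorm(p)
  if (corr_nm <= 0) {
    return(e)
  }
  half <- max(1L, ceiling(3 * corr_nm))
  kern <- stats::dnorm(seq(-half, half), 0, corr_nm)
  kern <- kern / sqrt(sum(kern^2))
  as.numeric(stats::filter(e, kern, sides = 2, circular = TRUE))
}

apply_noise <- function(spectrum, nm) {
  p <- length(spectrum)
  reps <- vapply(seq_len(nm$replicates), function(i) {
    spectrum *
      (1 + nm$multiplicative_sd * correlated_noise(p, nm$spectral_correlation_nm)) +
      nm$additive_sd * correlated_noise(p, nm$spectral_correlation_nm)
  }, numeric(p))
  pmin(pmax(rowMeans(reps), 0), 1)
}

#' Generate a synthetic field campaign
#'
#' Stand-in for an undeposited measured dataset: for each tree a SPAD value is
#' drawn from the truncated-normal campaign distribution, converted to leaf
#' chlorophyll content via [spad_to_lcc()] and used as the simulator's Cab;
#' nuisance canopy parameters (N, LAI, soil scale, ALA) are drawn uniformly
#' over the simulation grid ranges; the noiseless simulated spectrum receives
#' replicate measurement noise and averaging per [noise_model()], is extended
#' from 400 nm down to `lo_nm` by boundary extension (the simulator's lower
#' bound; flagged via the `extended_below_nm` attribute), and finally receives
#' the measured-data preprocessing (crop, Savitzky-Golay smoothing).
#'
#' @param n number of trees (default 69).
#' @param noise a [noise_model()].
#' @param seed root seed; all draws derive from it.
#' @param spad_mean,spad_sd,spad_lo,spad_hi campaign SPAD distribution.
#' @param geom an [rt_geometry()].
#' @param lo_nm lower bound of the emitted spectrum (default 350; values
#'   below 400 nm are boundary-extended).
#' @param smooth apply the measured-data Savitzky-Golay smoothing (default
#'   TRUE).
#' @return A spectra tibble with metadata `tree_id`, `spad`, `lcc`, `cab`,
#'   `n_structure`, `lai`, `soil_scale`, `ala`; attribute `extended_below_nm
#'   = 400` marks the boundary-extension region.
#' @export
generate_field_campaign <- function(n = 69, noise = noise_model(), seed = 1,
                                    spad_mean = 36, spad_sd = 2.69,
                                    spad_lo = 29.5, spad_hi = 42,
                                    geom = rt_geometry(), lo_nm = 350,
                                    smooth = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  spad <- sample_spad(n, spad_mean, spad_sd, spad_lo, spad_hi, seed = seed)
  lcc <- spad_to_lcc(spad)

  wl_sim <- 400:1050
  scenes <- withr::with_seed(seed + 1L, tibble::tibble(
    tree_id = seq_len(n), spad = spad, lcc = lcc, cab = lcc,
    n_structure = stats::runif(n, 1, 1.5),
    lai = stats::runif(n, 1, 7),
    soil_scale = stats::runif(n, 0.6, 1),
    ala = stats::runif(n, 0, 60)
  ))

  wl_out <- seq(lo_nm, 1050)
  n_ext <- sum(wl_out < 400)
  spectra <- withr::with_seed(seed + 2L, {
    m <- matrix(NA_real_, n, length(wl_out))
    for (i in seq_len(n)) {
      sc <- canopy_scene(
        cab = scenes$cab[i], n_structure = scenes$n_structure[i],
        lai_single_tree = scenes$lai[i], soil_scale = scenes$soil_scale[i],
        ala_deg = scenes$ala[i]
      )
      clean <- inform_simulate(sc, geom, wl_sim)$reflectance
      noisy <- apply_noise(clean, noise)
      m[i, ] <- c(rep(noisy[1], n_ext), noisy)
    }
    m
  })

  out <- as_spectra(spectra_bind(scenes, spectra, wl_out))
  if (smooth) out <- savgol_smooth(out)
  attr(out, "extended_below_nm") <- if (n_ext > 0) 400 else NA_real_
  attr(out, "seed") <- seed
  out
}
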