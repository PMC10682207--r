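#' Crop spectra to a wavelength window
#'
#' Keeps wavelength columns inside the inclusive `[lo_nm, hi_nm]` window;
#' metadata columns are preserved.
#'
#' @param x a spectra tibble.
#' @param lo_nm,hi_nm window bounds in nm.
#' @return A spectra tibble.
#' @export
crop_spectra <- function(x, lo_nm, hi_nm) {
  x <- as_spectra(x)
  wl <- spectra_wavelengths(x)
  keep <- wl[wl >= lo_nm & wl <= hi_nm]
  if (length(keep) == 0) {
    stop("crop window does not intersect the wavelength grid", call. = FALSE)
  }
  meta <- spectra_meta(x)
  out <- dplyr::bind_cols(meta, x[, as.character(keep)])
  attr(out, "derivative_order") <- attr(x, "derivative_order")
  out
}

#' Savitzky-Golay smoothing of spectra
#'
#' Applies a Savitzky-Golay polynomial smoothing filter along the wavelength
#' axis of every sample.  Interior points are convolved with the closed-form
#' least-squares kernel (for the default second-order, window-5 filter this is
#' `(-3, 12, 17, 12, -3)/35`); the first and last `(window-1)/2` points come
#' from the polynomial fitted to the edge window evaluated off-centre.
#'
#' @param x a spectra tibble.
#' @param window odd filter length (> `polyorder`), default 5.
#' @param polyorder polynomial order, default 2.
#' @return A smoothed spectra tibble.
#' @export
savgol_smooth <- function(x, window = 5, polyorder = 2) {
  x <- as_spectra(x)
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  wl <- spectra_wavelengths(x)
  if (window >= length(wl)) {
    stop("window must be shorter than the spectrum", call. = FALSE)
  }
  m <- spectra_matrix(x)
  sm <- t(apply(m, 1, signal::sgolayfilt, p = polyorder, n = window))
  spectra_bind(spectra_meta(x), sm, wl,
    derivative_order = attr(x, "derivative_order")
  )
}

#' First and second derivative spectra
#'
#' Central finite differences on the wavelength grid:
#' `FD_i = (R_[i+1] - R_[i-1]) / (lambda_[i+1] - lambda_[i-1])`; the second
#' derivative is the first derivative applied twice.  Edge wavelengths where
#' the central estimate is undefined are dropped (one per edge per order), so
#' every retained band is a true central estimate.
#'
#' @param x a spectra tibble (reflectance, order 0).
#' @param order 1 (first derivative) or 2 (second).
#' @return A spectra tibble of derivative values with a `derivative_order`
#'   attribute; units are reflectance per nm (order 1) or per nm^2 (order 2).
#' @export
#' @examples
#' sp <- tibble::tibble(sample_id = 1, `500` = 0.1, `501` = 0.2, `502` = 0.4, `503` = 0.7)
#' spectral_derivative(sp, 1)
spectral_derivative <- function(x, order = 1) {
  stopifnot(order %in% c(1, 2))
  x <- as_spectra(x)
  wl <- spectra_wavelengths(x)
  if (length(wl) < 2 * order + 1) {
    stop("not enough wavelengths for the requested derivative order",
      call. = FALSE
    )
  }
  central_diff <- function(m, wl) {
    p <- length(wl)
    d <- (m[, 3:p, drop = FALSE] - m[, 1:(p - 2), drop = FALSE]) /
      rep(wl[3:p] - wl[1:(p - 2)], each = nrow(m))
    list(values = d, wavelengths = wl[2:(p - 1)])
  }
  res <- central_diff(spectra_matrix(x), wl)
  if (order == 2) res <- central_diff(res$values, res$wavelengths)
  spectra_bind(spectra_meta(x), res$values, res$wavelengths,
    derivative_order = order
  )
}

#' Locate the red-edge inflection of a single spectrum
#'
#' Returns the wavelength in the 680-760 nm transition where the second
#' derivative of reflectance changes sign (maximum slope of the red edge).
#'
#' @param wavelength,reflectance numeric vectors of one spectrum.
#' @return Wavelength (nm) of the inflection, or `NA` if no sign change.
#' @export
red_edge_inflection <- function(wavelength, reflectance) {
  sel <- wavelength >= 680 & wavelength <= 760
  wl <- wavelength[sel]
  r <- reflectance[sel]
  d2 <- diff(diff(r))
  sgn <- sign(d2)
  idx <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)[1]
  if (is.na(idx)) {
    return(NA_real_)
  }
  wl[idx + 1]
}
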