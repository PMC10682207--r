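#' Synthetic leaf optical constants
#'
#' Generates a table of wavelength-dependent constants used by the plate-model
#' leaf optics simulator: the leaf refractive index and the specific absorption
#' coefficients of chlorophyll a+b, carotenoids, brown pigments, water and dry
#' matter.
#'
#' These curves are SYNTHETIC: they are smooth analytic stand-ins (sums of
#' Gaussian absorption features on a low-order baseline) constructed to match
#' the qualitative shape and order of magnitude of published in-vivo absorption
#' spectra - chlorophyll peaks in the blue (~430-460 nm) and red (~670 nm) with
#' no absorption beyond ~740 nm, carotenoid absorption confined to 400-550 nm,
#' water overtone bands growing through the near- and shortwave infrared, and a
#' weak, slowly varying dry-matter continuum.  They are not a reproduction of
#' any measured coefficient set, so simulated spectra are physically plausible
#' rather than instrument-accurate; all downstream statistical machinery is
#' agnostic to this choice.
#'
#' @param wavelengths integer or numeric vector of wavelengths in nm within
#'   the supported 400-2500 nm range.
#' @return A tibble with columns `wavelength`, `refractive_index`, `k_cab`
#'   (cm^2/ug), `k_car` (cm^2/ug), `k_brown`, `k_cw` (1/cm), `k_cm` (cm^2/g).
#' @export
#' @examples
#' oc <- synthetic_optical_constants()
#' oc[oc$wavelength == 670, ]
synthetic_optical_constants <- function(wavelengths = 400:2500) {
  wl <- as.numeric(wavelengths)
  if (any(wl < 400 | wl > 2500)) {
    stop("supported wavelength range is 400-2500 nm", call. = FALSE)
  }
  g <- function(center, width) exp(-((wl - center) / width)^2)

  # refractive index: slow monotone decrease, typical 1.54 -> 1.40
  nr <- 1.40 + 0.14 / (1 + exp((wl - 1200) / 450))

  # chlorophyll a+b: Soret blue bands + red band, zero past the red edge
  k_cab <- 0.070 * g(430, 26) + 0.048 * g(462, 32) +
    0.016 * g(585, 40) + 0.022 * g(635, 25) + 0.066 * g(672, 20)
  k_cab[wl > 750] <- 0

  # carotenoids: blue absorption only
  k_car <- 0.052 * g(450, 26) + 0.060 * g(482, 24) + 0.020 * g(515, 20)
  k_car[wl > 560] <- 0

  # brown pigments: exponentially decaying visible absorption
  k_brown <- 0.4 * exp(-(wl - 400) / 150)
  k_brown[wl > 900] <- 0

  # water (per cm of equivalent water thickness): overtone bands
  k_cw <- 0.35 * g(970, 35) + 1.1 * g(1200, 55) + 6 * g(1450, 45) +
    28 * exp(-((wl - 1450) / 140)^2) * (wl > 1450) +
    4.5 * g(1780, 80) + 95 * g(1935, 60) + 55 * g(2500, 250) +
    0.05 * pmax(0, (wl - 900) / 1000)

  # dry matter (cm^2/g): weak continuum rising into the SWIR + ligno-cellulose bands
  k_cm <- 2.5 + 6 * (wl - 400) / 2100 + 3.5 * g(2100, 60) + 3.0 * g(2300, 70) +
    1.2 * g(1730, 50)

  tibble::tibble(
    wavelength = wl,
    refractive_index = nr,
    k_cab = k_cab, k_car = k_car, k_brown = k_brown,
    k_cw = k_cw, k_cm = k_cm
  )
}

#' Synthetic reference dry-soil reflectance spectrum
#'
#' A smooth analytic stand-in for a reference bare dry-soil reflectance
#' spectrum: brightness rising from the blue to a broad near-infrared plateau,
#' with shallow water-absorption dips near 1450 and 1940 nm.  SYNTHETIC in the
#' same sense as [synthetic_optical_constants()].  The canopy-scene parameter
#' `soil_scale` multiplies this spectrum to emulate darker or brighter
#' understory backgrounds.
#'
#' @inheritParams synthetic_optical_constants
#' @return A tibble with columns `wavelength` (nm) and `reflectance`.
#' @export
synthetic_soil_spectrum <- function(wavelengths = 400:2500) {
  wl <- as.numeric(wavelengths)
  if (any(wl < 400 | wl > 2500)) {
    stop("supported wavelength range is 400-2500 nm", call. = FALSE)
  }
  base <- 0.10 + 0.28 / (1 + exp(-(wl - 900) / 320))
  dips <- 0.06 * exp(-((wl - 1450) / 70)^2) + 0.09 * exp(-((wl - 1940) / 80)^2)
  refl <- pmin(pmax(base - dips, 0), 1)
  tibble::tibble(wavelength = wl, reflectance = refl)
}
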