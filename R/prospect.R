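#' Leaf parameter set for the plate-model leaf optics simulator
#'
#' Bundles and validates the biochemical and structural inputs of the
#' generalized plate model: the mesophyll structure parameter N (number of
#' compact layers), chlorophyll a+b content, carotenoid content, equivalent
#' water thickness and dry matter content.  Carotenoids are tied to
#' chlorophyll as `cab / 4` by default (a realistic leaf pigment ratio) so the
#' four-parameter surface (N, Cab, Cw, Cm) used by the canopy grid stays
#' intact; pass `car` to override.
#'
#' @param cab chlorophyll a+b content, ug/cm^2 (>= 0).
#' @param n_structure leaf structure parameter N, dimensionless (>= 1).
#' @param cw equivalent water thickness, g/cm^2 (cm).
#' @param cm dry matter content, g/cm^2.
#' @param car carotenoid content, ug/cm^2; default `cab / 4`.
#' @param cbrown brown pigment fraction, dimensionless; default 0.
#' @return An object of class `leaf_params` (named list).
#' @export
#' @examples
#' leaf_params(cab = 40)
leaf_params <- function(cab, n_structure = 1.5, cw = 0.03, cm = 0.012,
                        car = cab / 4, cbrown = 0) {
  stopifnot(is.numeric(cab), is.numeric(n_structure))
  if (n_structure < 1) {
    stop("n_structure must be >= 1", call. = FALSE)
  }
  vals <- c(cab = cab, car = car, cbrown = cbrown, cw = cw, cm = cm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("leaf contents (cab, car, cbrown, cw, cm) must be finite and >= 0",
      call. = FALSE
    )
  }
  structure(
    list(
      cab = cab, n_structure = n_structure, car = car,
      cbrown = cbrown, cw = cw, cm = cm
    ),
    class = "leaf_params"
  )
}

# average transmissivity of a dielectric interface for isotropic light
# incident between 0 and `theta` degrees, refractive index `ref`
# (Stern's integral in the closed form used by plate-model leaf optics)
tav <- function(theta, ref) {
  if (theta == 0) {
    return(4 * ref / (ref + 1)^2)
  }
  theta <- theta * pi / 180
  r2 <- ref^2
  rp <- r2 + 1
  rm <- r2 - 1
  a <- (ref + 1)^2 / 2
  k <- -(r2 - 1)^2 / 4
  ds <- sin(theta)
  k2 <- k^2
  rm2 <- rm^2
  if (abs(theta - pi / 2) < 1e-12) {
    b1 <- 0
  } else {
    b1 <- sqrt((ds^2 - rp / 2)^2 + k)
  }
  b2 <- ds^2 - rp / 2
  b <- b1 - b2
  ts <- (k2 / (6 * b^3) + k / b - b / 2) - (k2 / (6 * a^3) + k / a - a / 2)
  tp1 <- -2 * r2 * (b - a) / rp^2
  tp2 <- -2 * r2 * rp * log(b / a) / rm2
  tp3 <- r2 * (1 / b - 1 / a) / 2
  tp4 <- 16 * r2^2 * (r2^2 + 1) * log((2 * rp * b - rm2) / (2 * rp * a - rm2)) /
    (rp^3 * rm2)
  tp5 <- 16 * r2^3 * (1 / (2 * rp * b - rm2) - 1 / (2 * rp * a - rm2)) / rp^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5
  (ts + tp) / (2 * ds^2)
}

# transmissivity of a single absorbing plate with absorption coefficient k
# tau(k) = (1 - k) e^-k + k^2 E1(k), tau(0) = 1
plate_transmissivity <- function(k) {
  tau <- rep(1, length(k))
  pos <- k > 0
  if (any(pos)) {
    kp <- k[pos]
    tau[pos] <- (1 - kp) * exp(-kp) + kp^2 * pracma::expint_E1(kp)
  }
  pmin(pmax(tau, 0), 1)
}

#' Simulate leaf reflectance and transmittance (generalized plate model)
#'
#' Implements the N-layer plate model of leaf optics: total absorption per
#' elementary layer is the content-weighted sum of the specific absorption
#' coefficients divided by N; single-plate reflectance/transmittance follow
#' from the interface transmissivities (light incident within a 40 degree
#' solid angle at the upper surface) and the Stokes system extends the stack
#' to N layers.
#'
#' @param leaf a [leaf_params()] object.
#' @param wavelengths wavelengths (nm) within 400-2500; default 400-1050.
#' @param constants optional constants table from
#'   [synthetic_optical_constants()] evaluated on `wavelengths`.
#' @return A tibble with columns `wavelength`, `reflectance`, `transmittance`.
#' @export
#' @examples
#' lo <- prospect(leaf_params(cab = 40))
#' lo[lo$wavelength %in% c(550, 670, 800), ]
prospect <- function(leaf, wavelengths = 400:1050, constants = NULL) {
  if (!inherits(leaf, "leaf_params")) leaf <- do.call(leaf_params, as.list(leaf))
  if (is.null(constants)) constants <- synthetic_optical_constants(wavelengths)
  stopifnot(all(constants$wavelength == wavelengths))
  n_str <- leaf$n_structure

  k <- (leaf$cab * constants$k_cab + leaf$car * constants$k_car +
    leaf$cbrown * constants$k_brown + leaf$cw * constants$k_cw +
    leaf$cm * constants$k_cm) / n_str
  trans <- plate_transmissivity(k)
  nr <- constants$refractive_index

  talf <- vapply(nr, tav, numeric(1), theta = 40)
  ralf <- 1 - talf
  t12 <- vapply(nr, tav, numeric(1), theta = 90)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * trans^2
  Ta <- talf * trans * t21 / denom
  Ra <- ralf + r21 * trans * Ta
  t <- t12 * trans * t21 / denom
  r <- r12 + r21 * trans * t

  # Stokes extension from 1 plate to N plates (N - 1 additional layers)
  D <- sqrt(pmax(
    (1 + r + t) * (1 + r - t) * (1 - r + t) * (1 - r - t),
    0
  ))
  rq <- r^2
  tq <- t^2
  a <- (1 + rq - tq + D) / (2 * r)
  b <- (1 - rq + tq + D) / (2 * t)

  bNm1 <- b^(n_str - 1)
  bN2 <- bNm1^2
  a2 <- a^2
  denom2 <- a2 * bN2 - 1
  Rsub <- a * (bN2 - 1) / denom2
  Tsub <- bNm1 * (a2 - 1) / denom2

  # nearly opaque plates: the Stokes expressions degenerate
  opaque <- (r + t) >= 1
  if (any(opaque)) {
    Tsub[opaque] <- t[opaque] / (t[opaque] + (1 - t[opaque]) * (n_str - 1))
    Rsub[opaque] <- 1 - Tsub[opaque]
  }

  denom3 <- 1 - Rsub * r
  transmittance <- Ta * Tsub / denom3
  reflectance <- Ra + Ta * Rsub * t / denom3

  tibble::tibble(
    wavelength = as.numeric(wavelengths),
    reflectance = pmin(pmax(reflectance, 0), 1),
    transmittance = pmin(pmax(transmittance, 0), 1)
  )
}
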