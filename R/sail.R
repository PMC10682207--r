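#' Observation / illumination geometry
#'
#' @param sun_zenith_deg solar zenith angle, degrees in `[0, 90)`.
#' @param view_zenith_deg view zenith angle, degrees in `[0, 90)`.
#' @param rel_azimuth_deg relative azimuth between sun and view, degrees.
#' @param diffuse_fraction fraction of diffuse incident radiation in `[0, 1]`.
#' @return An object of class `rt_geometry`.
#' @export
rt_geometry <- function(sun_zenith_deg = 30, view_zenith_deg = 0,
                        rel_azimuth_deg = 0, diffuse_fraction = 0.1) {
  if (sun_zenith_deg < 0 || sun_zenith_deg >= 90 ||
    view_zenith_deg < 0 || view_zenith_deg >= 90) {
    stop("zenith angles must lie in [0, 90)", call. = FALSE)
  }
  if (diffuse_fraction < 0 || diffuse_fraction > 1) {
    stop("diffuse_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      sun_zenith_deg = sun_zenith_deg, view_zenith_deg = view_zenith_deg,
      rel_azimuth_deg = rel_azimuth_deg, diffuse_fraction = diffuse_fraction
    ),
    class = "rt_geometry"
  )
}

# ellipsoidal (Campbell) leaf inclination distribution over the 13 standard
# angle classes; `ala_deg` is the mean leaf inclination angle
leaf_angle_distribution <- function(ala_deg) {
  ala_deg <- max(ala_deg, 1e-4) # ala = 0 -> extreme planophile limit
  excent <- exp(-1.6184e-5 * ala_deg^3 + 2.1145e-3 * ala_deg^2 -
    1.2390e-1 * ala_deg + 3.2491)
  tl1 <- c(seq(0, 70, by = 10), seq(80, 88, by = 2)) * pi / 180
  tl2 <- c(seq(10, 80, by = 10), seq(82, 90, by = 2)) * pi / 180
  freq <- numeric(13)
  for (i in seq_len(13)) {
    x1 <- excent / sqrt(1 + excent^2 * tan(tl1[i])^2)
    x2 <- excent / sqrt(1 + excent^2 * tan(tl2[i])^2)
    if (abs(excent - 1) < 1e-9) {
      freq[i] <- abs(cos(tl1[i]) - cos(tl2[i]))
    } else {
      alpha <- excent / sqrt(abs(1 - excent^2))
      alpha2 <- alpha^2
      x12 <- x1^2
      x22 <- x2^2
      if (excent > 1) {
        alpx1 <- sqrt(alpha2 + x12)
        alpx2 <- sqrt(alpha2 + x22)
        dum <- x1 * alpx1 + alpha2 * log(x1 + alpx1)
        freq[i] <- abs(dum - (x2 * alpx2 + alpha2 * log(x2 + alpx2)))
      } else {
        almx1 <- sqrt(alpha2 - x12)
        almx2 <- sqrt(alpha2 - x22)
        dum <- x1 * almx1 + alpha2 * asin(x1 / alpha)
        freq[i] <- abs(dum - (x2 * almx2 + alpha2 * asin(x2 / alpha)))
      }
    }
  }
  list(
    angles_deg = c(seq(5, 75, by = 10), seq(81, 89, by = 2)),
    freq = freq / sum(freq)
  )
}

# geometric factors for one leaf inclination: cross sections in the sun and
# view directions and the bidirectional scattering area fractions
volscatt <- function(tts, tto, psi, ttl) {
  costs <- cos(tts)
  costo <- cos(tto)
  sints <- sin(tts)
  sinto <- sin(tto)
  cospsi <- cos(psi)
  costl <- cos(ttl)
  sintl <- sin(ttl)
  cs <- costl * costs
  co <- costl * costo
  ss <- sintl * sints
  so <- sintl * sinto

  cosbts <- if (abs(ss) > 1e-6) -cs / ss else 5
  cosbto <- if (abs(so) > 1e-6) -co / so else 5

  if (abs(cosbts) < 1) {
    bts <- acos(cosbts)
    ds <- ss
  } else {
    bts <- pi
    ds <- cs
  }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)

  if (abs(cosbto) < 1) {
    bto <- acos(cosbto)
    do_ <- so
  } else if (tto < pi / 2) {
    bto <- pi
    do_ <- co
  } else {
    bto <- 0
    do_ <- -co
  }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psi <= btran1) {
    bt1 <- psi
    bt2 <- btran1
    bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psi <= btran2) {
      bt2 <- psi
      bt3 <- btran2
    } else {
      bt2 <- btran2
      bt3 <- psi
    }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- if (bt2 > 0) sin(bt2) * (2 * ds * do_ + ss * so * cos(bt1) * cos(bt3)) else 0
  denom <- 2 * pi^2
  frho <- max(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- max((-bt1 * t1 + t2) / denom, 0)
  c(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

jfunc1 <- function(k, m, t) {
  del <- (k - m) * t
  out <- numeric(length(m))
  big <- abs(del) > 1e-3
  out[big] <- (exp(-m[big] * t) - exp(-k * t)) / (k - m[big])
  sm <- !big
  out[sm] <- 0.5 * t * (exp(-k * t) + exp(-m[sm] * t)) * (1 - del[sm]^2 / 12)
  out
}
jfunc2 <- function(k, m, t) (1 - exp(-(k + m) * t)) / (k + m)

#' SAILH turbid-medium canopy radiative transfer
#'
#' Four-stream radiative transfer of a homogeneous leaf layer over a soil
#' background, with the hot-spot correction applied to the bidirectional
#' (single-scattering) term.  Leaf inclination follows the ellipsoidal
#' distribution parameterised by the average leaf angle.
#'
#' @param leaf_optics tibble from [prospect()] (columns `wavelength`,
#'   `reflectance`, `transmittance`).
#' @param lai leaf area index of the layer, m^2/m^2 (>= 0).
#' @param ala_deg average leaf inclination angle, degrees in `[0, 90]`.
#' @param hot_spot hot-spot size parameter (leaf size / canopy height).
#' @param soil_spectrum numeric vector of background reflectance on the same
#'   wavelength grid as `leaf_optics`.
#' @param geom an [rt_geometry()].
#' @return A tibble of class `canopy_rt` with columns `wavelength`,
#'   `reflectance` (directional reflectance for the given geometry, mixing
#'   the direct and diffuse incident streams by `diffuse_fraction`),
#'   `rho_so` (bidirectional), `rho_do` (diffuse-directional), `tau_ss`
#'   (direct beam transmittance in the sun direction), `tau_oo` (direct gap
#'   fraction in the view direction).
#' @export
sailh <- function(leaf_optics, lai, ala_deg, hot_spot, soil_spectrum, geom) {
  stopifnot(inherits(geom, "rt_geometry"))
  if (lai < 0) stop("lai must be >= 0", call. = FALSE)
  if (length(soil_spectrum) != nrow(leaf_optics)) {
    stop("leaf_optics and soil_spectrum must share the wavelength grid",
      call. = FALSE
    )
  }
  wl <- leaf_optics$wavelength
  rho <- leaf_optics$reflectance
  tau <- leaf_optics$transmittance
  rsoil <- soil_spectrum

  if (lai == 0) {
    return(structure(
      tibble::tibble(
        wavelength = wl, reflectance = rsoil, rho_so = rsoil,
        rho_do = rsoil, tau_ss = 1, tau_oo = 1
      ),
      class = c("canopy_rt", "tbl_df", "tbl", "data.frame")
    ))
  }

  tts <- geom$sun_zenith_deg * pi / 180
  tto <- geom$view_zenith_deg * pi / 180
  psi <- geom$rel_azimuth_deg * pi / 180
  cts <- cos(tts)
  cto <- cos(tto)
  ctscto <- cts * cto
  tants <- tan(tts)
  tanto <- tan(tto)
  dso <- sqrt(tants^2 + tanto^2 - 2 * tants * tanto * cos(psi))

  lidf <- leaf_angle_distribution(ala_deg)
  ks <- ko <- bf <- sob <- sof <- 0
  for (i in seq_along(lidf$angles_deg)) {
    ttl <- lidf$angles_deg[i] * pi / 180
    ctl <- cos(ttl)
    vs <- volscatt(tts, tto, psi, ttl)
    f <- lidf$freq[i]
    ks <- ks + f * vs[["chi_s"]] / cts
    ko <- ko + f * vs[["chi_o"]] / cto
    sob <- sob + f * vs[["frho"]] * pi / ctscto
    sof <- sof + f * vs[["ftau"]] * pi / ctscto
    bf <- bf + f * ctl^2
  }
  sdb <- 0.5 * (ks + bf)
  sdf <- 0.5 * (ks - bf)
  dob <- 0.5 * (ko + bf)
  dof <- 0.5 * (ko - bf)
  ddb <- 0.5 * (1 + bf)
  ddf <- 0.5 * (1 - bf)

  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  att <- 1 - sigf
  m <- sqrt(pmax((att + sigb) * (att - sigb), 1e-12))
  sb <- sdb * rho + sdf * tau
  sf <- sdf * rho + sdb * tau
  vb <- dob * rho + dof * tau
  vf <- dof * rho + dob * tau
  w <- sob * rho + sof * tau

  e1 <- exp(-m * lai)
  e2 <- e1^2
  rinf <- (att - m) / sigb
  rinf2 <- rinf^2
  re <- rinf * e1
  denom <- 1 - rinf2 * e2

  j1ks <- jfunc1(ks, m, lai)
  j2ks <- jfunc2(ks, m, lai)
  j1ko <- jfunc1(ko, m, lai)
  j2ko <- jfunc2(ko, m, lai)

  ps <- (sf + sb * rinf) * j1ks
  qs <- (sf * rinf + sb) * j2ks
  pv <- (vf + vb * rinf) * j1ko
  qv <- (vf * rinf + vb) * j2ko

  rdd <- rinf * (1 - e2) / denom
  tdd <- (1 - rinf2) * e1 / denom
  tsd <- (ps - re * qs) / denom
  rsd <- (qs - re * ps) / denom
  tdo <- (pv - re * qv) / denom
  rdo <- (qv - re * pv) / denom

  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)
  z <- jfunc2(ks, ko, lai)
  g1 <- (z - j1ks * too) / (ko + m)
  g2 <- (z - j1ko * tss) / (ks + m)
  tv1 <- (vf * rinf + vb) * g1
  tv2 <- (vf + vb * rinf) * g2
  t1 <- tv1 * (sf + sb * rinf)
  t2 <- tv2 * (sf * rinf + sb)
  t3 <- (rdo * qs + tdo * ps) * rinf
  rsod <- (t1 + t2 - t3) / (1 - rinf2)

  # hot-spot correction of the single-scattering bidirectional term
  alf <- 1e6
  if (hot_spot > 0) alf <- min((dso / hot_spot) * 2 / (ks + ko), 200)
  if (alf < 1e-12) {
    tsstoo <- tss
    sumint <- (1 - tss) / (ks * lai)
  } else {
    fhot <- lai * sqrt(ko * ks)
    x1 <- 0
    y1 <- 0
    f1 <- 1
    fint <- (1 - exp(-alf)) * 0.05
    sumint <- 0
    for (istep in 1:20) {
      x2 <- if (istep < 20) -log(1 - istep * fint) / alf else 1
      y2 <- -(ko + ks) * lai * x2 + fhot * (1 - exp(-alf * x2)) / alf
      f2 <- exp(y2)
      sumint <- sumint + (f2 - f1) * (x2 - x1) / (y2 - y1)
      x1 <- x2
      y1 <- y2
      f1 <- f2
    }
    tsstoo <- f1
  }
  rsos <- w * lai * sumint
  rso <- rsos + rsod

  # add the soil background via the adding equations
  dn <- 1 - rsoil * rdd
  rddt <- rdd + tdd * rsoil * tdd / dn
  rsdt <- rsd + (tsd + tss) * rsoil * tdd / dn
  rdot <- rdo + tdd * rsoil * (tdo + too) / dn
  rsodt <- rsod + ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) * rsoil / dn
  rsost <- rsos + tsstoo * rsoil
  rsot <- rsost + rsodt

  skyl <- geom$diffuse_fraction
  refl <- (1 - skyl) * rsot + skyl * rdot

  structure(
    tibble::tibble(
      wavelength = wl,
      reflectance = pmin(pmax(refl, 0), 1),
      rho_so = pmin(pmax(rsot, 0), 1),
      rho_do = pmin(pmax(rdot, 0), 1),
      tau_ss = tss, tau_oo = too
    ),
    class = c("canopy_rt", "tbl_df", "tbl", "data.frame")
  )
}
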