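#' Canopy scene description for the forest reflectance simulator
#'
#' Collects everything needed to simulate one tree stand: the leaf optical
#' inputs, the single-tree leaf area index, the average leaf inclination, the
#' understory/soil background, and the stand geometry that determines crown
#' cover.  Defaults for the fixed stand parameters follow a typical orchard
#' configuration (500 stems/ha, 2.5 m trees with 2 m crowns, understory LAI
#' 0.1, soil scale 1).
#'
#' @param cab chlorophyll a+b content, ug/cm^2.
#' @param n_structure leaf structure parameter N.
#' @param lai_single_tree single-tree leaf area index, m^2/m^2.
#' @param soil_scale multiplier in `[0, ~1]` on the reference dry-soil
#'   reflectance spectrum.
#' @param ala_deg average leaf inclination angle of the tree canopy, degrees.
#' @param cw,cm,car,cbrown leaf contents passed to [leaf_params()].
#' @param stem_density trees per hectare.
#' @param tree_height m.
#' @param crown_diameter m.
#' @param lai_understory understory leaf area index, m^2/m^2.
#' @param hot_spot hot-spot size parameter.
#' @return An object of class `canopy_scene`.
#' @export
#' @examples
#' canopy_scene(cab = 40, lai_single_tree = 3)
canopy_scene <- function(cab, n_structure = 1.5, lai_single_tree = 3,
                         soil_scale = 1, ala_deg = 30,
                         cw = 0.03, cm = 0.012, car = cab / 4, cbrown = 0,
                         stem_density = 500, tree_height = 2.5,
                         crown_diameter = 2, lai_understory = 0.1,
                         hot_spot = 0.01) {
  leaf <- leaf_params(
    cab = cab, n_structure = n_structure, cw = cw, cm = cm,
    car = car, cbrown = cbrown
  )
  if (lai_single_tree < 0) stop("lai_single_tree must be >= 0", call. = FALSE)
  if (ala_deg < 0 || ala_deg > 90) stop("ala_deg must be in [0, 90]", call. = FALSE)
  if (soil_scale < 0) stop("soil_scale must be >= 0", call. = FALSE)
  if (stem_density < 0 || crown_diameter < 0 || lai_understory < 0) {
    stop("stand parameters must be >= 0", call. = FALSE)
  }
  structure(
    list(
      leaf = leaf, lai_single_tree = lai_single_tree, soil_scale = soil_scale,
      ala_deg = ala_deg, stem_density = stem_density, tree_height = tree_height,
      crown_diameter = crown_diameter, lai_understory = lai_understory,
      hot_spot = hot_spot
    ),
    class = "canopy_scene"
  )
}

#' Crown cover fractions of a stand
#'
#' Vertical crown cover is `stem_density * pi * (crown_diameter/2)^2 / 10000`
#' (stems per hectare times crown ground area), capped at 1; the cover in the
#' sun direction inflates it by `1 / cos(sun_zenith)`, capped at 1.
#'
#' @param scene a [canopy_scene()].
#' @param geom an [rt_geometry()].
#' @return Named numeric vector with `c_view` and `c_sun`.
#' @export
crown_cover <- function(scene, geom) {
  c_view <- min(1, scene$stem_density * pi * (scene$crown_diameter / 2)^2 / 10000)
  c_sun <- min(1, c_view / cos(geom$sun_zenith_deg * pi / 180))
  c(c_view = c_view, c_sun = c_sun)
}

#' Geometric composition of crowns over the background (FLIM step)
#'
#' Mixes the reflectance of an optically infinite crown layer with the
#' background (understory over soil) reflectance through the directional scene
#' transmittances `T_d = 1 - C_d * (1 - tau_d)` for the sun and view
#' directions:
#' `R = rho_inf * (1 - T_s * T_o) + rho_background * T_s * T_o`.
#'
#' @param rho_inf per-wavelength reflectance of an infinitely deep crown layer.
#' @param rho_background per-wavelength understory-over-soil reflectance.
#' @param tau_sun,tau_view directional crown gap fractions (scalars or
#'   per-wavelength vectors) in the sun and view directions.
#' @param scene a [canopy_scene()] (supplies stem density and crown diameter).
#' @param geom an [rt_geometry()].
#' @return Numeric vector of per-wavelength scene reflectance, bounded between
#'   `rho_inf` and `rho_background` at each wavelength.
#' @export
flim_compose <- function(rho_inf, rho_background, tau_sun, tau_view,
                         scene, geom) {
  cc <- crown_cover(scene, geom)
  t_s <- 1 - cc[["c_sun"]] * (1 - tau_sun)
  t_o <- 1 - cc[["c_view"]] * (1 - tau_view)
  g <- t_s * t_o
  rho_inf * (1 - g) + rho_background * g
}

#' Simulate one forest canopy reflectance spectrum
#'
#' Composes the full chain: plate-model leaf optics, SAILH canopy radiative
#' transfer for (a) an optically infinite crown layer, giving `rho_inf`,
#' (b) the single-tree crown, giving the directional gap fractions, and
#' (c) the understory layer over the scaled reference soil, giving the
#' background reflectance; the FLIM step then mixes crowns and background by
#' crown cover.
#'
#' @param scene a [canopy_scene()].
#' @param geom an [rt_geometry()]; default nadir view, 30 degree sun,
#'   diffuse fraction 0.1.
#' @param wavelengths output grid, nm (default 400-1050 at 1 nm).
#' @param lai_infinite leaf area index used for the optically infinite crown
#'   layer (default 15; reflectance is saturated and soil-independent there).
#' @return Tibble with columns `wavelength` and `reflectance`.
#' @export
#' @examples
#' sp <- inform_simulate(canopy_scene(cab = 40, lai_single_tree = 3))
#' range(sp$reflectance)
inform_simulate <- function(scene, geom = rt_geometry(),
                            wavelengths = 400:1050, lai_infinite = 15) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(geom, "rt_geometry"))
  constants <- synthetic_optical_constants(wavelengths)
  lo <- prospect(scene$leaf, wavelengths, constants = constants)
  soil <- scene$soil_scale * synthetic_soil_spectrum(wavelengths)$reflectance

  crown <- sailh(
    lo, scene$lai_single_tree, scene$ala_deg, scene$hot_spot,
    soil, geom
  )
  inf <- sailh(lo, lai_infinite, scene$ala_deg, scene$hot_spot, soil, geom)
  background <- if (scene$lai_understory > 0) {
    sailh(
      lo, scene$lai_understory, scene$ala_deg, scene$hot_spot,
      soil, geom
    )$reflectance
  } else {
    soil
  }

  refl <- flim_compose(
    rho_inf = inf$reflectance, rho_background = background,
    tau_sun = crown$tau_ss, tau_view = crown$tau_oo,
    scene = scene, geom = geom
  )
  tibble::tibble(
    wavelength = as.numeric(wavelengths),
    reflectance = pmin(pmax(refl, 0), 1)
  )
}
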