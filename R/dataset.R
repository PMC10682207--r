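#' Full-factorial parameter grid for the canopy simulator
#'
#' Defines the varied parameters (chlorophyll content, leaf structure,
#' single-tree LAI, soil scale factor, average leaf angle) as
#' (minimum, maximum, step) triples, plus the fixed stand / leaf constants.
#' Defaults regenerate the study grid: Cab 25-50 by 5, N 1-1.5 by 0.5,
#' LAI 1-7 by 1, soil scale 0.6-1 by 0.1, ALA 0-60 by 15 (2100 combinations).
#'
#' @param cab,n_structure,lai,soil_scale,ala numeric `c(min, max, step)`
#'   triples.
#' @param fixed named list of fixed scene parameters passed to
#'   [canopy_scene()] (water, dry matter, stand geometry, hot spot).
#' @return An object of class `parameter_grid`.
#' @export
#' @examples
#' nrow(build_parameter_grid(parameter_grid()))
parameter_grid <- function(cab = c(25, 50, 5),
                           n_structure = c(1, 1.5, 0.5),
                           lai = c(1, 7, 1),
                           soil_scale = c(0.6, 1, 0.1),
                           ala = c(0, 60, 15),
                           fixed = list(
                             cw = 0.03, cm = 0.012,
                             stem_density = 500, tree_height = 2.5,
                             crown_diameter = 2, lai_understory = 0.1,
                             hot_spot = 0.01
                           )) {
  varied <- list(
    cab = cab, n_structure = n_structure, lai = lai,
    soil_scale = soil_scale, ala = ala
  )
  for (nm in names(varied)) {
    v <- varied[[nm]]
    if (length(v) != 3 || v[3] <= 0 || v[2] < v[1]) {
      stop(sprintf("parameter '%s' must be c(min, max, step) with step > 0 and max >= min", nm),
        call. = FALSE
      )
    }
  }
  structure(c(varied, list(fixed = fixed)), class = "parameter_grid")
}

grid_levels <- function(triple) {
  n <- floor((triple[2] - triple[1]) / triple[3] + 1e-9) + 1
  triple[1] + triple[3] * (seq_len(n) - 1)
}

#' Enumerate all scenes of a parameter grid
#'
#' Cartesian product of the per-parameter levels in lexicographic order with
#' `cab` varying slowest and `ala` fastest; deterministic.
#'
#' @param grid a [parameter_grid()].
#' @return A tibble with one row per scene (`sample_id`, `cab`, `n_structure`,
#'   `lai`, `soil_scale`, `ala`).
#' @export
build_parameter_grid <- function(grid = parameter_grid()) {
  stopifnot(inherits(grid, "parameter_grid"))
  scenes <- tidyr::expand_grid(
    cab = grid_levels(grid$cab),
    n_structure = grid_levels(grid$n_structure),
    lai = grid_levels(grid$lai),
    soil_scale = grid_levels(grid$soil_scale),
    ala = grid_levels(grid$ala)
  )
  dplyr::bind_cols(tibble::tibble(sample_id = seq_len(nrow(scenes))), scenes)
}

#' Simulate the full spectra dataset for a parameter grid
#'
#' Runs the forward simulator for every scene of the grid and returns a
#' spectra tibble with the scene parameters as metadata and `cab` as the
#' retrieval target.
#'
#' @param grid a [parameter_grid()].
#' @param geom an [rt_geometry()].
#' @param wavelengths output grid in nm.
#' @return A spectra tibble (see [as_spectra()]) with `nrow` equal to the
#'   number of grid combinations.
#' @export
simulate_dataset <- function(grid = parameter_grid(), geom = rt_geometry(),
                             wavelengths = 400:1050) {
  scenes <- build_parameter_grid(grid)
  fx <- grid$fixed
  spectra <- matrix(NA_real_, nrow(scenes), length(wavelengths))
  for (i in seq_len(nrow(scenes))) {
    sc <- canopy_scene(
      cab = scenes$cab[i], n_structure = scenes$n_structure[i],
      lai_single_tree = scenes$lai[i], soil_scale = scenes$soil_scale[i],
      ala_deg = scenes$ala[i],
      cw = fx$cw, cm = fx$cm, stem_density = fx$stem_density,
      tree_height = fx$tree_height, crown_diameter = fx$crown_diameter,
      lai_understory = fx$lai_understory, hot_spot = fx$hot_spot
    )
    spectra[i, ] <- inform_simulate(sc, geom, wavelengths)$reflectance
  }
  as_spectra(spectra_bind(scenes, spectra, wavelengths))
}

#' Descriptive statistics of a target variable
#'
#' Summary in the shape of a dataset-statistics table row: n, min, quartiles
#' (linear interpolation between order statistics), max, mean, sample standard
#' deviation and coefficient of variation (sd/mean, a ratio).
#'
#' @param values numeric vector (n >= 2).
#' @return A one-row tibble with columns `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' describe_target(rep(c(25, 30, 35, 40, 45, 50), each = 350))
describe_target <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  tibble::tibble(
    n = length(values), min = min(values), q1 = q[1], median = q[2],
    q3 = q[3], max = max(values), mean = m, sd = s, cv = s / m
  )
}

#' Random train/validation split
#'
#' Uniform random permutation split under a seed.  The training size is
#' `round(train_fraction * n)` unless `explicit_counts = c(n_train, n_validation)`
#' is given (used to pin a printed split that is not an exact fraction).
#'
#' @param n number of samples.
#' @param train_fraction fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @param explicit_counts optional `c(n_train, n_validation)` summing to `n`.
#' @return An object of class `lcc_split`: list with integer vectors `train`
#'   and `validation` (1-based, disjoint, covering `1:n`), and the `seed`.
#' @export
#' @examples
#' s <- split_dataset(69, seed = 1)
#' lengths(s[c("train", "validation")])
split_dataset <- function(n, train_fraction = 0.75, seed = 1,
                          explicit_counts = NULL) {
  stopifnot(n >= 2)
  if (is.null(explicit_counts)) {
    if (train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must be in (0, 1)", call. = FALSE)
    }
    n_train <- round(train_fraction * n)
  } else {
    if (length(explicit_counts) != 2 || sum(explicit_counts) != n) {
      stop("explicit_counts must be c(n_train, n_validation) summing to n",
        call. = FALSE
      )
    }
    n_train <- explicit_counts[1]
  }
  perm <- withr::with_seed(seed, sample.int(n))
  structure(
    list(
      train = sort(perm[seq_len(n_train)]),
      validation = sort(perm[seq(n_train + 1, n)]),
      seed = seed
    ),
    class = "lcc_split"
  )
}

#' SPAD to leaf chlorophyll content conversion
#'
#' Affine calibration between the handheld chlorophyll-meter reading (SPAD,
#' unitless) and leaf chlorophyll content (LCC, ug/cm^2):
#' `LCC = 0.709 * SPAD - 1.576`.  `lcc_to_spad()` is the exact inverse.  The
#' calibration extrapolates to negative LCC below SPAD ~ 2.22; a warning is
#' raised there.
#'
#' @param spad,lcc numeric vectors.
#' @return Numeric vector of converted values.
#' @export
#' @examples
#' spad_to_lcc(36)
spad_to_lcc <- function(spad) {
  if (any(spad < 0)) stop("spad must be >= 0", call. = FALSE)
  if (any(spad < 1.576 / 0.709)) {
    warning("SPAD below ~2.22 maps to negative LCC (formula extrapolation)",
      call. = FALSE
    )
  }
  0.709 * spad - 1.576
}

#' @rdname spad_to_lcc
#' @export
lcc_to_spad <- function(lcc) {
  (lcc + 1.576) / 0.709
}
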