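#' Spectra tibbles
#'
#' The common currency of the package is a wide "spectra tibble": one row per
#' sample, a `sample_id` column, any number of metadata columns (e.g. `cab`,
#' `n_structure`, `lai`, `soil_scale`, `ala`, `spad`), and one column per
#' wavelength, named by its integer nanometre value (`"400"`, `"401"`, ...).
#' Reflectance values are fractions in `[0, 1]`; derivative spectra carry a
#' `derivative_order` attribute of 1 or 2.
#'
#' @param x a data frame to validate / coerce.
#' @return `as_spectra()` returns the validated tibble;
#'   `spectra_wavelengths()` the ascending numeric wavelength grid;
#'   `spectra_matrix()` the samples-by-wavelengths numeric matrix.
#' @name spectra
NULL

is_wavelength_name <- function(nm) {
  suppressWarnings(!is.na(as.numeric(nm)))
}

#' @rdname spectra
#' @export
as_spectra <- function(x) {
  x <- tibble::as_tibble(x)
  wl_cols <- names(x)[is_wavelength_name(names(x))]
  if (length(wl_cols) < 2) {
    stop("a spectra tibble needs at least two wavelength columns", call. = FALSE)
  }
  wl <- as.numeric(wl_cols)
  if (anyDuplicated(wl)) stop("duplicate wavelength columns", call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE)) {
    ord <- order(wl)
    meta <- setdiff(names(x), wl_cols)
    x <- x[, c(meta, wl_cols[ord])]
    warning("wavelength columns were not ascending; reordered", call. = FALSE)
  }
  x
}

#' @rdname spectra
#' @export
spectra_wavelengths <- function(x) {
  sort(as.numeric(names(x)[is_wavelength_name(names(x))]))
}

#' @rdname spectra
#' @export
spectra_matrix <- function(x) {
  wl <- spectra_wavelengths(x)
  m <- as.matrix(x[, as.character(wl)])
  storage.mode(m) <- "double"
  rownames(m) <- if ("sample_id" %in% names(x)) as.character(x$sample_id) else NULL
  m
}

# metadata (non-wavelength) part of a spectra tibble
spectra_meta <- function(x) {
  x[, !is_wavelength_name(names(x)), drop = FALSE]
}

# rebuild a spectra tibble from metadata + matrix with wavelength names
spectra_bind <- function(meta, m, wavelengths, derivative_order = NULL) {
  colnames(m) <- as.character(wavelengths)
  out <- dplyr::bind_cols(meta, tibble::as_tibble(m))
  if (!is.null(derivative_order)) {
    attr(out, "derivative_order") <- derivative_order
  }
  out
}

#' Line plot of spectra
#'
#' Draws one line per sample over wavelength, optionally coloured by a
#' metadata column.
#'
#' @param x a spectra tibble.
#' @param colour_by name of a metadata column to map to colour (default the
#'   target-like column `cab`/`spad` if present).
#' @param n_max maximum number of sample curves to draw (random thinning not
#'   applied; the first `n_max` rows are used).
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, colour_by = NULL, n_max = 100) {
  x <- as_spectra(x)
  if (is.null(colour_by)) {
    colour_by <- intersect(c("cab", "spad", "lcc"), names(x))[1]
  }
  x <- utils::head(x, n_max)
  if (!"sample_id" %in% names(x)) x$sample_id <- seq_len(nrow(x))
  long <- tidyr::pivot_longer(
    x,
    cols = dplyr::all_of(as.character(spectra_wavelengths(x))),
    names_to = "wavelength", values_to = "value"
  )
  long$wavelength <- as.numeric(long$wavelength)
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$wavelength, y = .data$value,
      group = .data$sample_id
    )
  ) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
  if (!is.na(colour_by) && !is.null(colour_by)) {
    p <- p + ggplot2::aes(colour = .data[[colour_by]])
  }
  p
}
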