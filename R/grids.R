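#' Wavelength grids
#'
#' A wavelength grid is a strictly increasing, uniformly spaced vector of
#' wavelengths in nanometres. Two grids matter in practice: the simulation
#' grid on which tissue spectra are forward-modelled (300--1000 nm at 2 nm,
#' 351 points) and the camera grid of the imaging system's 100 bands
#' (500--995 nm at 5 nm).
#'
#' @param from,to Range endpoints in nm.
#' @param by Uniform spacing in nm.
#' @return An object of class `wavelength_grid`: a list with `wavelengths_nm`
#'   and `spacing_nm`.
#' @examples
#' g <- wavelength_grid(500, 995, 5)
#' length(g$wavelengths_nm)  # 100
#' @export
wavelength_grid <- function(from, to, by) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(by), by > 0, to > from)
  wl <- seq(from, to, by = by)
  structure(list(wavelengths_nm = wl, spacing_nm = by), class = "wavelength_grid")
}

#' @describeIn wavelength_grid The default simulation grid, 300--1000 nm at 2 nm.
#' @export
sim_grid <- function() wavelength_grid(300, 1000, 2)

#' @describeIn wavelength_grid The default camera grid, 500--995 nm at 5 nm.
#' @export
camera_grid <- function() wavelength_grid(500, 995, 5)

#' @export
print.wavelength_grid <- function(x, ...) {
  wl <- x$wavelengths_nm
  cat(sprintf("<wavelength_grid> %d points, %g-%g nm, step %g nm\n",
              length(wl), wl[1], wl[length(wl)], x$spacing_nm))
  invisible(x)
}

#' Camera digital twin
#'
#' Describes the spectral sampling of the hyperspectral camera: 100 band
#' centers from 500 to 995 nm in 5 nm steps, each with a spectral response
#' function (SRF) of width `band_width_nm`. The default SRF is a boxcar
#' (uniform window) matching the printed 5 nm resolution; a Gaussian
#' alternative (`srf_kind = "gaussian"`, FWHM = `band_width_nm`) is provided.
#'
#' @param band_centers_nm Band center wavelengths; default `camera_grid()`.
#' @param band_width_nm Spectral response width in nm.
#' @param srf_kind `"boxcar"` or `"gaussian"`.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(band_centers_nm = camera_grid()$wavelengths_nm,
                         band_width_nm = 5,
                         srf_kind = c("boxcar", "gaussian")) {
  srf_kind <- match.arg(srf_kind)
  stopifnot(is.numeric(band_centers_nm), band_width_nm > 0)
  if (length(band_centers_nm) != 100L)
    stop("camera model requires 100 bands, got ", length(band_centers_nm))
  steps <- diff(band_centers_nm)
  if (any(abs(steps - steps[1]) > 1e-9) || abs(steps[1] - 5) > 1e-9)
    stop("band centers must be uniformly spaced at 5 nm")
  structure(list(band_centers_nm = band_centers_nm,
                 band_width_nm = band_width_nm,
                 srf_kind = srf_kind),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d bands, %g-%g nm, %s SRF (%g nm)\n",
              length(x$band_centers_nm), min(x$band_centers_nm),
              max(x$band_centers_nm), x$srf_kind, x$band_width_nm))
  invisible(x)
}
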