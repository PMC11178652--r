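#' Tissue absorption coefficient
#'
#' Computes the per-wavelength absorption coefficient (1/cm) of the tissue
#' model from its blood and water content:
#'
#' mua(lambda) = vhb * C_hb * ln(10) * (sto2 * eps_HbO2 + (1 - sto2) * eps_Hb)
#'             + w_water * mua_water(lambda)
#'
#' where `C_hb` is the molar concentration of hemoglobin in whole blood
#' (150 g/L over 64500 g/mol), so that `vhb` reads directly as the blood
#' volume fraction of the tissue.
#'
#' @param params A [tissue_params()] data.frame (N records).
#' @param wavelengths_nm Wavelength vector (nm) or a `wavelength_grid`.
#' @param table A [chromophore_table()].
#' @return N x L matrix of absorption coefficients (1/cm).
#' @export
absorption_coefficient <- function(params, wavelengths_nm, table = chromophore_table()) {
  params <- as_tissue_params(params)
  if (inherits(wavelengths_nm, "wavelength_grid"))
    wavelengths_nm <- wavelengths_nm$wavelengths_nm
  eps_hbo2 <- interp_table(table, "eps_hbo2", wavelengths_nm)
  eps_hb <- interp_table(table, "eps_hb", wavelengths_nm)
  mua_w <- interp_table(table, "mua_water", wavelengths_nm)
  # blood term: outer products give N x L
  eps_mix <- outer(params$sto2, eps_hbo2) + outer(1 - params$sto2, eps_hb)
  mua <- params$vhb * HB_MOLARITY * log(10) * eps_mix + outer(params$w_water, mua_w)
  stopifnot(all(is.finite(mua)), all(mua >= 0))
  mua
}

# whole-blood hemoglobin molarity: 150 g/L / 64500 g/mol
HB_MOLARITY <- 150 / 64500

#' Reduced scattering coefficient
#'
#' Mie-type power law anchored at 500 nm:
#' musp(lambda) = mus500 * (lambda / 500)^(-b_mie).
#'
#' @inheritParams absorption_coefficient
#' @return N x L matrix of reduced scattering coefficients (1/cm).
#' @export
reduced_scattering <- function(params, wavelengths_nm) {
  params <- as_tissue_params(params)
  if (inherits(wavelengths_nm, "wavelength_grid"))
    wavelengths_nm <- wavelengths_nm$wavelengths_nm
  exp(outer(-params$b_mie, log(wavelengths_nm / 500))) * params$mus500
}

# internal-reflection parameter of the diffusion model from the relative
# refractive index (Groenhuis/Egan-Hilgeman empirical fit)
internal_reflection_A <- function(n_refr) {
  r_id <- -1.440 / n_refr^2 + 0.710 / n_refr + 0.668 + 0.0636 * n_refr
  (1 + r_id) / (1 - r_id)
}

#' Diffuse reflectance of a semi-infinite tissue layer
#'
#' Closed-form diffusion-approximation reflectance of a single optically
#' thick layer. With transport albedo a' = musp / (mua + musp) and
#' internal-reflection parameter A(n):
#'
#' R_d = a' / (1 + 2 A (1 - a') + (1 + 2A/3) * sqrt(3 (1 - a')))
#'
#' R_d is 1 for a non-absorbing medium, decreases strictly with absorption
#' at fixed scattering, tends to 0 in the opaque limit, and decreases with
#' the refractive-index mismatch through A.
#'
#' @inheritParams absorption_coefficient
#' @param grid A `wavelength_grid` (default [sim_grid()]).
#' @param mua_override Optional N x L matrix replacing the computed
#'   absorption (hook for sensitivity and limit checks).
#' @return An object of class `reflectance_spectra`: list with `values`
#'   (N x L matrix in \[0,1\]), `grid`, and `normalized = FALSE`.
#' @export
diffuse_reflectance <- function(params, grid = sim_grid(),
                                table = chromophore_table(),
                                mua_override = NULL) {
  params <- as_tissue_params(params)
  wl <- grid$wavelengths_nm
  mua <- if (is.null(mua_override)) absorption_coefficient(params, wl, table)
         else mua_override
  musp <- reduced_scattering(params, wl)
  if (!all(dim(mua) == dim(musp)))
    stop("mua_override must be an N x L matrix matching params and grid")
  albedo <- musp / (mua + musp)
  A <- internal_reflection_A(params$n_refr)  # length N, recycled by column
  refl <- albedo / (1 + 2 * A * (1 - albedo) +
                      (1 + 2 * A / 3) * sqrt(3 * (1 - albedo)))
  if (!all(is.finite(refl)))
    stop("non-finite reflectance encountered in diffusion model")
  structure(list(values = refl, grid = grid, normalized = FALSE),
            class = "reflectance_spectra")
}

#' @export
print.reflectance_spectra <- function(x, ...) {
  cat(sprintf("<reflectance_spectra> %d spectra x %d bands (%g-%g nm)%s\n",
              nrow(x$values), ncol(x$values), min(x$grid$wavelengths_nm),
              max(x$grid$wavelengths_nm),
              if (isTRUE(x$normalized)) ", L1-normalized" else ""))
  invisible(x)
}

#' Resample spectra through the camera digital twin
#'
#' Projects simulation-grid spectra onto the camera's 100 bands by averaging
#' the input spectrum under each band's spectral response function. The
#' operation is linear in the input, preserves constants exactly, and each
#' output lies within the range of the input samples under its band window.
#'
#' @param spec A `reflectance_spectra` object (or bare N x L matrix with
#'   `grid` supplied).
#' @param cam A [camera_model()].
#' @param grid Required when `spec` is a bare matrix.
#' @return `reflectance_spectra` on the camera grid (N x 100).
#' @export
resample_to_camera <- function(spec, cam = camera_model(), grid = NULL) {
  if (inherits(spec, "reflectance_spectra")) {
    values <- spec$values
    grid <- spec$grid
  } else {
    values <- as.matrix(spec)
    if (is.null(grid)) stop("grid required for bare matrix input")
  }
  W <- srf_weights(cam, grid)
  out <- values %*% W
  out_grid <- wavelength_grid(cam$band_centers_nm[1],
                              cam$band_centers_nm[length(cam$band_centers_nm)],
                              diff(cam$band_centers_nm)[1])
  structure(list(values = out, grid = out_grid, normalized = FALSE),
            class = "reflectance_spectra")
}

# L x 100 matrix of band-response weights; each column sums to 1
srf_weights <- function(cam, grid) {
  wl <- grid$wavelengths_nm
  centers <- cam$band_centers_nm
  half <- cam$band_width_nm / 2
  W <- matrix(0, length(wl), length(centers))
  for (b in seq_along(centers)) {
    if (cam$srf_kind == "boxcar") {
      w <- as.numeric(abs(wl - centers[b]) <= half + 1e-9)
    } else {
      sd <- cam$band_width_nm / (2 * sqrt(2 * log(2)))  # FWHM -> sd
      w <- exp(-(wl - centers[b])^2 / (2 * sd^2))
      w[abs(wl - centers[b]) > 3 * cam$band_width_nm] <- 0
    }
    if (sum(w) == 0)
      stop(sprintf("camera band %g nm not covered by the input grid", centers[b]))
    # a band whose window is truncated by the grid edge would extrapolate
    if (centers[b] - half < min(wl) - 1e-9 || centers[b] + half > max(wl) + 1e-9)
      stop(sprintf("camera band %g nm exceeds input grid coverage", centers[b]))
    W[, b] <- w / sum(w)
  }
  W
}

#' L1 normalization
#'
#' Scales a non-negative spectrum (or each row of a matrix of spectra) so
#' its absolute values sum to one. The direction of the vector is preserved;
#' an all-zero spectrum is rejected.
#'
#' @param x Numeric vector, or matrix with one spectrum per row.
#' @return Same shape as `x`, rows summing to 1.
#' @examples
#' l1_normalize(c(2, 2))  # 0.5 0.5
#' @export
l1_normalize <- function(x) {
  if (is.matrix(x)) {
    s <- rowSums(abs(x))
    if (any(s == 0)) stop("cannot L1-normalize an all-zero spectrum (row ",
                          which(s == 0)[1], ")")
    return(x / s)
  }
  s <- sum(abs(x))
  if (s == 0) stop("cannot L1-normalize an all-zero spectrum")
  x / s
}
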