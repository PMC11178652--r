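#' Chromophore extinction and absorption table
#'
#' Loads the bundled table of molar extinction coefficients of oxy- and
#' deoxyhemoglobin (cm^-1/M) and the absorption coefficient of pure water
#' (1/cm) on the 300--1000 nm simulation grid. The bundled file
#' `chromophores_synthetic.tsv` is a smooth synthetic approximation of the
#' standard literature curves: it is anchored at the classic band positions
#' (Soret band, the oxyhemoglobin 542/576 nm double peak, the deoxyhemoglobin
#' 555 and 760 nm bands, the near-infrared water rise) and at the classic
#' isosbestic wavelengths (~498, 529, 545, 570, 584 and 797 nm), and
#' interpolated monotonically between anchors. It reproduces the magnitudes
#' and crossing structure the pipeline depends on, not digitized laboratory
#' values.
#'
#' @param path Optional path to an alternative tab-separated table with
#'   columns `wavelength_nm`, `eps_hbo2`, `eps_hb`, `mua_water`.
#' @return A data.frame of class `chromophore_table`.
#' @export
chromophore_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chromophores_synthetic.tsv",
                        package = "hsitta", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb", "mua_water")
  if (!all(need %in% names(tab)))
    stop("chromophore table must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE))
    stop("chromophore table wavelengths must be strictly increasing")
  if (any(tab[, c("eps_hbo2", "eps_hb", "mua_water")] < 0))
    stop("chromophore table values must be non-negative")
  class(tab) <- c("chromophore_table", "data.frame")
  tab
}

# Linear interpolation of a table column at arbitrary wavelengths; errors
# outside coverage, naming the offending wavelength.
interp_table <- function(table, column, wavelengths_nm) {
  rng <- range(table$wavelength_nm)
  bad <- wavelengths_nm < rng[1] | wavelengths_nm > rng[2]
  if (any(bad))
    stop(sprintf("wavelength %g nm outside chromophore table coverage [%g, %g]",
                 wavelengths_nm[which(bad)[1]], rng[1], rng[2]))
  stats::approx(table$wavelength_nm, table[[column]], xout = wavelengths_nm,
                method = "linear", rule = 1)$y
}

#' Locate isosbestic wavelengths
#'
#' Finds wavelengths where the (linearly interpolated) oxy- and
#' deoxyhemoglobin extinction curves cross. At such a wavelength the blood
#' absorption coefficient is independent of oxygen saturation, so simulated
#' reflectance there is invariant to StO2.
#'
#' @param table A [chromophore_table()].
#' @param range Wavelength window in nm to search, default the camera range.
#' @return Numeric vector of crossing wavelengths (nm), possibly empty.
#' @export
find_isosbestic <- function(table, range = c(500, 995)) {
  stopifnot(inherits(table, "chromophore_table"))
  wl <- table$wavelength_nm
  keep <- wl >= range[1] & wl <= range[2]
  wl <- wl[keep]
  d <- table$eps_hbo2[keep] - table$eps_hb[keep]
  out <- wl[d == 0]
  sw <- which(d[-length(d)] * d[-1] < 0)
  if (length(sw)) {
    # linear interpolants cross where the difference line hits zero
    lam <- wl[sw] - d[sw] * (wl[sw + 1] - wl[sw]) / (d[sw + 1] - d[sw])
    out <- c(out, lam)
  }
  sort(unique(out))
}
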