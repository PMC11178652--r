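#' Tissue parameter vectors
#'
#' The simulation parameter space of the generic tissue model. Each record
#' holds oxygen saturation `sto2` (fraction of hemoglobin that is
#' oxygenated), blood volume fraction `vhb`, reduced scattering at 500 nm
#' `mus500` (1/cm), scattering power `b_mie` (dimensionless Mie-type
#' exponent), anisotropy `g`, refractive index `n_refr`, layer thickness
#' `d_cm` (cm) and water volume fraction `w_water`. Values outside the
#' admissible ranges are rejected at construction.
#'
#' `g` and `d_cm` are carried for completeness (a photon-transport backend
#' would use them) but are not consumed by the diffusion-approximation
#' forward model, which works in reduced-scattering terms on a single
#' optically thick layer.
#'
#' @param sto2,vhb,mus500,b_mie,g,n_refr,d_cm,w_water Numeric vectors
#'   (recycled to a common length).
#' @return A data.frame of class `tissue_params`, one row per record.
#' @examples
#' tissue_params(sto2 = 0.7, vhb = 0.05)
#' @export
tissue_params <- function(sto2 = 0.6, vhb = 0.04, mus500 = 20, b_mie = 1.2,
                          g = 0.9, n_refr = 1.4, d_cm = 0.1, w_water = 0.85) {
  p <- data.frame(sto2 = sto2, vhb = vhb, mus500 = mus500, b_mie = b_mie,
                  g = g, n_refr = n_refr, d_cm = d_cm, w_water = w_water)
  validate_tissue_params(p)
  class(p) <- c("tissue_params", "data.frame")
  p
}

#' Admissible parameter ranges
#'
#' Default bounds of the tissue parameter space: StO2 0--1, VHb 0--0.3,
#' reduced scattering at 500 nm 5--50 1/cm, scattering power 0.3--3,
#' anisotropy 0.8--0.95, refractive index 1.33--1.54, thickness 0.002--0.2 cm,
#' water content 0.8--0.9.
#'
#' @return Named list of `c(lo, hi)` bounds per parameter.
#' @export
param_ranges <- function() {
  list(sto2 = c(0, 1), vhb = c(0, 0.3), mus500 = c(5, 50), b_mie = c(0.3, 3),
       g = c(0.8, 0.95), n_refr = c(1.33, 1.54), d_cm = c(0.002, 0.2),
       w_water = c(0.8, 0.9))
}

param_names <- function() names(param_ranges())

validate_tissue_params <- function(p) {
  rng <- param_ranges()
  for (nm in names(rng)) {
    v <- p[[nm]]
    if (is.null(v) || anyNA(v) || !is.numeric(v))
      stop("tissue_params: missing or non-numeric field '", nm, "'")
    if (any(v < rng[[nm]][1] - 1e-12) || any(v > rng[[nm]][2] + 1e-12))
      stop(sprintf("tissue_params: '%s' outside admissible range [%g, %g]",
                   nm, rng[[nm]][1], rng[[nm]][2]))
  }
  invisible(p)
}

as_tissue_params <- function(p) {
  p <- as.data.frame(p)[param_names()]
  validate_tissue_params(p)
  class(p) <- c("tissue_params", "data.frame")
  p
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> %d record(s)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
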