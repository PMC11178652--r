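#' Hyperspectral image cube
#'
#' An H x W x B reflectance cube on the camera wavelength grid (B = 100
#' bands by default), with subject/image identifiers and an L1-normalization
#' flag. When `normalized` is TRUE every pixel spectrum must sum to one
#' (within 1e-6), matching the input contract of the frozen segmentation
#' model.
#'
#' @param values Numeric H x W x B array, finite.
#' @param grid A `wavelength_grid` (default [camera_grid()]).
#' @param subject_id,image_id Identifiers carried through the pipeline.
#' @param normalized Logical; whether pixels are L1-normalized.
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(values, grid = camera_grid(), subject_id = "s1",
                     image_id = "i1", normalized = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("cube values must be finite")
  if (dim(values)[3] != length(grid$wavelengths_nm))
    stop("cube has ", dim(values)[3], " bands but grid has ",
         length(grid$wavelengths_nm))
  if (isTRUE(normalized)) {
    sums <- apply(abs(values), c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-6))
      stop("normalized flag set but pixel sums deviate from 1 by up to ",
           format(max(abs(sums - 1))))
  }
  structure(list(values = values, grid = grid,
                 dim = dim(values), subject_id = subject_id,
                 image_id = image_id, normalized = isTRUE(normalized)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  cat(sprintf("<hsi_cube> %d x %d x %d [%s/%s]%s\n", x$dim[1], x$dim[2],
              x$dim[3], x$subject_id, x$image_id,
              if (x$normalized) ", L1-normalized" else ""))
  invisible(x)
}

# flatten an hsi_cube to a (H*W) x B pixel matrix, row-major over (row, col)
# pairs in R's column-major pixel order
cube_pixels <- function(cube) {
  d <- cube$dim
  matrix(cube$values, d[1] * d[2], d[3])
}

# inverse of cube_pixels
pixels_to_cube <- function(px, cube, normalized = cube$normalized) {
  d <- cube$dim
  hsi_cube(array(px, d), grid = cube$grid, subject_id = cube$subject_id,
           image_id = cube$image_id, normalized = normalized)
}

#' L1-normalize a cube
#'
#' Returns a copy of the cube with every pixel spectrum scaled to unit
#' absolute sum and the `normalized` flag set.
#'
#' @param cube An `hsi_cube`.
#' @return An `hsi_cube` with `normalized = TRUE`.
#' @export
normalize_cube <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (isTRUE(cube$normalized)) return(cube)
  pixels_to_cube(l1_normalize(cube_pixels(cube)), cube, normalized = TRUE)
}
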