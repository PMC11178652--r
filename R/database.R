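#' Sample tissue parameters
#'
#' Draws `n` tissue parameter records, each field independently uniform
#' within its bounds. The sampler covers the full admissible space by
#' default — including extreme perfusion states (StO2 0--100%, VHb 0--30%)
#' that physiological training data never shows.
#'
#' @param n Number of records.
#' @param ranges Named list of `c(lo, hi)` bounds per parameter; must lie
#'   within [param_ranges()].
#' @param seed Integer seed; the draw is reproducible.
#' @return A [tissue_params()] data.frame with `n` rows.
#' @export
sample_params <- function(n, ranges = param_ranges(), seed = 1L) {
  stopifnot(n >= 1)
  full <- param_ranges()
  if (!all(param_names() %in% names(ranges)))
    stop("ranges must name all parameters: ", paste(param_names(), collapse = ", "))
  for (nm in param_names()) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] ||
        r[1] < full[[nm]][1] - 1e-12 || r[2] > full[[nm]][2] + 1e-12)
      stop(sprintf("sampling bounds for '%s' outside admissible range [%g, %g]",
                   nm, full[[nm]][1], full[[nm]][2]))
  }
  cols <- with_seed(seed, lapply(param_names(), function(nm) {
    r <- ranges[[nm]]
    stats::runif(n, r[1], r[2])
  }))
  names(cols) <- param_names()
  p <- as.data.frame(cols)
  class(p) <- c("tissue_params", "data.frame")
  p
}

# evaluate `code` under a local RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Build the synthetic spectral database
#'
#' Forward-simulates `n` parameter records on the simulation grid
#' (300--1000 nm at 2 nm), resamples each spectrum through the camera
#' digital twin, L1-normalizes the camera-space spectra, and attaches the
#' exact nearest-neighbor index (precomputed squared row norms). The default
#' database size follows the reference pipeline (500,000 records); tests and
#' examples use far smaller databases.
#'
#' @param n Number of records (default 500000).
#' @param ranges Sampling bounds, as in [sample_params()].
#' @param cam A [camera_model()].
#' @param table A [chromophore_table()].
#' @param seed Integer seed.
#' @param keep_raw Keep the N x 351 simulation-grid spectra (default TRUE).
#' @return An object of class `spectral_db`: list with `params`,
#'   `spectra_cam` (N x 100, rows L1-normalized), `spectra_raw` (or NULL),
#'   `index` (squared row norms), and `meta` (seed, ranges, grids, metric).
#' @export
build_database <- function(n = 500000L, ranges = param_ranges(),
                           cam = camera_model(), table = chromophore_table(),
                           seed = 1L, keep_raw = TRUE) {
  params <- sample_params(n, ranges, seed)
  raw <- diffuse_reflectance(params, sim_grid(), table)
  cam_spec <- resample_to_camera(raw, cam)
  spectra_cam <- l1_normalize(cam_spec$values)
  db <- structure(list(
    params = params,
    spectra_cam = spectra_cam,
    spectra_raw = if (keep_raw) raw$values else NULL,
    index = rowSums(spectra_cam^2),
    meta = list(seed = as.integer(seed), n = as.integer(n), ranges = ranges,
                sim_grid = sim_grid()$wavelengths_nm,
                cam_grid = cam$band_centers_nm,
                srf = cam$srf_kind, metric = "euclidean-L1norm",
                created = "hsitta build_database")
  ), class = "spectral_db")
  db
}

#' @export
print.spectral_db <- function(x, ...) {
  cat(sprintf("<spectral_db> %d records, %d camera bands%s, seed %d\n",
              nrow(x$spectra_cam), ncol(x$spectra_cam),
              if (!is.null(x$spectra_raw)) sprintf(", %d raw bands", ncol(x$spectra_raw)) else "",
              x$meta$seed))
  invisible(x)
}

# Exact nearest neighbor of each query row among db rows (optionally a
# subset), via blocked d^2 = |q|^2 + |d|^2 - 2 q.d with BLAS crossprod.
# which.min breaks ties at the lowest record id. The reported distance is
# recomputed directly as sqrt(sum((q - d)^2)) for the winner so that it is
# bit-identical to a naive scan.
nn_search <- function(queries, db, subset = NULL, block = 256L) {
  queries <- if (is.matrix(queries)) queries else matrix(queries, nrow = 1)
  if (ncol(queries) != ncol(db$spectra_cam))
    stop("query length ", ncol(queries), " does not match database bands ",
         ncol(db$spectra_cam))
  if (is.null(subset)) {
    spectra <- db$spectra_cam
    norms <- db$index
    ids <- seq_len(nrow(spectra))
  } else {
    if (length(subset) == 0) stop("empty candidate subset")
    subset <- sort(unique(as.integer(subset)))
    spectra <- db$spectra_cam[subset, , drop = FALSE]
    norms <- db$index[subset]
    ids <- subset
  }
  nq <- nrow(queries)
  out_id <- integer(nq)
  out_d <- numeric(nq)
  for (start in seq(1L, nq, by = block)) {
    idx <- start:min(start + block - 1L, nq)
    Q <- queries[idx, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), norms, "+") - 2 * tcrossprod(Q, spectra)
    local <- max.col(-d2, ties.method = "first")
    out_id[idx] <- ids[local]
    for (j in seq_along(idx)) {
      out_d[idx[j]] <- sqrt(sum((Q[j, ] - spectra[local[j], ])^2))
    }
  }
  list(id = out_id, distance = out_d)
}

#' Nearest synthetic spectrum
#'
#' Exact nearest-neighbor lookup of a camera-space L1-normalized query
#' spectrum in the synthetic database (Euclidean metric on L1-normalized
#' spectra). Ties are broken deterministically at the lowest record id.
#'
#' @param query Numeric vector of length 100 (one spectrum), or a matrix
#'   with one query per row.
#' @param db A `spectral_db`.
#' @param subset Optional integer vector restricting the candidate records.
#' @return List with `id` and `distance` (vectors, one entry per query).
#' @export
nearest_spectrum <- function(query, db, subset = NULL) {
  stopifnot(inherits(db, "spectral_db"))
  nn_search(query, db, subset)
}

#' Convert a hyperspectral image to its tissue digital twin
#'
#' Matches every pixel spectrum to its nearest synthetic database record and
#' reads off that record's tissue parameters. The result annotates the image
#' with per-pixel StO2 and VHb maps plus the matched record ids and spectral
#' distances.
#'
#' @param cube An `hsi_cube` (see [hsi_cube()]); normalized internally if
#'   its `normalized` flag is unset.
#' @param db A `spectral_db`.
#' @return An object of class `twin_map`: list with H x W matrices
#'   `record_id`, `sto2`, `vhb`, `distance`, plus `dim` and ids.
#' @export
generate_twin <- function(cube, db) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(db, "spectral_db"))
  px <- cube_pixels(cube)
  if (!all(is.finite(px))) {
    bad <- which(!apply(is.finite(px), 1, all))[1]
    rc <- arrayInd(bad, cube$dim[1:2])
    stop(sprintf("non-finite pixel spectrum at (%d, %d)", rc[1], rc[2]))
  }
  if (!isTRUE(cube$normalized)) px <- l1_normalize(px)
  nn <- nn_search(px, db)
  h <- cube$dim[1]; w <- cube$dim[2]
  structure(list(
    record_id = matrix(nn$id, h, w),
    sto2 = matrix(db$params$sto2[nn$id], h, w),
    vhb = matrix(db$params$vhb[nn$id], h, w),
    distance = matrix(nn$distance, h, w),
    dim = c(h, w), subject_id = cube$subject_id, image_id = cube$image_id
  ), class = "twin_map")
}

#' @export
print.twin_map <- function(x, ...) {
  cat(sprintf("<twin_map> %d x %d; StO2 median %.3f, VHb median %.3f\n",
              x$dim[1], x$dim[2], stats::median(x$sto2), stats::median(x$vhb)))
  invisible(x)
}

#' Save / load a synthetic database
#'
#' Serializes a `spectral_db` to a directory of flat little-endian float64
#' binary arrays plus a JSON metadata file (`meta.json` records the seed,
#' sampling ranges, grids, metric and array shapes). The format is
#' deliberately language-portable: any numeric environment can memory-map
#' the arrays from the shapes in the metadata.
#'
#' @param db A `spectral_db`.
#' @param path Directory to create (overwritten if present).
#' @return `save_database` returns `path` invisibly; `load_database` the
#'   reconstructed `spectral_db`.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "spectral_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_f64 <- function(m, file)
    writeBin(as.vector(t(m)), file.path(path, file), size = 8, endian = "little")
  write_f64(as.matrix(as.data.frame(db$params)), "params.f64")
  write_f64(db$spectra_cam, "spectra_cam.f64")
  shapes <- list(params = dim(db$params), spectra_cam = dim(db$spectra_cam))
  if (!is.null(db$spectra_raw)) {
    write_f64(db$spectra_raw, "spectra_raw.f64")
    shapes$spectra_raw <- dim(db$spectra_raw)
  }
  meta <- c(db$meta, list(shapes = shapes, param_names = param_names(),
                          order = "row-major", dtype = "float64-le"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  read_f64 <- function(file, shape) {
    v <- readBin(file.path(path, file), "double", n = prod(shape), size = 8,
                 endian = "little")
    matrix(v, shape[1], shape[2], byrow = TRUE)
  }
  pm <- read_f64("params.f64", meta$shapes$params)
  colnames(pm) <- meta$param_names
  params <- as_tissue_params(as.data.frame(pm))
  spectra_cam <- read_f64("spectra_cam.f64", meta$shapes$spectra_cam)
  spectra_raw <- if (!is.null(meta$shapes$spectra_raw))
    read_f64("spectra_raw.f64", meta$shapes$spectra_raw) else NULL
  ranges <- lapply(meta$ranges, as.numeric)
  meta_out <- list(seed = meta$seed, n = meta$n, ranges = ranges,
                   sim_grid = meta$sim_grid, cam_grid = meta$cam_grid,
                   srf = meta$srf, metric = meta$metric, created = meta$created)
  structure(list(params = params, spectra_cam = spectra_cam,
                 spectra_raw = spectra_raw, index = rowSums(spectra_cam^2),
                 meta = meta_out), class = "spectral_db")
}
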