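#' Read and write hyperspectral cubes (ENVI format)
#'
#' Cubes are stored as an ENVI header (`.hdr`, plain text) plus a raw
#' binary file, band-sequential (BSQ) order, 64-bit little-endian floats so
#' round-trips are bit-exact. The header carries the wavelength list and
#' the subject/image identifiers and normalization flag as metadata.
#' Reading validates the declared band count (100 expected) and that the
#' wavelengths are 500...995 at 5 nm unless `allow_any_grid` is set.
#'
#' @param cube An `hsi_cube`.
#' @param path Path without extension (writes `path.hdr` + `path.raw`), or
#'   either file's path when reading.
#' @param allow_any_grid Accept wavelength grids other than the 100-band
#'   camera default.
#' @return `read_cube` returns an `hsi_cube`; `write_cube` its `path`,
#'   invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  path <- sub("\\.(hdr|raw)$", "", path)
  d <- cube$dim
  hdr <- c(
    "ENVI",
    "description = {hsitta hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$wavelengths_nm, trim = TRUE), collapse = ", ")),
    sprintf("subject id = %s", cube$subject_id),
    sprintf("image id = %s", cube$image_id),
    sprintf("l1 normalized = %d", as.integer(cube$normalized)))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, within band row-major (line, then sample)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube$values[, , b])), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, allow_any_grid = FALSE) {
  path <- sub("\\.(hdr|raw)$", "", path)
  hdr_lines <- readLines(paste0(path, ".hdr"))
  get_field <- function(key, required = TRUE) {
    hit <- grep(paste0("^", key, " *="), hdr_lines, value = TRUE)
    if (!length(hit)) {
      if (required) stop("ENVI header missing field '", key, "'")
      return(NULL)
    }
    trimws(sub("^[^=]*= *", "", hit[1]))
  }
  lines_n <- as.integer(get_field("lines"))
  samples <- as.integer(get_field("samples"))
  bands <- as.integer(get_field("bands"))
  if (as.integer(get_field("data type")) != 5L)
    stop("only ENVI data type 5 (float64) is supported")
  if (tolower(get_field("interleave")) != "bsq")
    stop("only BSQ interleave is supported")
  wl_txt <- paste(hdr_lines[grep("wavelength *= *\\{", hdr_lines):length(hdr_lines)],
                  collapse = " ")
  wl_txt <- sub(".*wavelength *= *\\{", "", wl_txt)
  wl_txt <- sub("\\}.*", "", wl_txt)
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  if (length(wl) != bands)
    stop("header declares ", bands, " bands but lists ", length(wl),
         " wavelengths")
  if (!allow_any_grid) {
    expect <- camera_grid()$wavelengths_nm
    if (bands != 100L)
      stop("expected 100 bands (500-995 nm at 5 nm), header declares ", bands,
           "; use allow_any_grid = TRUE to override")
    if (max(abs(wl - expect)) > 1e-6)
      stop("header wavelengths differ from 500...995 at 5 nm; ",
           "use allow_any_grid = TRUE to override")
  }
  n <- lines_n * samples * bands
  raw_path <- paste0(path, ".raw")
  if (file.size(raw_path) != 8 * n)
    stop("raw file size does not match header dimensions")
  v <- readBin(raw_path, "double", n = n, size = 8, endian = "little")
  vals <- array(NA_real_, c(lines_n, samples, bands))
  per_band <- lines_n * samples
  for (b in seq_len(bands)) {
    band <- v[((b - 1) * per_band + 1):(b * per_band)]
    vals[, , b] <- matrix(band, lines_n, samples, byrow = TRUE)
  }
  spacing <- if (bands > 1) wl[2] - wl[1] else 1
  hsi_cube(vals, grid = wavelength_grid(wl[1], wl[bands], spacing),
           subject_id = get_field("subject id", required = FALSE) %||% "s?",
           image_id = get_field("image id", required = FALSE) %||% "i?",
           normalized = identical(get_field("l1 normalized", required = FALSE), "1"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write label masks (8-bit PNG)
#'
#' Label masks are stored as 8-bit grayscale PNG with the integer label in
#' the pixel value (labels must lie in 0...255).
#'
#' @param mask Integer label matrix.
#' @param path PNG file path.
#' @return `read_mask` returns an integer matrix; the writer its path,
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 255),
            all(mask == round(mask)))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write / read a labeled scene
#'
#' A scene is stored as an ENVI cube (`<stem>.hdr`/`.raw`), an 8-bit PNG
#' mask (`<stem>_mask.png`) and a JSON sidecar (`<stem>.json`) with the
#' ground-truth per-pixel tissue parameters and provenance.
#'
#' @param scene A `labeled_scene`.
#' @param stem Path stem (no extension).
#' @return `read_scene` returns a `labeled_scene`; the writer its stem,
#'   invisibly.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "labeled_scene"))
  write_cube(scene$cube, stem)
  write_mask(scene$mask, paste0(stem, "_mask.png"))
  side <- list(subject_id = scene$subject_id, image_id = scene$image_id,
               state = scene$state, organ = scene$organ,
               class_labels = as.list(scene$class_labels),
               true_params = as.data.frame(scene$true_params))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  cube <- read_cube(stem)
  mask <- read_mask(paste0(stem, "_mask.png"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(cube = cube, mask = mask,
                 true_params = as_tissue_params(side$true_params),
                 class_labels = unlist(side$class_labels),
                 organ = side$organ, subject_id = side$subject_id,
                 image_id = side$image_id, state = side$state),
            class = "labeled_scene")
}
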