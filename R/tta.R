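#' Physiological reference statistics
#'
#' Pools the retrieved per-pixel StO2 and VHb values of a collection of
#' digital twins of physiological images and reduces each parameter to its
#' median and a pair of percentile bounds. Two settings are used in
#' practice: a conservative (5, 95) in-distribution range and a
#' comprehensive (25, 75) interquartile range. Percentiles use linear
#' interpolation between order statistics (R's `quantile` type 7),
#' documented and fixed so results are convention-stable.
#'
#' @param twins A `twin_map` or list of `twin_map`s from physiological
#'   images.
#' @param percentile_pair Numeric pair of lower/upper percentiles, e.g.
#'   `c(25, 75)` (default) or `c(5, 95)`.
#' @return An object of class `physio_stats`: medians, bounds and the
#'   percentile pair.
#' @export
fit_physio_stats <- function(twins, percentile_pair = c(25, 75)) {
  if (inherits(twins, "twin_map")) twins <- list(twins)
  if (length(twins) == 0) stop("empty collection of twin maps")
  stopifnot(all(vapply(twins, inherits, TRUE, "twin_map")),
            length(percentile_pair) == 2,
            percentile_pair[1] < percentile_pair[2])
  sto2 <- unlist(lapply(twins, function(t) as.vector(t$sto2)))
  vhb <- unlist(lapply(twins, function(t) as.vector(t$vhb)))
  q <- function(x, p) unname(stats::quantile(x, p / 100, type = 7))
  structure(list(
    median_sto2 = stats::median(sto2), median_vhb = stats::median(vhb),
    lo_sto2 = q(sto2, percentile_pair[1]), hi_sto2 = q(sto2, percentile_pair[2]),
    lo_vhb = q(vhb, percentile_pair[1]), hi_vhb = q(vhb, percentile_pair[2]),
    percentile_pair = percentile_pair,
    n_pixels = length(sto2), n_images = length(twins)
  ), class = "physio_stats")
}

#' @export
print.physio_stats <- function(x, ...) {
  cat(sprintf(paste0("<physio_stats> (%g, %g) percentiles over %d pixels\n",
                     "  StO2: median %.3f, in-distribution [%.3f, %.3f]\n",
                     "  VHb : median %.3f, in-distribution [%.3f, %.3f]\n"),
              x$percentile_pair[1], x$percentile_pair[2], x$n_pixels,
              x$median_sto2, x$lo_sto2, x$hi_sto2,
              x$median_vhb, x$lo_vhb, x$hi_vhb))
  invisible(x)
}

#' Save / load physiological statistics as JSON
#' @param stats A `physio_stats` object.
#' @param path JSON file path.
#' @return `read_physio_stats` returns the `physio_stats`; the writer its
#'   path, invisibly.
#' @export
write_physio_stats <- function(stats, path) {
  stopifnot(inherits(stats, "physio_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_physio_stats
#' @export
read_physio_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$percentile_pair <- as.numeric(x$percentile_pair)
  structure(x, class = "physio_stats")
}

#' Detect out-of-distribution perfusion pixels
#'
#' A pixel is out-of-distribution (OOD) iff its retrieved StO2 lies outside
#' `[lo_sto2, hi_sto2]` OR its retrieved VHb lies outside `[lo_vhb,
#' hi_vhb]`; a pixel is in-distribution only when both values lie within
#' their reference ranges. Boundary values count as in-distribution.
#'
#' @param twin A `twin_map`.
#' @param stats A `physio_stats`.
#' @return An object of class `ood_mask`: logical H x W matrix `flags`
#'   (TRUE = OOD).
#' @export
detect_ood <- function(twin, stats) {
  stopifnot(inherits(twin, "twin_map"), inherits(stats, "physio_stats"))
  flags <- twin$sto2 < stats$lo_sto2 | twin$sto2 > stats$hi_sto2 |
    twin$vhb < stats$lo_vhb | twin$vhb > stats$hi_vhb
  structure(list(flags = flags, dim = twin$dim), class = "ood_mask")
}

#' @export
print.ood_mask <- function(x, ...) {
  cat(sprintf("<ood_mask> %d x %d, %.1f%% OOD\n", x$dim[1], x$dim[2],
              100 * mean(x$flags)))
  invisible(x)
}

#' Median-constrained replacement pool
#'
#' Indices of database records whose StO2 and VHb lie within box tolerances
#' of the physiological medians. If the box is empty, both tolerances are
#' doubled until at least one record qualifies (each widening is logged via
#' `message`), so the pool is nonempty for any nonempty database.
#'
#' @param db A `spectral_db`.
#' @param stats A `physio_stats`.
#' @param tol_sto2,tol_vhb Box half-widths around the medians.
#' @return Integer vector of record indices (attribute `widenings` counts
#'   tolerance doublings).
#' @export
select_replacement_pool <- function(db, stats, tol_sto2 = 0.05, tol_vhb = 0.02) {
  stopifnot(inherits(db, "spectral_db"), inherits(stats, "physio_stats"),
            tol_sto2 > 0, tol_vhb > 0)
  widenings <- 0L
  repeat {
    pool <- which(abs(db$params$sto2 - stats$median_sto2) <= tol_sto2 &
                    abs(db$params$vhb - stats$median_vhb) <= tol_vhb)
    if (length(pool) > 0) break
    tol_sto2 <- tol_sto2 * 2
    tol_vhb <- tol_vhb * 2
    widenings <- widenings + 1L
    message(sprintf("replacement pool empty; widening tolerances to (%.4g, %.4g)",
                    tol_sto2, tol_vhb))
  }
  attr(pool, "widenings") <- widenings
  pool
}

#' Hybrid test-time augmentation of an image
#'
#' Leaves in-distribution pixels untouched (bit-exact) and replaces each OOD
#' pixel by the L1-normalized arithmetic mean of its (L1-normalized) real
#' spectrum and the nearest synthetic spectrum drawn from the
#' median-constrained replacement pool. The output cube carries the
#' normalized flag, preserving the frozen model's input contract.
#'
#' @param cube An `hsi_cube` (L1-normalized; normalized internally
#'   otherwise).
#' @param twin The cube's `twin_map` (unused beyond shape checks when
#'   `ood` is supplied, kept for provenance).
#' @param ood An `ood_mask` from [detect_ood()].
#' @param db A `spectral_db`.
#' @param stats A `physio_stats`.
#' @param pool Optional precomputed replacement pool
#'   ([select_replacement_pool()] is called otherwise).
#' @param tol_sto2,tol_vhb Tolerances forwarded to the pool selection.
#' @return The hybrid `hsi_cube` (normalized).
#' @export
augment_image <- function(cube, twin, ood, db, stats, pool = NULL,
                          tol_sto2 = 0.05, tol_vhb = 0.02) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(ood, "ood_mask"),
            inherits(db, "spectral_db"), inherits(stats, "physio_stats"))
  if (!all(cube$dim[1:2] == ood$dim))
    stop("cube and OOD mask shapes differ")
  cube <- normalize_cube(cube)
  flags <- as.vector(ood$flags)
  if (!any(flags)) return(cube)
  if (is.null(pool)) pool <- select_replacement_pool(db, stats, tol_sto2, tol_vhb)
  px <- cube_pixels(cube)
  real <- px[flags, , drop = FALSE]
  nn <- nn_search(real, db, subset = pool)
  synth <- db$spectra_cam[nn$id, , drop = FALSE]
  px[flags, ] <- l1_normalize((real + synth) / 2)
  pixels_to_cube(px, cube, normalized = TRUE)
}

#' Choose the percentile setting on validation data
#'
#' Runs the full test-time-augmentation + segmentation + Dice pipeline for
#' each candidate percentile pair on labeled validation scenes and returns
#' the pair maximizing the overall hierarchically aggregated Dice score
#' (mean over per-organ hierarchical scores). Ties break to the first
#' candidate in list order.
#'
#' @param candidate_pairs List of percentile pairs, e.g.
#'   `list(c(5, 95), c(25, 75))`.
#' @param validation_scenes List of `labeled_scene`s with reference masks.
#' @param model A frozen segmentation model ([train_segmenter()]).
#' @param db A `spectral_db`.
#' @param physio_twins Twin maps of the physiological fitting data, passed
#'   to [fit_physio_stats()] per candidate.
#' @param ... Forwarded to [augment_image()].
#' @return The winning percentile pair, with attributes `dsc` (per-candidate
#'   overall scores) and `stats` (the fitted `physio_stats`).
#' @export
select_percentile_setting <- function(candidate_pairs, validation_scenes,
                                      model, db, physio_twins, ...) {
  if (length(candidate_pairs) == 0) stop("no candidate percentile pairs")
  stopifnot(length(validation_scenes) > 0)
  scores <- numeric(length(candidate_pairs))
  stats_list <- vector("list", length(candidate_pairs))
  for (k in seq_along(candidate_pairs)) {
    stats <- fit_physio_stats(physio_twins, candidate_pairs[[k]])
    stats_list[[k]] <- stats
    pool <- select_replacement_pool(db, stats, ...)
    recs <- list()
    for (sc in validation_scenes) {
      twin <- generate_twin(sc$cube, db)
      hybrid <- augment_image(sc$cube, twin, detect_ood(twin, stats), db,
                              stats, pool = pool)
      pred <- predict(model, hybrid)
      recs[[length(recs) + 1]] <- dsc_records(pred, sc$mask, sc$subject_id,
                                              sc$image_id)
    }
    agg <- hierarchical_aggregate(do.call(rbind, recs))
    scores[k] <- mean(agg$dsc)
  }
  best <- which.max(scores)  # first maximum = first candidate in list order
  out <- candidate_pairs[[best]]
  attr(out, "dsc") <- scores
  attr(out, "stats") <- stats_list[[best]]
  out
}
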