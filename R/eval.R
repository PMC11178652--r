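#' Dice similarity coefficient
#'
#' Overlap score 2|P (intersect) R| / (|P| + |R|) between the pixel sets of
#' one label in a predicted and a reference mask. When the label is absent
#' from both masks the score is 1 by convention.
#'
#' @param pred,ref Integer label matrices of equal shape.
#' @param organ_label The label to score.
#' @return Dice score in \[0, 1\].
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dsc(m, m, 1)  # 1
#' @export
dsc <- function(pred, ref, organ_label) {
  if (!all(dim(pred) == dim(ref))) stop("prediction and reference shapes differ")
  p <- pred == organ_label
  r <- ref == organ_label
  np <- sum(p); nr <- sum(r)
  if (np + nr == 0) return(1)
  2 * sum(p & r) / (np + nr)
}

#' Per-image, per-organ Dice records
#'
#' Scores every requested organ label of one image and returns tidy records
#' for hierarchical aggregation.
#'
#' @param pred,ref Label matrices.
#' @param subject_id,image_id Identifiers.
#' @param organ_labels Labels to score; default every non-background
#'   (non-zero) label present in the reference.
#' @return data.frame with columns `subject_id`, `image_id`, `organ_label`,
#'   `dsc`.
#' @export
dsc_records <- function(pred, ref, subject_id, image_id, organ_labels = NULL) {
  if (is.null(organ_labels))
    organ_labels <- sort(setdiff(unique(as.vector(ref)), 0))
  data.frame(subject_id = subject_id, image_id = image_id,
             organ_label = organ_labels,
             dsc = vapply(organ_labels, function(l) dsc(pred, ref, l), 0))
}

#' Hierarchical Dice aggregation
#'
#' Two-level mean per organ: Dice scores are first averaged over the images
#' of each subject, then over subjects, so that subjects with many images do
#' not dominate the aggregate.
#'
#' @param records data.frame as produced by [dsc_records()] (rows from many
#'   images concatenated).
#' @return data.frame with one row per `organ_label` and the aggregated
#'   `dsc`.
#' @export
hierarchical_aggregate <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no Dice records to aggregate")
  stopifnot(all(c("subject_id", "image_id", "organ_label", "dsc") %in%
                  names(records)))
  per_subject <- stats::aggregate(dsc ~ organ_label + subject_id, records, mean)
  out <- stats::aggregate(dsc ~ organ_label, per_subject, mean)
  out[order(out$organ_label), , drop = FALSE]
}

#' Relative performance decrease
#'
#' `100 * (baseline - degraded) / baseline`, the percentage by which a
#' score dropped relative to its baseline.
#'
#' @param baseline Baseline score (> 0).
#' @param degraded Degraded score.
#' @return Percentage.
#' @examples
#' relative_decrease(0.73, 0.05)  # ~93
#' @export
relative_decrease <- function(baseline, degraded) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * (baseline - degraded) / baseline
}

#' Improvement factor
#'
#' `improved / baseline`, the multiplicative gain over a baseline score.
#'
#' @param baseline Baseline score (> 0).
#' @param improved Improved score.
#' @return Factor.
#' @examples
#' improvement_factor(0.05, 0.23)  # 4.6
#' @export
improvement_factor <- function(baseline, improved) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  improved / baseline
}

#' Median organ spectrum of an image
#'
#' Per-band median over the pixels carrying `organ_label` in the mask.
#'
#' @param cube An `hsi_cube`.
#' @param mask Integer label matrix matching the cube's spatial shape.
#' @param organ_label Label selecting the pixels.
#' @return Numeric vector of length B (the cube's band count).
#' @export
median_masked_spectrum <- function(cube, mask, organ_label) {
  stopifnot(inherits(cube, "hsi_cube"), all(dim(mask) == cube$dim[1:2]))
  sel <- as.vector(mask == organ_label)
  if (!any(sel)) stop("no pixels with label ", organ_label, " in mask")
  px <- cube_pixels(cube)[sel, , drop = FALSE]
  apply(px, 2, stats::median)
}

#' Domain-gap report
#'
#' Quantifies the gap between physiological and malperfused spectra the way
#' the study's diagnostics do: a 2-component PCA is fitted on the union of
#' all original and augmented per-image median spectra, every spectrum is
#' embedded, a Gaussian kernel density estimate is computed per
#' (state, phase) group on the plane, and for each state the Euclidean
#' distance between that state's mean embedding and the physiological mean
#' embedding is reported before and after augmentation.
#'
#' @param spectra Matrix of per-image median spectra, one row per image.
#' @param state Character vector of perfusion state names per row.
#' @param phase Character vector per row: `"original"` or `"augmented"`.
#' @param density_n Grid size per axis of the KDE evaluation grid.
#' @return An object of class `gap_report`: `embedding` (n x 2),
#'   `explained_variance`, `densities` (list per state/phase with `x`,
#'   `y`, `z`), and `mean_gap` (data.frame: state, phase, gap).
#' @export
domain_gap <- function(spectra, state, phase, density_n = 64) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(state), length(state) == length(phase),
            all(phase %in% c("original", "augmented")))
  if (length(unique(state)) < 2)
    stop("domain gap requires at least 2 perfusion states")
  counts <- table(state, phase)
  if (any(counts < 2))
    stop("each state/phase group needs at least 2 images")
  pc <- stats::prcomp(spectra, center = TRUE, scale. = FALSE, rank. = 2)
  emb <- pc$x[, 1:2, drop = FALSE]
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  # physiological mean per phase is the reference point
  gap_rows <- list()
  for (ph in unique(phase)) {
    ref <- colMeans(emb[state == "physiological" & phase == ph, , drop = FALSE])
    for (st in setdiff(unique(state), "physiological")) {
      m <- colMeans(emb[state == st & phase == ph, , drop = FALSE])
      gap_rows[[length(gap_rows) + 1]] <-
        data.frame(state = st, phase = ph, gap = sqrt(sum((m - ref)^2)))
    }
  }
  dens <- list()
  for (st in unique(state)) for (ph in unique(phase)) {
    pts <- emb[state == st & phase == ph, , drop = FALSE]
    hx <- MASS::bandwidth.nrd(pts[, 1]); hy <- MASS::bandwidth.nrd(pts[, 2])
    if (hx == 0 || hy == 0) next  # degenerate cloud, no density
    lims <- c(range(pts[, 1]) + c(-3, 3) * hx, range(pts[, 2]) + c(-3, 3) * hy)
    dens[[paste(st, ph, sep = ".")]] <-
      MASS::kde2d(pts[, 1], pts[, 2], n = density_n, lims = lims)
  }
  structure(list(embedding = emb, explained_variance = ev, densities = dens,
                 mean_gap = do.call(rbind, gap_rows)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> PC1 %.1f%%, PC2 %.1f%% explained variance\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  print(x$mean_gap)
  invisible(x)
}
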