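#' Train the frozen pixel-wise segmentation model
#'
#' Fits a pixel-wise spectral classifier on the L1-normalized spectra of
#' physiological training scenes and freezes it. Two families are
#' available:
#'
#' * `"lda"` (default): a regularized Gaussian linear discriminant — class
#'   means plus a pooled within-class covariance ridged by
#'   `lambda * mean(diag(S))`, classifying by the linear discriminant score.
#'   Whitening by the within-class covariance makes the decision rule
#'   sharply tuned to the physiological training manifold, which is exactly
#'   the brittleness under perfusion shifts the pipeline addresses.
#' * `"prototype"`: nearest class mean in Euclidean distance.
#'
#' Both families operate on apparent-absorbance features,
#' `log(spectrum + 1e-4)` of the L1-normalized spectrum — the standard
#' spectroscopic representation in which chromophore contributions combine
#' near-additively (`features = "linear"` uses the normalized spectrum
#' directly).
#'
#' The model stands in for a full image-wise segmentation network behind
#' the same contract: frozen after training, L1-normalized spectra in,
#' label mask out. Training scenes must all be physiological; any other
#' perfusion state is rejected.
#'
#' @param scenes List of physiological `labeled_scene`s.
#' @param method `"lda"` or `"prototype"`.
#' @param features `"log"` (apparent absorbance, default) or `"linear"`.
#' @param lambda Ridge fraction for the pooled covariance (default 0.05).
#' @param max_pixels_per_class Training pixels subsampled per class
#'   (default 20000) for scalability; subsampling is seeded.
#' @param seed Integer seed (used only for the subsampling draw).
#' @return An object of class `frozen_model`.
#' @export
train_segmenter <- function(scenes, method = c("lda", "prototype"),
                            features = c("log", "linear"), lambda = 0.05,
                            max_pixels_per_class = 20000, seed = 1L) {
  method <- match.arg(method)
  features <- match.arg(features)
  if (inherits(scenes, "labeled_scene")) scenes <- list(scenes)
  stopifnot(length(scenes) > 0)
  states <- vapply(scenes, `[[`, "", "state")
  if (any(states != "physiological"))
    stop("frozen model must be trained on physiological scenes only; got ",
         paste(unique(states[states != "physiological"]), collapse = ", "))
  class_labels <- scenes[[1]]$class_labels
  X <- do.call(rbind, lapply(scenes, function(s) cube_pixels(s$cube)))
  y <- unlist(lapply(scenes, function(s) as.vector(s$mask)))
  missing <- setdiff(class_labels, unique(y))
  if (length(missing))
    stop("no training pixels for class label(s): ", paste(missing, collapse = ", "))
  keep <- with_seed(seed, {
    unlist(lapply(class_labels, function(l) {
      idx <- which(y == l)
      if (length(idx) > max_pixels_per_class)
        idx <- sort(sample(idx, max_pixels_per_class))
      idx
    }))
  })
  X <- spec_features(X[keep, , drop = FALSE], features)
  y <- y[keep]
  k <- length(class_labels)
  b <- ncol(X)
  means <- matrix(NA_real_, k, b)
  priors <- numeric(k)
  S <- matrix(0, b, b)
  for (i in seq_len(k)) {
    Xi <- X[y == class_labels[i], , drop = FALSE]
    means[i, ] <- colMeans(Xi)
    priors[i] <- nrow(Xi) / nrow(X)
    Xc <- sweep(Xi, 2, means[i, ])
    S <- S + crossprod(Xc)
  }
  model <- list(method = method, features = features,
                class_labels = unname(class_labels),
                class_names = names(class_labels), n_bands = b,
                means = means, priors = priors,
                provenance = list(seed = as.integer(seed), lambda = lambda,
                                  n_train = nrow(X),
                                  scene_ids = vapply(scenes, `[[`, "", "image_id")))
  if (method == "lda") {
    S <- S / (nrow(X) - k)
    S <- S + lambda * mean(diag(S)) * diag(b)
    Sinv_mu <- solve(S, t(means))               # b x k
    model$coef <- Sinv_mu
    model$const <- -0.5 * colSums(t(means) * Sinv_mu) + log(priors)
  }
  model$frozen <- TRUE
  class(model) <- "frozen_model"
  model
}

# apparent-absorbance feature map; the offset guards the log at near-zero
# bands of strongly absorbing (blood-rich) pixels
spec_features <- function(px, features) {
  if (features == "log") log(px + 1e-4) else px
}

#' @export
print.frozen_model <- function(x, ...) {
  cat(sprintf("<frozen_model> %s, %d classes (%s), %d bands, frozen\n",
              x$method, length(x$class_labels),
              paste(x$class_names, collapse = ", "), x$n_bands))
  invisible(x)
}

#' Predict a label mask
#'
#' Pure function of the input cube: per-pixel argmax of the frozen
#' classifier's scores. The model is never modified.
#'
#' @param object A `frozen_model`.
#' @param cube An `hsi_cube` (L1-normalized; normalized internally
#'   otherwise).
#' @param ... Unused.
#' @return H x W integer label matrix.
#' @export
predict.frozen_model <- function(object, cube, ...) {
  stopifnot(inherits(cube, "hsi_cube"), isTRUE(object$frozen))
  if (cube$dim[3] != object$n_bands)
    stop("cube has ", cube$dim[3], " bands but model expects ", object$n_bands)
  px <- spec_features(cube_pixels(normalize_cube(cube)), object$features)
  if (object$method == "lda") {
    scores <- px %*% object$coef
    scores <- sweep(scores, 2, object$const, "+")
  } else {
    # nearest prototype: argmin distance = argmax (x.mu - |mu|^2/2)
    scores <- px %*% t(object$means)
    scores <- sweep(scores, 2, 0.5 * rowSums(object$means^2))
  }
  lab <- object$class_labels[max.col(scores, ties.method = "first")]
  matrix(as.integer(lab), cube$dim[1], cube$dim[2])
}

#' Save / load a frozen model
#'
#' Serialization round-trips exactly (byte-for-byte identical predictions
#' before and after).
#'
#' @param model A `frozen_model`.
#' @param path File path.
#' @return `load_model` returns the `frozen_model`; the writer its path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "frozen_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "frozen_model"))
  model
}
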