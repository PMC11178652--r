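#' Perfusion states
#'
#' The four perfusion conditions of the study, with the StO2/VHb sampling
#' ranges the scene generator uses for the affected organ's pixels:
#' `physiological` (StO2 0.55--0.85, VHb 0.03--0.10), `avascular` (inflow
#' and outflow blocked; StO2 0--0.15, VHb 0.02--0.08), `arterial_ischemia`
#' (inflow blocked; StO2 0--0.15, VHb 0.01--0.05) and `venous_congestion`
#' (outflow blocked, blood pooling; StO2 0--0.20, VHb 0.12--0.30). The
#' directions are physiologically motivated (ischemia desaturates with
#' reduced inflow, congestion pools desaturated blood); the exact numbers
#' are this package's synthetic surrogates, not measured values.
#'
#' @param name One of `"physiological"`, `"avascular"`,
#'   `"arterial_ischemia"`, `"venous_congestion"`.
#' @return An object of class `perfusion_state`: list with `name`,
#'   `sto2_range`, `vhb_range`.
#' @export
perfusion_state <- function(name = c("physiological", "avascular",
                                     "arterial_ischemia", "venous_congestion")) {
  name <- match.arg(name)
  ranges <- switch(name,
    physiological     = list(sto2 = c(0.55, 0.85), vhb = c(0.03, 0.10)),
    avascular         = list(sto2 = c(0.00, 0.15), vhb = c(0.02, 0.08)),
    arterial_ischemia = list(sto2 = c(0.00, 0.15), vhb = c(0.01, 0.05)),
    venous_congestion = list(sto2 = c(0.00, 0.20), vhb = c(0.12, 0.30)))
  structure(list(name = name, sto2_range = ranges$sto2, vhb_range = ranges$vhb),
            class = "perfusion_state")
}

#' @export
print.perfusion_state <- function(x, ...) {
  cat(sprintf("<perfusion_state> %s: StO2 [%.2f, %.2f], VHb [%.2f, %.2f]\n",
              x$name, x$sto2_range[1], x$sto2_range[2],
              x$vhb_range[1], x$vhb_range[2]))
  invisible(x)
}

# per-class physiological sampling bounds; fields not listed fall back to
# `base`. The auxiliary classes give malperfused kidney spectra plausible
# competitors, mirroring a multi-organ atlas: a poorly saturated, low-blood,
# strongly scattering bowel-wall analog (retrieved StO2 of some physiological
# organs is genuinely low) and a dark blood-pool major-vein analog. Their
# scattering ranges deliberately differ from the kidney's, as real organs'
# do.
scene_class_ranges <- function() {
  base <- list(g = c(0.85, 0.95), n_refr = c(1.36, 1.44), d_cm = c(0.05, 0.2),
               w_water = c(0.8, 0.9))
  fill <- function(x) utils::modifyList(base, x)
  list(
    background = fill(list(sto2 = c(0.50, 0.90), vhb = c(0.005, 0.03),
                           mus500 = c(25, 40), b_mie = c(1.5, 2.5),
                           w_water = c(0.80, 0.86))),
    kidney     = fill(list(sto2 = c(0.55, 0.85), vhb = c(0.03, 0.10),
                           mus500 = c(10, 25), b_mie = c(0.6, 1.4))),
    bowel      = fill(list(sto2 = c(0.02, 0.18), vhb = c(0.002, 0.02),
                           mus500 = c(22, 36), b_mie = c(1.4, 2.2))),
    vein       = fill(list(sto2 = c(0.05, 0.25), vhb = c(0.15, 0.25),
                           mus500 = c(8, 20), b_mie = c(0.5, 1.2)))
  )
}

#' Scene layout
#'
#' Defines the label raster and per-class parameter ranges of a synthetic
#' surgical scene: a background (label 0, fat/connective-like optics) and
#' elliptical organ regions — the kidney analog (label 1, the organ whose
#' perfusion state varies), a bowel-wall analog (label 2) and a major-vein
#' analog (label 3). Spatial realism is irrelevant for a pixel-wise frozen
#' model; geometry only fixes region sizes.
#'
#' @param height,width Scene size in pixels.
#' @return An object of class `scene_layout`: `labels` (H x W integer
#'   matrix), `class_labels` (named integer vector), `class_ranges`,
#'   and `organ` (name of the perfusion-altered class).
#' @export
scene_layout <- function(height = 24, width = 24) {
  stopifnot(height >= 12, width >= 12)
  lab <- matrix(0L, height, width)
  ell <- function(cy, cx, ry, rx) {
    r <- row(lab); c <- col(lab)
    ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
  }
  lab[ell(0.38 * height, 0.33 * width, 0.26 * height, 0.22 * width)] <- 1L
  lab[ell(0.72 * height, 0.68 * width, 0.20 * height, 0.24 * width)] <- 2L
  lab[ell(0.22 * height, 0.80 * width, 0.14 * height, 0.12 * width)] <- 3L
  cl <- c(background = 0L, kidney = 1L, bowel = 2L, vein = 3L)
  structure(list(labels = lab, class_labels = cl,
                 class_ranges = scene_class_ranges(), organ = "kidney"),
            class = "scene_layout")
}

# uniform draw of all 8 tissue parameters within `ranges` for n pixels,
# with optional per-subject offsets (additive StO2 shift, multiplicative
# scattering scale), clamped to the admissible space
draw_class_params <- function(n, ranges, subject_effect = NULL) {
  full <- param_ranges()
  cols <- lapply(param_names(), function(nm) {
    r <- ranges[[nm]]
    stats::runif(n, r[1], r[2])
  })
  names(cols) <- param_names()
  if (!is.null(subject_effect)) {
    cols$sto2 <- pmin(pmax(cols$sto2 + subject_effect$sto2_shift,
                           full$sto2[1]), full$sto2[2])
    cols$mus500 <- pmin(pmax(cols$mus500 * subject_effect$mus_scale,
                             full$mus500[1]), full$mus500[2])
  }
  as.data.frame(cols)
}

#' Generate one labeled synthetic scene
#'
#' Samples per-pixel tissue parameters from the layout's class ranges (the
#' kidney-analog organ uses the perfusion state's StO2/VHb ranges),
#' forward-simulates every pixel on the simulation grid, resamples through
#' the camera twin, applies multiplicative Gaussian noise of relative
#' standard deviation `noise_sd` (clipped at zero), and L1-normalizes. The
#' scene records its ground-truth parameters and label mask.
#'
#' @param layout A [scene_layout()].
#' @param state A [perfusion_state()] (or state name).
#' @param cam A [camera_model()].
#' @param table A [chromophore_table()].
#' @param noise_sd Relative noise standard deviation (default 0.02).
#' @param seed Integer seed; scenes are reproducible.
#' @param subject_id,image_id Identifiers.
#' @param subject_effect Optional list(`sto2_shift`, `mus_scale`) of
#'   per-subject offsets (see [make_dataset()]).
#' @return An object of class `labeled_scene`: `cube` (normalized
#'   `hsi_cube`), `mask` (H x W integer), `true_params`
#'   ([tissue_params()], one row per pixel in column-major order),
#'   `subject_id`, `image_id`, `state`.
#' @export
make_scene <- function(layout = scene_layout(), state = perfusion_state(),
                       cam = camera_model(), table = chromophore_table(),
                       noise_sd = 0.02, seed = 1L, subject_id = "s1",
                       image_id = "i1", subject_effect = NULL) {
  stopifnot(inherits(layout, "scene_layout"))
  if (is.character(state)) state <- perfusion_state(state)
  stopifnot(inherits(state, "perfusion_state"), noise_sd >= 0)
  if (!any(layout$labels > 0) || !any(layout$labels == 0))
    stop("layout must define at least one organ region and a background")
  lab <- as.vector(layout$labels)
  n <- length(lab)
  params <- with_seed(seed, {
    p <- as.data.frame(matrix(NA_real_, n, length(param_names())))
    names(p) <- param_names()
    for (cls in names(layout$class_labels)) {
      idx <- which(lab == layout$class_labels[[cls]])
      if (!length(idx)) next
      rng <- layout$class_ranges[[cls]]
      if (cls == layout$organ) {
        rng$sto2 <- state$sto2_range
        rng$vhb <- state$vhb_range
      }
      p[idx, ] <- draw_class_params(length(idx), rng, subject_effect)
    }
    p
  })
  params <- as_tissue_params(params)
  raw <- diffuse_reflectance(params, sim_grid(), table)
  cam_vals <- resample_to_camera(raw, cam)$values
  if (noise_sd > 0) {
    noise <- with_seed(seed + 1L, matrix(stats::rnorm(length(cam_vals), 1, noise_sd),
                                         nrow(cam_vals), ncol(cam_vals)))
    cam_vals <- pmax(cam_vals * noise, 0)
  }
  px <- l1_normalize(cam_vals)
  d <- dim(layout$labels)
  cube <- hsi_cube(array(px, c(d[1], d[2], ncol(px))),
                   grid = wavelength_grid(cam$band_centers_nm[1],
                                          max(cam$band_centers_nm),
                                          diff(cam$band_centers_nm)[1]),
                   subject_id = subject_id, image_id = image_id,
                   normalized = TRUE)
  structure(list(cube = cube, mask = layout$labels, true_params = params,
                 class_labels = layout$class_labels, organ = layout$organ,
                 subject_id = subject_id, image_id = image_id,
                 state = state$name),
            class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene> %s/%s, state %s, %d x %d\n", x$subject_id,
              x$image_id, x$state, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Generate a multi-subject scene dataset
#'
#' Emulates the study's subject structure: per-subject variability offsets
#' (a small additive StO2 shift and a multiplicative scattering scale) are
#' drawn once per subject, then every subject contributes
#' `images_per_subject` scenes per requested perfusion state. Scenes are
#' tagged `subject_id`/`image_id`; [split_subjects()] provides a
#' subject-disjoint validation/test split.
#'
#' @param n_subjects Number of subjects (default 12, as in the study's
#'   kidney cohort).
#' @param images_per_subject Scenes per subject and state.
#' @param states Character vector of perfusion state names.
#' @param seed Integer seed.
#' @param layout,cam,table,noise_sd Forwarded to [make_scene()].
#' @return List of `labeled_scene`s.
#' @export
make_dataset <- function(n_subjects = 12, images_per_subject = 2,
                         states = c("physiological", "avascular",
                                    "arterial_ischemia", "venous_congestion"),
                         seed = 1L, layout = scene_layout(),
                         cam = camera_model(), table = chromophore_table(),
                         noise_sd = 0.02) {
  stopifnot(n_subjects >= 1, images_per_subject >= 1, length(states) >= 1)
  n_scenes <- n_subjects * images_per_subject * length(states)
  rand <- with_seed(seed, list(
    sto2_shift = stats::runif(n_subjects, -0.03, 0.03),
    mus_scale = stats::runif(n_subjects, 0.9, 1.1),
    scene_seeds = sample.int(.Machine$integer.max - 1L, n_scenes)
  ))
  scenes <- vector("list", n_scenes)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    eff <- list(sto2_shift = rand$sto2_shift[s], mus_scale = rand$mus_scale[s])
    for (st in states) {
      for (i in seq_len(images_per_subject)) {
        k <- k + 1L
        scenes[[k]] <- make_scene(layout, perfusion_state(st), cam, table,
                                  noise_sd = noise_sd,
                                  seed = rand$scene_seeds[k],
                                  subject_id = sprintf("pig%02d", s),
                                  image_id = sprintf("pig%02d_%s_%02d", s, st, i),
                                  subject_effect = eff)
      }
    }
  }
  scenes
}

#' Subject-disjoint split
#'
#' Randomly partitions subjects into a validation and a hold-out test group
#' (default 7 vs 5, as in the study) and assigns every scene to the group
#' of its subject, keeping subjects disjoint across splits.
#'
#' @param scenes List of `labeled_scene`s.
#' @param n_val,n_test Subject counts per split.
#' @param seed Integer seed for the subject shuffle.
#' @return List with `validation` and `test` scene lists.
#' @export
split_subjects <- function(scenes, n_val = 7, n_test = 5, seed = 1L) {
  subjects <- unique(vapply(scenes, `[[`, "", "subject_id"))
  if (length(subjects) != n_val + n_test)
    stop("dataset has ", length(subjects), " subjects but split asks for ",
         n_val + n_test)
  shuffled <- with_seed(seed, sample(subjects))
  val_ids <- shuffled[seq_len(n_val)]
  in_val <- vapply(scenes, function(s) s$subject_id %in% val_ids, TRUE)
  list(validation = scenes[in_val], test = scenes[!in_val])
}
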