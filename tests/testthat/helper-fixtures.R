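# shared fixtures, built once per test run; all sizes deliberately small
fix_tab <- chromophore_table()
fix_cam <- camera_model()

# 100-record database for exhaustive-scan oracle checks
fix_db_tiny <- build_database(100, seed = 5, keep_raw = FALSE)

# moderate database for TTA behaviour tests
fix_db <- build_database(4000, seed = 7, keep_raw = FALSE)

# small physiological scenes + twins for statistics fixtures
fix_layout <- scene_layout(16, 16)
fix_phys_scenes <- lapply(1:3, function(i)
  make_scene(fix_layout, perfusion_state("physiological"), seed = 100 + i,
             subject_id = sprintf("pig%02d", i),
             image_id = sprintf("pig%02d_phys", i)))
fix_phys_twins <- lapply(fix_phys_scenes, function(s) generate_twin(s$cube, fix_db))
fix_stats <- fit_physio_stats(fix_phys_twins, c(25, 75))

# naive exhaustive scan, the independent oracle for nearest-neighbor search
oracle_nn <- function(queries, spectra, ids = seq_len(nrow(spectra))) {
  queries <- if (is.matrix(queries)) queries else matrix(queries, nrow = 1)
  id <- integer(nrow(queries)); d <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(spectra))) {
      dj <- sqrt(sum((queries[i, ] - spectra[j, ])^2))
      if (dj < best) { best <- dj; best_j <- j }
    }
    id[i] <- ids[best_j]; d[i] <- best
  }
  list(id = id, distance = d)
}
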