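test_that("Dice coefficient: worked examples, symmetry, conventions", {
  m <- matrix(c(1, 1, 0, 0, 2, 2), 2, 3)
  expect_equal(dsc(m, m, 1), 1)
  disjoint <- matrix(c(0, 0, 1, 1, 0, 0), 2, 3)
  expect_equal(dsc(m, disjoint, 1), 0)
  # |P| = 2, |R| = 2, overlap 1 -> 0.5
  p <- matrix(c(1, 1, 0, 0), 2, 2)
  r <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dsc(p, r, 1), 0.5)
  # both-empty convention
  expect_equal(dsc(p, r, 9), 1)
  # symmetry over random masks
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(sample(0:2, 36, TRUE), 6)
    b <- matrix(sample(0:2, 36, TRUE), 6)
    expect_equal(dsc(a, b, 1), dsc(b, a, 1))
  }
  expect_error(dsc(p, matrix(0, 3, 3), 1), "shape")
})

test_that("hierarchical aggregation averages images within subjects first", {
  rec <- data.frame(subject_id = c("A", "B", "B"),
                    image_id = c("a1", "b1", "b2"),
                    organ_label = 1, dsc = c(1, 0, 0))
  expect_equal(hierarchical_aggregate(rec)$dsc, 0.5)  # not pooled 1/3

  one <- data.frame(subject_id = "A", image_id = "a1", organ_label = 1,
                    dsc = 0.7)
  expect_equal(hierarchical_aggregate(one)$dsc, 0.7)

  # independent two-level group-mean oracle on 200 random records
  set.seed(42)
  rec <- data.frame(subject_id = sample(paste0("s", 1:5), 200, TRUE),
                    image_id = paste0("img", 1:200),
                    organ_label = sample(1:3, 200, TRUE),
                    dsc = runif(200))
  got <- hierarchical_aggregate(rec)
  for (l in 1:3) {
    rl <- rec[rec$organ_label == l, ]
    per_subj <- tapply(rl$dsc, rl$subject_id, mean)
    expect_equal(got$dsc[got$organ_label == l], mean(per_subj))
  }

  # duplicating every image of one subject leaves the aggregate unchanged
  dup <- rec[rec$subject_id == "s1", ]
  dup$image_id <- paste0(dup$image_id, "_copy")
  expect_equal(hierarchical_aggregate(rbind(rec, dup))$dsc, got$dsc)

  expect_error(hierarchical_aggregate(rec[0, ]), "no Dice")
})

test_that("relative decrease and improvement factor reproduce printed arithmetic", {
  # the study's kidney DSC drops 0.73 -> 0.05 under venous congestion: -93%
  expect_equal(round(relative_decrease(0.73, 0.05)), 93)
  expect_equal(relative_decrease(1.0, 0.5), 50)
  expect_equal(relative_decrease(0.4, 0.4), 0)
  expect_error(relative_decrease(0, 0.5), "positive")

  # a +0.18 gain over a 0.05 baseline is a 4.6-fold improvement
  expect_equal(improvement_factor(0.05, 0.05 + 0.18), 4.6)
  expect_equal(improvement_factor(0.5, 1.0), 2.0)
  expect_equal(improvement_factor(0.3, 0.3), 1.0)
  expect_error(improvement_factor(-1, 0.5), "positive")

  # consistency: factor of the score left after a d% decrease recovers d/b
  b <- 0.73; d <- 0.05
  expect_equal(improvement_factor(b, b * (1 - relative_decrease(b, d) / 100)),
               d / b)
})

test_that("median organ spectrum matches a sort-and-middle oracle", {
  vals <- array(runif(9 * 11 * 100), c(9, 11, 100))
  cube <- hsi_cube(vals, grid = camera_grid())
  mask <- matrix(0L, 9, 11)
  set.seed(7)
  mask[sample(99, 40)] <- 1L
  got <- median_masked_spectrum(cube, mask, 1)
  px <- matrix(vals, 99, 100)[as.vector(mask == 1), ]
  want <- vapply(1:100, function(b) {
    x <- sort(px[, b])
    (x[20] + x[21]) / 2  # even count: mean of the middle pair
  }, 0)
  expect_equal(got, want)

  # uniform region returns that pixel spectrum
  uni <- hsi_cube(array(rep(1:100 / sum(1:100), each = 4), c(2, 2, 100)),
                  normalized = TRUE)
  expect_equal(median_masked_spectrum(uni, matrix(1L, 2, 2), 1),
               1:100 / sum(1:100))
  expect_error(median_masked_spectrum(cube, mask, 5), "label")
})

test_that("domain-gap report embeds, normalizes densities and orders variance", {
  set.seed(3)
  n <- 12
  base <- matrix(runif(100), 1)[rep(1, 4 * n), ] +
    matrix(rnorm(4 * n * 100, 0, 0.01), 4 * n)
  state <- rep(c("physiological", "avascular"), each = 2 * n)
  base[state == "avascular", 1:30] <- base[state == "avascular", 1:30] + 0.5
  phase <- rep(rep(c("original", "augmented"), each = n), 2)
  # augmented avascular rows pulled halfway back toward physiological
  pull <- state == "avascular" & phase == "augmented"
  base[pull, 1:30] <- base[pull, 1:30] - 0.25
  rep_ <- domain_gap(base, state, phase)

  expect_true(all(diff(rep_$explained_variance) <= 0))
  expect_true(all(rep_$explained_variance >= 0 &
                    rep_$explained_variance <= 1))
  expect_lte(sum(rep_$explained_variance), 1)

  # KDE integrates to ~1 over its grid
  for (d in rep_$densities) {
    dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
    expect_equal(sum(d$z) * dx * dy, 1, tolerance = 0.02)
  }

  # the constructed augmentation halves the avascular gap
  g <- rep_$mean_gap
  g_orig <- g$gap[g$state == "avascular" & g$phase == "original"]
  g_aug <- g$gap[g$state == "avascular" & g$phase == "augmented"]
  expect_lt(g_aug, g_orig)

  expect_error(domain_gap(base, rep("physiological", 4 * n), phase), "states")
})
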