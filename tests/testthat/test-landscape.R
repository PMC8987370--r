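test_that("axial distances are 3D Euclidean and validated", {
  expect_equal(axial_distance(data.frame(x_um = 3, y_um = 4, z_um = 0),
                              c(0, 0, 0)), 5)
  expect_equal(axial_distance(data.frame(x_um = 11, y_um = 2, z_um = 3),
                              c(1, 2, 3)), 10)
  expect_error(axial_distance(data.frame(x_um = NA_real_, y_um = 0, z_um = 0),
                              c(0, 0, 0)), "finite")
})

test_that("normalisation rescales to the cohort mean length", {
  expect_equal(normalize_and_scale(55, 220, 200), 50)
  expect_equal(normalize_and_scale(c(0, 110, 220), 220, 200), c(0, 100, 200))
  # small landmark overshoot clamps to the end of the axis
  expect_equal(normalize_and_scale(101, 100, 300), 300)
  expect_warning(out <- normalize_and_scale(c(50, 110), 100, 300),
                 "exceed")
  expect_equal(out, c(150, NA))
  expect_error(normalize_and_scale(10, 0, 100), "positive")
})

test_that("binning uses half-open 20 um bins with a closed terminal bin", {
  expect_identical(bin_frequencies(c(5, 19.9, 25), 20, 40), c(2L, 1L))
  expect_identical(bin_frequencies(c(20), 20, 40), c(0L, 1L))
  expect_identical(bin_frequencies(c(40), 20, 40), c(0L, 1L)) # closed end
  expect_identical(bin_frequencies(numeric(), 20, 40), c(0L, 0L))
  expect_identical(bin_frequencies(c(150), 20, 150), c(rep(0L, 7), 1L))
  expect_error(bin_frequencies(c(41), 20, 40), "within")
  expect_error(bin_frequencies(1, 20, -1), "positive")
})

test_that("cohort landscape averages per-embryo counts on the mean axis", {
  nuc <- dplyr::bind_rows(
    toy_nuclei(c(10, 100, 199), embryo_id = "a"),
    toy_nuclei(50, embryo_id = "b")
  )
  lm <- dplyr::bind_rows(toy_landmarks("a", 200), toy_landmarks("b", 100))
  row <- cohort_landscape(nuc, lm, "edu", bin_width = 20)
  expect_equal(nrow(row), 8) # ceiling(150 / 20)
  expect_equal(row$mean_length_um, rep(150, 8))
  expect_equal(row$mean_frequency, c(0.5, 0, 0, 1, 0, 0, 0, 0.5))
  expect_equal(row$partial_bin, c(rep(FALSE, 7), TRUE))
  # phh3 row is all zero for this cohort
  expect_equal(cohort_landscape(nuc, lm, "phh3")$mean_frequency, rep(0, 8))
  # mixed stages are rejected
  lm_bad <- lm
  lm_bad$stage_ss[2] <- 9
  expect_error(cohort_landscape(nuc, lm_bad, "edu"), "stage")
})

test_that("assemble_landscape stacks stages and supports tidy/glance", {
  nuc <- dplyr::bind_rows(
    toy_nuclei(c(10, 100), embryo_id = "a", stage_ss = 7),
    toy_nuclei(c(20, 30), embryo_id = "c", stage_ss = 9)
  )
  lm <- dplyr::bind_rows(toy_landmarks("a", 200, 7), toy_landmarks("c", 200, 9))
  ls <- assemble_landscape(nuc, lm, markers = "edu")
  expect_s3_class(ls, "proliferation_landscape")
  expect_equal(sort(unique(tidy(ls)$stage_ss)), c(7, 9))
  g <- glance(ls)
  expect_equal(g$total_labeled, c(2, 2)) # de-normalised integer totals
  expect_s3_class(ggplot2::autoplot(ls), "ggplot")
})

test_that("detect_domains finds thresholded runs and merges single-bin gaps", {
  d <- detect_domains(c(5, 4, 0, 0, 0, 6, 7), 0.5)
  expect_equal(d$start_bin, c(0, 5))
  expect_equal(d$end_bin, c(1, 6))
  # single-bin gap merged
  m <- detect_domains(c(5, 0, 5, 0, 0, 5), 0.5)
  expect_equal(m$start_bin, c(0, 5))
  expect_equal(m$end_bin, c(2, 5))
  expect_equal(nrow(detect_domains(rep(0, 6))), 0)
  expect_error(detect_domains(c(1, -1)), "non-negative")
  um <- detect_domains(c(5, 4, 0, 0, 0, 6, 7), 0.5, bin_width = 20)
  expect_equal(um$start_um, c(0, 100))
  expect_equal(um$end_um, c(40, 140))
})
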