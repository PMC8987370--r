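toy_fate_embryo <- function() {
  nuc <- toy_nuclei(
    x = c(10, 150, 190, 100),
    tissue = c("neural", "neural", "somite", "endoderm"),
    edu = c(TRUE, TRUE, TRUE, FALSE),
    floor_plate = c(FALSE, TRUE, FALSE, FALSE),
    somite_index = c(NA, NA, 10, NA)
  )
  list(nuclei = nuc, landmarks = toy_landmarks("a", 200))
}

test_that("tissue profiles bin labelled nuclei per tissue", {
  x <- toy_fate_embryo()
  prof <- tissue_profiles(x$nuclei, x$landmarks, n_bins = 10)
  expect_equal(sort(unique(prof$tissue)),
               c("endoderm", "floor_plate", "neural", "somite"))
  get <- function(t) prof$count[prof$tissue == t]
  expect_equal(get("neural"), c(1, rep(0, 9)))       # 10/200 -> bin 1
  expect_equal(get("floor_plate"), c(rep(0, 7), 1, 0, 0)) # 0.75 -> bin 8
  expect_equal(get("somite"), c(rep(0, 9), 1))       # 0.95 -> bin 10
  expect_equal(sum(get("endoderm")), 0)              # unlabelled
  expect_equal(sum(prof$count), sum(x$nuclei$edu))
  # floor plate can stay merged with the neural class
  merged <- tissue_profiles(x$nuclei, x$landmarks, split_floorplate = FALSE)
  expect_equal(sum(merged$count[merged$tissue == "neural"]), 2)
  bad <- x$nuclei
  bad$tissue[2] <- NA
  expect_error(tissue_profiles(bad, x$landmarks), "missing tissue")
})

test_that("cohort profiles average per-embryo counts", {
  x <- toy_fate_embryo()
  y <- list(nuclei = dplyr::mutate(x$nuclei, embryo_id = "b"),
            landmarks = toy_landmarks("b", 200))
  prof <- cohort_profiles(dplyr::bind_rows(x$nuclei, y$nuclei),
                          dplyr::bind_rows(x$landmarks, y$landmarks),
                          condition = "pulse_7ss")
  expect_equal(unique(prof$n_embryos), 2)
  expect_equal(unique(prof$condition), "pulse_7ss")
  expect_equal(prof$mean_frequency[prof$tissue == "neural" & prof$bin == 1], 1)
  expect_s3_class(plot_fate_profiles(prof), "ggplot")
})

test_that("floor-plate clone fraction measures posterior extent coverage", {
  nuc <- toy_nuclei(
    x = c(100, 150, 200),
    tissue = "neural", floor_plate = TRUE,
    edu = c(FALSE, TRUE, TRUE)
  )
  lm <- toy_landmarks("a", 200)
  expect_equal(floorplate_clone_fraction(nuc, lm)$floorplate_fraction, 0.5)
  expect_equal(floorplate_clone_fraction(nuc, lm, mode = "count")$floorplate_fraction,
               2 / 3)
  # unlabelled floor plate gives 0; absent floor plate errors
  nuc0 <- dplyr::mutate(nuc, edu = FALSE)
  expect_equal(floorplate_clone_fraction(nuc0, lm)$floorplate_fraction, 0)
  nofp <- dplyr::mutate(nuc, floor_plate = FALSE)
  expect_error(floorplate_clone_fraction(nofp, lm), "floor-plate")
})

test_that("labelled somite counting filters singletons and reports gaps", {
  nuc <- toy_nuclei(
    x = seq(150, 200, length.out = 6),
    tissue = "somite",
    somite_index = c(10, 10, 12, 12, 12, 13),
    edu = TRUE
  )
  out <- labeled_somite_count(nuc, min_cells = 2)
  expect_equal(out$labeled_posterior_somites, 2L) # 13 has a single cell
  expect_false(out$contiguous)
  expect_equal(out$gaps, "11")
  # nothing labelled
  none <- labeled_somite_count(dplyr::mutate(nuc, edu = FALSE))
  expect_equal(none$labeled_posterior_somites, 0L)
})

test_that("clone_stats joins the per-embryo statistics", {
  x <- toy_fate_embryo()
  cs <- clone_stats(x$nuclei, x$landmarks)
  expect_equal(names(cs), c("embryo_id", "floorplate_fraction",
                            "labeled_posterior_somites",
                            "anteriormost_labeled_ap_norm"))
  expect_equal(cs$anteriormost_labeled_ap_norm, 10 / 200)
  expect_equal(cs$labeled_posterior_somites, 0L) # single labelled somite cell
})
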