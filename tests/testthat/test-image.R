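two_blob_stack <- function() {
  v <- array(1, c(30, 20, 10)) # dim non-nuclear background
  v[5:7, 5:7, 3:5] <- 100
  v[15:17, 10:12, 6:8] <- 100
  new_stack(v, channel = "dapi")
}

test_that("stack construction is validated", {
  expect_error(new_stack(matrix(0, 2, 2)), "3D")
  expect_error(new_stack(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(new_stack(array(0, c(2, 2, 2)), voxel_size = c(1, 1)), "three")
  s <- new_stack(array(1, c(2, 2, 2)), c(0.5, 0.5, 2), "edu")
  expect_s3_class(s, "stack")
  expect_output(print(s), "edu")
})

test_that("Otsu masking separates nuclei from dim background", {
  dapi <- two_blob_stack()
  m <- binary_mask(dapi)
  expect_setequal(unique(as.vector(m$voxels)), c(0, 1))
  expect_identical(m$voxels == 1, dapi$voxels == 100)
  # constant images cannot be auto-thresholded
  expect_error(binary_mask(new_stack(array(3, c(4, 4, 4)))), "fixed")
  fx <- binary_mask(new_stack(array(3, c(4, 4, 4))), "fixed", level = 2)
  expect_true(all(fx$voxels == 1))
  expect_error(binary_mask(two_blob_stack(), "fixed"), "level")
})

test_that("masking zeroes intensities outside the mask", {
  dapi <- two_blob_stack()
  m <- binary_mask(dapi)
  chan <- new_stack(array(7, dim(dapi$voxels)), channel = "edu")
  out <- mask_channel(chan, m)
  expect_equal(sort(unique(as.vector(out$voxels))), c(0, 7))
  expect_equal(sum(out$voxels > 0), sum(m$voxels))
  small <- new_stack(array(1, c(2, 2, 2)))
  expect_error(mask_channel(small, m), "dimensions")
})

test_that("3D component labelling uses 26-connectivity", {
  fg <- array(FALSE, c(6, 6, 6))
  fg[1, 1, 1] <- TRUE
  fg[2, 2, 2] <- TRUE # diagonal neighbour: same component
  fg[5, 5, 5] <- TRUE
  lab <- prolifscape:::label_components_3d(fg)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[5, 5, 5] != lab[1, 1, 1])
})

test_that("detection recovers centroids, volumes and marker calls", {
  dapi <- two_blob_stack()
  masked <- mask_channel(dapi, binary_mask(dapi))
  edu <- array(0, dim(dapi$voxels))
  edu[5:7, 5:7, 3:5] <- 50 # only the first nucleus is labelled
  det <- detect_nuclei(masked, min_volume = 5,
                       marker_stacks = list(edu = new_stack(edu)),
                       threshold = 50, marker_threshold = 10)
  det <- det[order(det$x_um), ]
  expect_equal(nrow(det), 2)
  expect_equal(det$volume, c(27, 27))
  expect_equal(det$x_um, c(5.5, 15.5))
  expect_equal(det$y_um, c(5.5, 10.5))
  expect_equal(det$z_um, c(3.5, 6.5))
  expect_equal(det$edu, c(TRUE, FALSE))
  # volume filter removes small components
  none <- detect_nuclei(masked, min_volume = 50, threshold = 50)
  expect_equal(nrow(none), 0)
})

test_that("TIFF round trip preserves a stack to float precision", {
  set.seed(1)
  v <- array(runif(4 * 5 * 3, 0, 1000), c(4, 5, 3))
  st <- new_stack(v, channel = "dapi")
  path <- tempfile(fileext = ".tif")
  write_stack(st, path, scale = 1000)
  back <- read_stack(path, scale = 1000)
  expect_equal(dim(back$voxels), dim(v))
  expect_equal(back$voxels, v, tolerance = 1e-5)
  unlink(path)
})

test_that("rendering is deterministic per seed", {
  nuc <- toy_nuclei(c(10, 20), y = 5, z = 5, edu = c(TRUE, FALSE))
  a <- render_embryo(nuc, seed = 4)
  b <- render_embryo(nuc, seed = 4)
  expect_identical(a$dapi$voxels, b$dapi$voxels)
  c <- render_embryo(nuc, seed = 5)
  expect_false(identical(a$dapi$voxels, c$dapi$voxels))
  expect_error(render_embryo(nuc, seed = 4,
                             field = list(origin = c(0, 0, 0), dim = c(5, 5, 5))),
               "outside")
})
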