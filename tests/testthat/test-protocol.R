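test_that("protocol validates windows and fixation time", {
  p <- protocol(edu_windows = list(c(18, 20)), fixation_hpf = 20)
  expect_s3_class(p, "protocol")
  expect_error(protocol(edu_windows = list(c(20, 18)), fixation_hpf = 22),
               "start < end")
  expect_error(protocol(edu_windows = list(c(18)), fixation_hpf = 22),
               "start < end")
  expect_error(protocol(edu_windows = list(c(24, 26)), fixation_hpf = 20),
               "precedes")
  # fixation inside a window is allowed
  expect_s3_class(protocol(hu_windows = list(c(18, 34)), fixation_hpf = 30),
                  "protocol")
  expect_error(protocol(fixation_hpf = -1), "non-negative")
})

test_that("window_active detects overlap with a time step", {
  w <- list(c(18, 20))
  expect_true(prolifscape:::window_active(w, 18, 18.1))
  expect_true(prolifscape:::window_active(w, 19.95, 20.05))
  expect_false(prolifscape:::window_active(w, 20, 20.1))
  expect_false(prolifscape:::window_active(w, 17.5, 18))
  expect_false(prolifscape:::window_active(list(), 19, 19.1))
})

test_that("protocol prints its windows", {
  p <- protocol(list(c(18, 20)), list(c(8, 34)), fixation_hpf = 34)
  out <- paste(capture.output(print(p)), collapse = "\n")
  expect_match(out, "\\[18, 20\\]")
  expect_match(out, "\\[8, 34\\]")
  expect_match(out, "34")
})
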