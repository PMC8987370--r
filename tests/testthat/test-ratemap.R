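rm_default <- default_ratemap(sim_config())
mult <- rm_default$multiplier

test_that("central neural tube is quiescent between 5 and 10 ss", {
  expect_equal(mult(7, "neural", 0.5, 0.5, 0, "none"), 0)
  expect_equal(mult(5, "neural", 0.3, 0.1, 0, "none"), 0)
  # the posterior growth zone stays on across stages
  expect_equal(mult(2, "neural", 0.95, 0.5, 0, "pnp"), 1)
  expect_equal(mult(9, "neural", 0.95, 0.5, 0, "pnp"), 1)
})

test_that("anterior competence sweeps ventral to dorsal", {
  # ventral cells at 6-7 ss
  expect_gt(mult(6.5, "neural", 0.05, 0.1, 0, "none"), 0)
  expect_equal(mult(6.5, "neural", 0.05, 0.9, 0, "none"), 0)
  # lateral cells at 7-8 ss
  expect_gt(mult(7.5, "neural", 0.05, 0.5, 0.5, "none"), 0)
  # dorsal cells only at 9-10 ss
  expect_equal(mult(7.5, "neural", 0.05, 0.9, 0, "none"), 0)
  expect_gt(mult(9.5, "neural", 0.05, 0.9, 0, "none"), 0)
  # never outside the anterior fraction of the axis
  expect_equal(mult(6.5, "neural", 0.3, 0.1, 0, "none"), 0)
})

test_that("division resumes after 10 ss only in floor plate and lateral walls", {
  cfg <- sim_config()
  expect_equal(mult(11, "neural", 0.5, 0.1, 0, "none"), cfg$late_neural_mult)
  expect_equal(mult(11, "neural", 0.5, 0.5, 0.9, "none"), cfg$late_neural_mult)
  expect_equal(mult(11, "neural", 0.5, 0.5, 0.3, "none"), 0)
})

test_that("chordoneural hinge and presomitic pool are stage-gated", {
  expect_equal(mult(5, "chordoneural_hinge", 1, 0.5, 0, "cnh"), 0)
  expect_equal(mult(7, "chordoneural_hinge", 1, 0.5, 0, "cnh"), 1)
  expect_equal(mult(7, "somite", 0.95, 0.5, 0.5, "psm"), 1)
  expect_equal(mult(11, "somite", 0.95, 0.5, 0.5, "psm"), 0)
})

test_that("before 5 ss all division competence is posterior", {
  for (tis in c("endoderm", "somite", "notochord")) {
    expect_equal(mult(3, tis, 0.5, 0.5, 0.5, "none"), 0)
  }
  expect_gt(mult(7, "endoderm", 0.5, 0.5, 0.5, "none"), 0)
})

test_that("division_rate is zero for arrested cells", {
  st <- sim_init(sim_config(), rm_default, protocol(fixation_hpf = 20))
  r1 <- division_rate(st)
  expect_true(all(r1 >= 0))
  st$cells$cycling[] <- FALSE
  expect_true(all(division_rate(st) == 0))
})

test_that("dropping a domain silences it", {
  rm_ant <- default_ratemap(sim_config(), domains = "anterior")
  expect_equal(rm_ant$multiplier(7, "neural", 0.95, 0.5, 0, "pnp"), 0)
  expect_equal(rm_ant$multiplier(7, "chordoneural_hinge", 1, 0.5, 0, "cnh"), 0)
  expect_gt(rm_ant$multiplier(6.5, "neural", 0.05, 0.1, 0, "none"), 0)
})
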