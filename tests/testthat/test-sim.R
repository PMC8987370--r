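test_that("identical seeds and protocols give identical exports", {
  p <- protocol(list(c(18, 20)), fixation_hpf = 20)
  a <- simulate_embryo(p, seed = 42)
  b <- simulate_embryo(p, seed = 42)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$landmarks, b$landmarks)
  c <- simulate_embryo(p, seed = 43)
  expect_false(identical(a$nuclei, c$nuclei))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(simulate_embryo(protocol(fixation_hpf = 12), seed = 7))
  expect_identical(runif(3), before)
})

test_that("sim_step validates the time step", {
  st <- sim_init(sim_config(), protocol = protocol(fixation_hpf = 20))
  expect_error(sim_step(st, 0), "dt")
  expect_error(sim_step(st, -0.1), "dt")
  expect_error(sim_step(st, 0.3), "dt")
})

test_that("EdU label is heritable and traces to in-window S phases", {
  p <- protocol(list(c(12, 14)), fixation_hpf = 26)
  emb <- simulate_embryo(p, seed = 3, keep_state = TRUE)
  expect_true(isTRUE(verify_label_lineage(emb$state)))
  expect_gt(sum(emb$nuclei$edu), 0)
  # direct labelling events only inside the pulse window
  lt <- emb$state$label_log$t
  expect_true(all(lt >= 12 - 1e-9 & lt <= 14 + 1e-9))
})

test_that("hydroxyurea from gastrula blocks all S entry and all labelling", {
  p <- protocol(edu_windows = list(c(20, 22)), hu_windows = list(c(8, 30)),
                fixation_hpf = 30)
  emb <- simulate_embryo(p, seed = 5, keep_state = TRUE)
  expect_equal(sum(emb$nuclei$edu), 0)
  expect_equal(sum(emb$nuclei$phh3), 0)
  expect_equal(nrow(division_log(emb$state)), 0)
  # arrested embryos do not elongate
  expect_equal(emb$landmarks$hinge_x, sim_config()$axis_length0)
})

test_that("blastopore sectors carry the documented fate programs", {
  cfg <- sim_config()
  expect_equal(blastopore_fate_assignment("dorsal", cfg)$pool, "cnh")
  expect_equal(blastopore_fate_assignment("dorsal", cfg)$tissue,
               "chordoneural_hinge")
  for (sec in c("upper_lateral", "lower_lateral", "ventral")) {
    expect_equal(blastopore_fate_assignment(sec, cfg)$pool, "psm")
  }
  expect_equal(blastopore_fate_assignment("dorsal", cfg)$s_window,
               cfg$sector_s_windows$dorsal)
  expect_error(blastopore_fate_assignment("animal_pole", cfg), "sector")
})

test_that("a control run elongates and exports a consistent table", {
  emb <- simulate_embryo(protocol(fixation_hpf = 34), seed = 8)
  nuc <- emb$nuclei
  expect_equal(unique(nuc$stage_ss), 14)
  expect_gt(emb$landmarks$hinge_x, sim_config()$axis_length0)
  expect_false(any(duplicated(nuc$id)))
  expect_true(all(is.finite(nuc$x_um)))
  expect_true(all(nuc$tissue %in% c("neural", "notochord", "somite",
                                    "endoderm", "chordoneural_hinge")))
  expect_true(all(nuc$ap_um >= 0 & nuc$ap_um <= emb$landmarks$hinge_x + 1e-6))
  # somite indices only on somite cells
  expect_true(all(is.na(nuc$somite_index) | nuc$tissue == "somite"))
})

test_that("at 7 ss neural divisions are confined to the two poles", {
  hits <- 0
  for (i in 1:30) {
    emb <- simulate_embryo(protocol(fixation_hpf = 21), seed = 20 + i,
                           keep_state = TRUE)
    d <- division_log(emb$state)
    d <- d[d$tissue %in% c("neural", "chordoneural_hinge") &
             d$t_hpf >= stage_to_hpf(6.5), ]
    hits <- hits + nrow(d)
    expect_true(all(d$ap_frac <= 0.15 | d$ap_frac >= 0.85))
  }
  expect_gt(hits, 200)
})
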