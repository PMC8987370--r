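#' Blastopore-lip fate programs
#'
#' The four sectors of the late-gastrula blastopore lip carry distinct fate
#' programs. Dorsal-lip founders become chordoneural-hinge axial progenitors
#' whose descendants elongate the posterior floor plate and notochord and
#' contribute cells to the posterior somites; upper-lateral founders join
#' the posterior presomitic pool but traverse S phase together with the
#' dorsal sector (10-12 hpf); lower-lateral and ventral founders join the
#' presomitic pool and traverse S at 12-14 hpf, giving rise to posterior
#' somites only.
#'
#' @param sector One of `"dorsal"`, `"upper_lateral"`, `"lower_lateral"`,
#'   `"ventral"`.
#' @param config A [sim_config()].
#' @return A list with elements `tissue`, `pool` and `s_window` (hpf).
#' @export
blastopore_fate_assignment <- function(sector, config = sim_config()) {
  sectors <- names(config$sector_s_windows)
  if (!is.character(sector) || length(sector) != 1 || !sector %in% sectors) {
    abort(paste0("Unknown blastopore sector; must be one of: ",
                 paste(sectors, collapse = ", ")))
  }
  if (sector == "dorsal") {
    list(tissue = "chordoneural_hinge", pool = "cnh",
         s_window = config$sector_s_windows$dorsal)
  } else {
    list(tissue = "somite", pool = "psm",
         s_window = config$sector_s_windows[[sector]])
  }
}

PHASE_G1 <- 1L; PHASE_S <- 2L; PHASE_G2 <- 3L; PHASE_M <- 4L

#' Initialise a simulated embryo
#'
#' Builds the founding cell field of a late-gastrula embryo: in-place neural
#' plate cells, a posterior neural growth zone riding the elongating tip,
#' notochord, endoderm, paraxial cells of the anterior (gastrula-derived)
#' somites, and blastopore-lip founders carrying sector fate programs.
#' The returned state is an environment (reference semantics): [sim_step()]
#' advances it in place and returns it invisibly.
#'
#' @param config A [sim_config()].
#' @param ratemap A `rate_map` from [default_ratemap()].
#' @param protocol A [protocol()].
#' @return An environment of class `"sim_state"` with fields `t_hpf`,
#'   `axis_length`, `cells` (parallel vectors), lineage and event logs.
#' @export
sim_init <- function(config = sim_config(), ratemap = default_ratemap(config),
                     protocol = NULL) {
  p <- config
  L0 <- p$axis_length0
  e <- new.env(parent = emptyenv())
  e$t_hpf <- p$t_start_hpf
  e$axis_length <- L0
  e$config <- p
  e$ratemap <- ratemap
  e$protocol <- protocol
  e$next_id <- 1L

  add <- function(n, tissue, ap, offset, dv, ml, somite = NA_integer_,
                  pool = "none", sector = NA_character_, sched = NA_real_) {
    list(
      id = as.integer(seq.int(e$next_id, length.out = n)),
      parent = rep(NA_integer_, n),
      ap = rep_len(ap, n), offset = rep_len(offset, n),
      dv = rep_len(dv, n), ml = rep_len(ml, n),
      tissue = rep_len(tissue, n),
      somite_index = rep_len(as.integer(somite), n),
      phase = rep(PHASE_G1, n),
      clock = runif(n, 0, p$phase_hours[["G1"]]),
      jit = runif(n, 1 - p$phase_jitter, 1 + p$phase_jitter),
      edu = rep(FALSE, n), cycling = rep(TRUE, n),
      pool = rep_len(pool, n), sector = rep_len(sector, n),
      sched_s = rep_len(sched, n)
    )
  }
  groups <- list()
  # in-place neural plate, anterior of the growth zone
  groups[[1]] <- add(p$n_neural, "neural",
                     ap = runif(p$n_neural, 0, L0 - p$pnp_zone_um),
                     offset = NA_real_, dv = runif(p$n_neural),
                     ml = runif(p$n_neural, -1, 1))
  e$next_id <- e$next_id + as.integer(p$n_neural)
  # posterior neural-plate growth zone (rides the tip)
  off <- runif(p$n_pnp, 0, p$pnp_zone_um)
  groups[[2]] <- add(p$n_pnp, "neural", ap = L0 - off, offset = off,
                     dv = runif(p$n_pnp), ml = runif(p$n_pnp, -1, 1),
                     pool = "pnp")
  e$next_id <- e$next_id + as.integer(p$n_pnp)
  groups[[3]] <- add(p$n_notochord, "notochord",
                     ap = runif(p$n_notochord, 0.05 * L0, L0 - p$pnp_zone_um),
                     offset = NA_real_, dv = 0.35,
                     ml = rnorm(p$n_notochord, 0, 0.05))
  e$next_id <- e$next_id + as.integer(p$n_notochord)
  groups[[4]] <- add(p$n_endoderm, "endoderm",
                     ap = runif(p$n_endoderm, 0, L0), offset = NA_real_,
                     dv = runif(p$n_endoderm), ml = runif(p$n_endoderm, -1, 1))
  e$next_id <- e$next_id + as.integer(p$n_endoderm)
  # gastrula-derived anterior somites
  ns <- p$n_preformed_somites * p$n_somite_cells
  k <- rep(seq_len(p$n_preformed_somites), each = p$n_somite_cells)
  groups[[5]] <- add(ns, "somite",
                     ap = L0 * (0.12 + 0.72 * (k - 0.5) / p$n_preformed_somites) +
                       runif(ns, -2, 2),
                     offset = NA_real_, dv = runif(ns, 0.3, 0.7),
                     ml = sample(c(-1, 1), ns, replace = TRUE) * runif(ns, 0.5, 0.9),
                     somite = k)
  e$next_id <- e$next_id + as.integer(ns)
  # blastopore-lip founders with scheduled S traversal
  for (sec in names(p$n_founders)) {
    nf <- p$n_founders[[sec]]
    fate <- blastopore_fate_assignment(sec, p)
    w <- fate$s_window
    s_len <- p$phase_hours[["S"]] * (1 + p$phase_jitter)
    sched <- runif(nf, w[1] + 0.1, max(w[1] + 0.2, w[2] - s_len - 0.1))
    off <- if (fate$pool == "cnh") rep(0, nf) else runif(nf, 3, 10)
    g <- add(nf, fate$tissue, ap = L0 - off, offset = off,
             dv = runif(nf, 0.3, 0.7),
             ml = if (sec %in% c("dorsal")) runif(nf, -0.2, 0.2) else
               sample(c(-1, 1), nf, replace = TRUE) * runif(nf, 0.3, 0.8),
             pool = fate$pool, sector = sec, sched = sched)
    g$clock <- rep(0, nf) # founders are G1-complete, awaiting scheduled S
    groups[[length(groups) + 1]] <- g
    e$next_id <- e$next_id + as.integer(nf)
  }
  nm <- names(groups[[1]])
  e$cells <- setNames(lapply(nm, function(f) unlist(lapply(groups, `[[`, f))), nm)
  e$cells$tissue <- as.character(e$cells$tissue)
  e$cells$pool <- as.character(e$cells$pool)
  e$cells$sector <- as.character(e$cells$sector)

  e$lin_id <- e$cells$id
  e$lin_parent <- rep(NA_integer_, length(e$cells$id))
  e$label_log <- list(t = numeric(), id = integer())
  e$div_log <- list(t = numeric(), id = integer(), ap = numeric(),
                    frac = numeric(), tissue = character())
  e$event_log <- list(t = numeric(), event = character(), detail = character())
  class(e) <- "sim_state"
  e
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %.2f hpf (%.2f ss), axis %.1f um, %d cells\n",
              x$t_hpf, hpf_to_stage(x$t_hpf), x$axis_length, length(x$cells$id)))
  invisible(x)
}

log_event <- function(state, t, event, detail = "") {
  state$event_log$t <- c(state$event_log$t, t)
  state$event_log$event <- c(state$event_log$event, event)
  state$event_log$detail <- c(state$event_log$detail, detail)
}

#' Advance a simulated embryo by one time step
#'
#' Discretised update: phase clocks advance; hydroxyurea windows block G1->S
#' entry and freeze cells already in S (stalled replication forks; G2 and M
#' complete); cells finishing M divide into two daughters that inherit the
#' EdU label; daughters of chordoneural-hinge cells insert at the posterior,
#' adding one cell diameter of axis length per floor-plate/notochord column;
#' presomitic pool cells are deposited into forming posterior somites; cells
#' in S during an active EdU window acquire the heritable label.
#'
#' @param state A `sim_state` environment; modified in place.
#' @param dt Step in hours, `0 < dt <= 0.25`.
#' @return The state, invisibly.
#' @export
sim_step <- function(state, dt = state$config$dt) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive.")
  if (dt > 0.25) abort("`dt` must be <= 0.25 h.")
  p <- state$config
  pr <- state$protocol
  cs <- state$cells
  t0 <- state$t_hpf
  t1 <- t0 + dt
  stage0 <- hpf_to_stage(t0)
  stage1 <- hpf_to_stage(t1)
  hu_on <- !is.null(pr) && window_active(pr$hu_windows, t0, t1)
  edu_on <- !is.null(pr) && window_active(pr$edu_windows, t0, t1)
  ph <- p$phase_hours

  # EdU incorporation: any cell in S while the pulse is active
  if (edu_on) {
    newly <- which(cs$phase == PHASE_S & !cs$edu)
    if (length(newly) > 0) {
      cs$edu[newly] <- TRUE
      state$label_log$t <- c(state$label_log$t, rep(t0, length(newly)))
      state$label_log$id <- c(state$label_log$id, cs$id[newly])
    }
  }

  # phase progression (S frozen under HU)
  adv <- cs$cycling & (cs$phase != PHASE_S | !hu_on) & cs$phase != PHASE_G1
  cs$clock[adv] <- cs$clock[adv] - dt
  g1 <- cs$cycling & cs$phase == PHASE_G1 & cs$clock > 0
  cs$clock[g1] <- pmax(0, cs$clock[g1] - dt)

  done <- which(adv & cs$clock <= 0)
  to_divide <- integer()
  for (i in done) {
    if (cs$phase[i] == PHASE_S) {
      cs$phase[i] <- PHASE_G2
      cs$clock[i] <- ph[["G2"]] * cs$jit[i]
    } else if (cs$phase[i] == PHASE_G2) {
      cs$phase[i] <- PHASE_M
      cs$clock[i] <- ph[["M"]] * cs$jit[i]
    } else if (cs$phase[i] == PHASE_M) {
      to_divide <- c(to_divide, i)
    }
  }

  # divisions
  if (length(to_divide) > 0) {
    keep <- rep(TRUE, length(cs$id))
    new <- list()
    for (i in to_divide) {
      L <- state$axis_length
      state$div_log$t <- c(state$div_log$t, t1)
      state$div_log$id <- c(state$div_log$id, cs$id[i])
      state$div_log$ap <- c(state$div_log$ap, cs$ap[i])
      state$div_log$frac <- c(state$div_log$frac, cs$ap[i] / L)
      state$div_log$tissue <- c(state$div_log$tissue, cs$tissue[i])

      mk <- function(ap, offset, dv, ml, tissue, somite, pool, cycling = TRUE) {
        id <- as.integer(state$next_id)
        state$next_id <- id + 1L
        state$lin_id <- c(state$lin_id, id)
        state$lin_parent <- c(state$lin_parent, cs$id[i])
        list(id = id, parent = cs$id[i], ap = ap, offset = offset,
             dv = dv, ml = ml, tissue = tissue,
             somite_index = as.integer(somite),
             phase = PHASE_G1, clock = ph[["G1"]] * runif(1, 1 - p$phase_jitter,
                                                          1 + p$phase_jitter),
             jit = runif(1, 1 - p$phase_jitter, 1 + p$phase_jitter),
             edu = cs$edu[i], cycling = cycling, pool = pool,
             sector = cs$sector[i], sched_s = NA_real_)
      }
      pool <- cs$pool[i]
      founder_div <- !is.na(cs$sector[i]) && is.na(cs$parent[i])
      if (pool == "cnh" && !founder_div) {
        # one daughter remains in the hinge; the other is deposited as a
        # posterior column (floor plate or notochord, extending the axis)
        # or joins the presomitic pool
        new[[length(new) + 1]] <- mk(L, 0, cs$dv[i], cs$ml[i],
                                     "chordoneural_hinge", NA, "cnh")
        fate <- sample(names(p$cnh_deposit_probs), 1, prob = p$cnh_deposit_probs)
        if (fate == "floor_plate") {
          new[[length(new) + 1]] <- mk(L, NA_real_, runif(1, 0, p$dv_floorplate),
                                       runif(1, -p$ml_floorplate, p$ml_floorplate),
                                       "neural", NA, "none")
          state$axis_length <- L + p$cell_diameter
        } else if (fate == "notochord") {
          new[[length(new) + 1]] <- mk(L, NA_real_, 0.35, rnorm(1, 0, 0.05),
                                       "notochord", NA, "none")
          state$axis_length <- L + p$cell_diameter
        } else {
          new[[length(new) + 1]] <- mk(L - 6, 6, runif(1, 0.3, 0.7),
                                       sample(c(-1, 1), 1) * runif(1, 0.3, 0.8),
                                       "somite", NA, "psm")
        }
      } else if (pool == "pnp" && !founder_div) {
        # growth-zone division: one rider stays, one column is left behind
        new[[length(new) + 1]] <- mk(L - cs$offset[i], cs$offset[i],
                                     cs$dv[i], cs$ml[i], "neural", NA, "pnp")
        new[[length(new) + 1]] <- mk(cs$ap[i], NA_real_, cs$dv[i], cs$ml[i],
                                     "neural", NA, "none", cycling = TRUE)
        state$axis_length <- L + p$cell_diameter
      } else if (pool %in% c("cnh", "psm") && founder_div) {
        # founding division at the blastopore lip: both daughters stay in
        # their sector compartment
        for (d in 1:2) {
          new[[length(new) + 1]] <- mk(L - cs$offset[i], cs$offset[i],
                                       cs$dv[i], cs$ml[i], cs$tissue[i], NA, pool)
        }
      } else if (pool == "psm") {
        for (d in 1:2) {
          new[[length(new) + 1]] <- mk(L - cs$offset[i], cs$offset[i],
                                       runif(1, 0.3, 0.7), cs$ml[i],
                                       "somite", NA, "psm")
        }
      } else {
        # interspersed division: local dilation, no length change
        for (d in 1:2) {
          ap_d <- min(max(cs$ap[i] + runif(1, -2.5, 2.5), 0), state$axis_length)
          new[[length(new) + 1]] <- mk(ap_d, NA_real_,
                                       min(max(cs$dv[i] + runif(1, -0.05, 0.05), 0), 1),
                                       min(max(cs$ml[i] + runif(1, -0.05, 0.05), -1), 1),
                                       cs$tissue[i], cs$somite_index[i], "none")
        }
      }
      keep[i] <- FALSE
    }
    fields <- names(cs)
    newv <- setNames(lapply(fields, function(f) {
      vapply(new, function(cell) cell[[f]], cs[[f]][1][NA])
    }), fields)
    cs <- setNames(lapply(fields, function(f) c(cs[[f]][keep], newv[[f]])), fields)
  }

  # S-phase entry: scheduled founders, then stochastic competence
  ready <- cs$cycling & cs$phase == PHASE_G1 & cs$clock <= 0
  if (!hu_on) {
    sched <- ready & !is.na(cs$sched_s) & cs$sched_s <= t1
    hazard <- which(ready & !sched & is.na(cs$sched_s))
    entered <- which(sched)
    if (length(hazard) > 0) {
      state$cells <- cs # division_rate reads the updated vectors
      rate <- division_rate(state, cells = hazard)
      go <- runif(length(hazard)) < 1 - exp(-rate * dt)
      entered <- c(entered, hazard[go])
    }
    if (length(entered) > 0) {
      cs$phase[entered] <- PHASE_S
      cs$clock[entered] <- ph[["S"]] * cs$jit[entered]
      cs$sched_s[entered] <- NA_real_
    }
  }

  # somite formation from the presomitic pool
  ks <- seq(p$posterior_somite_start, p$total_somites)
  formed <- ks[stage0 < ks & stage1 >= ks]
  for (k in formed) {
    pool_idx <- which(cs$pool == "psm")
    if (length(pool_idx) > 0) {
      dep <- pool_idx[runif(length(pool_idx)) < p$somite_deposit_prob]
      if (length(dep) > 0) {
        cs$pool[dep] <- "none"
        cs$tissue[dep] <- "somite"
        cs$somite_index[dep] <- k
        cs$ap[dep] <- state$axis_length - 12 + runif(length(dep), -4, 4)
        cs$offset[dep] <- NA_real_
        cs$cycling[dep] <- FALSE
        cs$phase[dep] <- PHASE_G1
        cs$clock[dep] <- 0
      }
    }
    log_event(state, t1, "somite_formed", as.character(k))
  }

  # growth-zone dissolution: posterior neural riders become ordinary
  # neural-tube cells once division resumes axis-wide
  if (stage0 <= p$pnp_stop_ss && stage1 > p$pnp_stop_ss) {
    cs$pool[cs$pool == "pnp"] <- "none"
    cs$offset[cs$tissue == "neural"] <- NA_real_
    log_event(state, t1, "pnp_dissolved")
  }

  # riders keep station relative to the advancing tip
  riders <- !is.na(cs$offset)
  cs$ap[riders] <- state$axis_length - cs$offset[riders]

  if (!is.null(pr)) {
    for (w in pr$edu_windows) {
      if (t0 < w[2] && t1 >= w[2]) log_event(state, t1, "edu_washout")
      if (t0 <= w[1] && t1 > w[1]) log_event(state, t1, "edu_pulse_start")
    }
    for (w in pr$hu_windows) {
      if (t0 <= w[1] && t1 > w[1]) log_event(state, t1, "hu_start")
      if (t0 < w[2] && t1 >= w[2]) log_event(state, t1, "hu_end")
    }
  }

  state$cells <- cs
  state$t_hpf <- t1
  invisible(state)
}

#' Fix a simulated embryo and export its nucleus table
#'
#' Exports one nucleus per cell at fixation. The EdU flag is the heritable
#' label (set by S-phase traversal during a pulse window, inherited by
#' daughters; entries into S after washout never label); the PhH3 flag marks
#' cells in M phase at the moment of fixation. Positions are mapped to
#' 3D micrometre coordinates (x along the axis, y mediolateral, z
#' dorsoventral) with Gaussian jitter of `noise` um; landmarks are the
#' anterior tip at the origin and the chordoneural hinge at
#' `(axis_length, 0, 0)`.
#'
#' @param state A `sim_state` advanced to the protocol's fixation time.
#' @param protocol The applied [protocol()]; defaults to the one in `state`.
#' @param noise Positional jitter standard deviation, um.
#' @param embryo_id Identifier recorded in the output tables.
#' @return A list with `nuclei` (tibble: id, x_um, y_um, z_um, ap_um, tissue,
#'   somite_index, edu, phh3, floor_plate, embryo_id, stage_ss) and
#'   `landmarks` (one-row tibble with tip and hinge coordinates).
#' @export
apply_protocol_and_fix <- function(state, protocol = state$protocol,
                                   noise = state$config$jitter_sigma_um,
                                   embryo_id = "embryo_1") {
  if (is.null(protocol)) abort("No protocol attached to this simulation.")
  if (state$t_hpf < protocol$fixation_hpf - 1e-6) {
    abort(sprintf("Simulation is at %.2f hpf but fixation is %.2f hpf.",
                  state$t_hpf, protocol$fixation_hpf))
  }
  p <- state$config
  cs <- state$cells
  n <- length(cs$id)
  stage <- hpf_to_stage(state$t_hpf)
  nuclei <- tibble(
    id = cs$id,
    x_um = cs$ap + rnorm(n, 0, noise),
    y_um = cs$ml * p$half_width_um + rnorm(n, 0, noise),
    z_um = cs$dv * p$dv_height_um + rnorm(n, 0, noise),
    ap_um = cs$ap,
    tissue = cs$tissue,
    somite_index = cs$somite_index,
    edu = cs$edu,
    phh3 = cs$phase == PHASE_M,
    # floor plate is the ventral midline of the neural tube proper; the
    # cerebral vesicle (anterior fraction of the axis) has no floor plate
    floor_plate = cs$tissue == "neural" & cs$dv < p$dv_floorplate &
      abs(cs$ml) <= p$ml_floorplate &
      cs$ap / state$axis_length > p$ap_anterior_frac,
    embryo_id = embryo_id,
    stage_ss = stage
  )
  landmarks <- tibble(
    embryo_id = embryo_id, stage_ss = stage,
    tip_x = 0, tip_y = 0, tip_z = 0,
    hinge_x = state$axis_length, hinge_y = 0, hinge_z = 0
  )
  list(nuclei = nuclei, landmarks = landmarks)
}

#' Simulate one embryo under a protocol
#'
#' Runs the agent-based simulation from `config$t_start_hpf` to the
#' protocol's fixation time and exports the nucleus table. All randomness is
#' drawn from a private stream seeded with `seed`, so identical seeds and
#' protocols yield identical exports.
#'
#' @param protocol A [protocol()].
#' @param config A [sim_config()].
#' @param ratemap A `rate_map`; defaults to [default_ratemap()] of `config`.
#' @param seed Integer seed for this embryo.
#' @param embryo_id Identifier used in the exported tables.
#' @param keep_state If `TRUE`, return the final `sim_state` as well.
#' @return A list with `nuclei` and `landmarks` tibbles (and `state` if
#'   requested).
#' @examples
#' emb <- simulate_embryo(protocol(list(c(18, 20)), fixation_hpf = 20), seed = 1)
#' dplyr::count(emb$nuclei, tissue, edu)
#' @export
simulate_embryo <- function(protocol, config = sim_config(),
                            ratemap = default_ratemap(config), seed = 1L,
                            embryo_id = "embryo_1", keep_state = FALSE) {
  with_seed(seed, {
    state <- sim_init(config, ratemap, protocol)
    while (state$t_hpf < protocol$fixation_hpf - 1e-9) {
      sim_step(state, min(config$dt, protocol$fixation_hpf - state$t_hpf))
    }
    out <- apply_protocol_and_fix(state, protocol, embryo_id = embryo_id)
    if (keep_state) out$state <- state
    out
  })
}

#' Simulate a cohort of embryos
#'
#' Independent embryos under a common protocol, each with its own derived
#' seed (`seed + i - 1`).
#'
#' @inheritParams simulate_embryo
#' @param n Number of embryos.
#' @param embryo_prefix Prefix for embryo identifiers.
#' @return A list with stacked `nuclei` and `landmarks` tibbles.
#' @export
simulate_cohort <- function(protocol, n, config = sim_config(),
                            ratemap = default_ratemap(config), seed = 1L,
                            embryo_prefix = "embryo") {
  runs <- lapply(seq_len(n), function(i) {
    simulate_embryo(protocol, config, ratemap, seed = seed + i - 1L,
                    embryo_id = sprintf("%s_%02d", embryo_prefix, i))
  })
  list(nuclei = list_rbind(map(runs, "nuclei")),
       landmarks = list_rbind(map(runs, "landmarks")))
}

#' Check heritable-label bookkeeping of a finished simulation
#'
#' Verifies that every EdU-positive cell at fixation traces, through the
#' lineage map, to a cell that was directly labelled while in S phase during
#' an EdU window.
#'
#' @param state A `sim_state`.
#' @return `TRUE` if the bookkeeping is exact; otherwise a vector of
#'   offending cell ids.
#' @export
verify_label_lineage <- function(state) {
  labelled <- unique(state$label_log$id)
  parent <- setNames(state$lin_parent, state$lin_id)
  pos <- which(state$cells$edu)
  bad <- integer()
  for (i in pos) {
    id <- state$cells$id[i]
    ok <- FALSE
    while (!is.na(id)) {
      if (id %in% labelled) { ok <- TRUE; break }
      id <- parent[[as.character(id)]]
    }
    if (!ok) bad <- c(bad, state$cells$id[i])
  }
  if (length(bad) == 0) TRUE else bad
}

#' Tidy views of a simulation's logs
#'
#' @param state A `sim_state`.
#' @return `division_log()`: tibble of divisions (time, mother id, axial
#'   position and fraction, tissue). `sim_events()`: tibble of protocol and
#'   morphogenetic events.
#' @export
division_log <- function(state) {
  as_tibble(state$div_log) %>%
    rename(t_hpf = "t", mother_id = "id", ap_um = "ap", ap_frac = "frac")
}

#' @rdname division_log
#' @export
sim_events <- function(state) {
  as_tibble(state$event_log) %>% rename(t_hpf = "t")
}
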