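#' Simulator configuration
#'
#' All tunable parameters of the agent-based embryo simulator, with defaults
#' chosen to emulate *Branchiostoma lanceolatum* neurulation at 21 deg C:
#' a late-gastrula starting axis of 150 um, a 5 um cell diameter, fixed
#' cell-cycle phase durations (G1 2 h, S 1.5 h, G2 0.5 h, M 0.5 h) with a
#' +/-10% per-cell multiplicative jitter so that a 2 h EdU pulse reliably
#' marks cells traversing S phase, and stage-gated proliferative domains
#' (see [default_ratemap()]).
#'
#' Division-competence entry rates (`rates`, per hour, applied to cells that
#' have completed their minimum G1) and the initial pool sizes are calibrated
#' so that cohort means reproduce the magnitudes reported for this system:
#' hydroxyurea-arrested embryos reach less than half the control axis length
#' by the 14-somite stage, 7-8 ss posterior pulse-chases cover roughly one
#' third of the floor plate at 12 ss, 2 h pulses at 10 ss label about 3-5
#' anterior neural nuclei, and late-gastrula dorsal-lip pulses label the
#' posterior 4-5 somites.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_neural = 60, dt = 0.25)
#' cfg$rates
#' @export
sim_config <- function(...) {
  defaults <- list(
    t_start_hpf = 8,         # simulation start (mid/late gastrula)
    dt = 0.1,                # integration step, hours (must be <= 0.25)
    axis_length0 = 150,      # initial anterior tip -> hinge distance, um
    cell_diameter = 5,       # um added per posterior column insertion
    # initial cell numbers
    n_neural = 120,          # in-place neural plate/tube cells
    n_pnp = 18,              # posterior neural-plate growth-zone cells
    pnp_zone_um = 25,        # depth of the posterior growth zone, um
    n_notochord = 40,
    n_endoderm = 60,
    n_somite_cells = 6,      # per preformed somite
    n_preformed_somites = 9, # somites formed from gastrula paraxial mesoderm
    n_founders = c(dorsal = 8, upper_lateral = 8,
                   lower_lateral = 8, ventral = 8),
    total_somites = 14,
    posterior_somite_start = 10, # first somite drawn from the tailbud pool
    somite_deposit_prob = 0.35,  # per pool cell, per forming somite
    # cell cycle
    phase_hours = c(G1 = 2, S = 1.5, G2 = 0.5, M = 0.5),
    phase_jitter = 0.1,
    # S-entry hazard rates per hour, by compartment/tissue
    rates = c(neural = 0.30, cnh = 0.14, psm = 0.10,
              endoderm = 0.08, somite = 0.10, notochord = 0.10),
    # anterior cerebral-vesicle strata: relative competence by dorsoventral
    # position; the ventral stratum divides first and most strongly
    anterior_strata = c(ventral = 1, lateral = 0.8, dorsal = 0.5),
    late_neural_mult = 0.25, # low resumed division after 10 ss
    somite_mult = 0.2,       # housekeeping division in formed somites
    endoderm_late_mult = 0.3,
    notochord_late_mult = 0.3,
    # geometry of the proliferative domains (fractions of axis length)
    ap_anterior_frac = 0.15,
    ap_posterior_frac = 0.85,
    dv_floorplate = 0.2,
    ml_floorplate = 0.2,
    ml_lateral_band = 0.6,
    # stage gates
    cnh_resume_ss = 6,       # chordoneural hinge re-enters the cycle
    pnp_stop_ss = 10,        # posterior neural growth zone dissolves
    psm_active_ss = c(1, 10),
    cnh_deposit_probs = c(floor_plate = 0.5, notochord = 0.3, somite = 0.2),
    # blastopore-lip sectors traverse S in sector-specific windows (hpf)
    sector_s_windows = list(dorsal = c(10, 12), upper_lateral = c(10, 12),
                            lower_lateral = c(12, 14), ventral = c(12, 14)),
    # export geometry
    jitter_sigma_um = 2,
    half_width_um = 8,       # mediolateral half-width used for y positions
    dv_height_um = 16,       # dorsoventral height used for z positions
    apoptosis = FALSE        # cell death outside the modelled window
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown sim_config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  if (cfg$dt <= 0 || cfg$dt > 0.25) abort("`dt` must be in (0, 0.25] hours.")
  structure(cfg, class = c("sim_config", "list"))
}
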