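#' Stage-dependent division-competence map
#'
#' Builds the rate map used by the simulator: a function of somite stage,
#' tissue, normalised axial position (ap / axis length), dorsoventral and
#' mediolateral coordinates that returns a multiplier in \[0, 1\], combined
#' with per-compartment base entry rates (per hour). The default map encodes
#' the three observed phases of neural proliferation:
#'
#' * before 5 ss, neural division is confined to the posterior growth zone
#'   of the neural plate (the extreme posterior, adjacent to the dorsal
#'   blastopore lip);
#' * between 5 and 10 ss, division is restricted to the two poles: the
#'   posterior growth zone plus the anterior cerebral vesicle, where
#'   competence sweeps dorsoventrally (ventral cells at 6-7 ss, lateral at
#'   7-8 ss, dorsal at 9-10 ss) and the central axis is quiescent;
#' * after 10 ss, division resumes at a low level, but only in floor-plate
#'   (ventral midline) and lateral-wall neural cells.
#'
#' The chordoneural hinge re-enters the cycle at `cnh_resume_ss`; endoderm
#' and formed somites cycle at modest housekeeping rates from 5 ss onwards.
#'
#' @param config A [sim_config()] list.
#' @param domains Character subset of `c("anterior", "posterior")`: which
#'   neural proliferative domains are active. Dropping `"posterior"` silences
#'   the posterior growth zone, chordoneural hinge and presomitic pool
#'   (useful to study anterior clones in isolation); dropping `"anterior"`
#'   silences the cerebral-vesicle strata.
#' @return An object of class `"rate_map"` with elements `base` (named rates
#'   per hour) and `multiplier` (vectorised function).
#' @examples
#' rm <- default_ratemap(sim_config())
#' # central neural tube at 7 ss is quiescent:
#' rm$multiplier(7, "neural", 0.5, 0.5, 0, "none")
#' @export
default_ratemap <- function(config = sim_config(),
                            domains = c("anterior", "posterior")) {
  p <- config
  domains <- match.arg(domains, several.ok = TRUE)
  anterior_on <- "anterior" %in% domains
  posterior_on <- "posterior" %in% domains

  multiplier <- function(stage, tissue, ap_frac, dv, ml, pool = "none") {
    n <- max(length(tissue), length(ap_frac), length(dv), length(ml), length(pool))
    tissue <- rep_len(tissue, n); ap_frac <- rep_len(ap_frac, n)
    dv <- rep_len(dv, n); ml <- rep_len(ml, n); pool <- rep_len(pool, n)
    m <- numeric(n)
    stage <- stage[1]

    neural <- tissue == "neural"
    pnp <- pool == "pnp"
    if (posterior_on) m[neural & pnp] <- 1
    if (stage >= 5 && stage <= 10 && anterior_on) {
      ant <- neural & !pnp & ap_frac <= p$ap_anterior_frac
      strata <- p$anterior_strata
      m[ant & dv < 1 / 3 & stage >= 6 & stage < 7] <- strata[["ventral"]]
      m[ant & dv >= 1 / 3 & dv < 2 / 3 & stage >= 7 & stage < 8] <- strata[["lateral"]]
      m[ant & dv >= 2 / 3 & stage >= 9 & stage < 10] <- strata[["dorsal"]]
    }
    if (stage > 10) {
      fp <- neural & dv < p$dv_floorplate & abs(ml) <= p$ml_floorplate
      lat <- neural & abs(ml) >= p$ml_lateral_band
      m[fp | lat] <- p$late_neural_mult
    }

    cnh <- tissue == "chordoneural_hinge"
    if (posterior_on && stage >= p$cnh_resume_ss) m[cnh] <- 1

    psm <- pool == "psm"
    m[psm] <- 0
    if (posterior_on && stage >= p$psm_active_ss[1] && stage <= p$psm_active_ss[2]) {
      m[psm] <- 1
    }

    if (stage >= 5) {
      endo <- tissue == "endoderm"
      m[endo] <- if (stage > 10) p$endoderm_late_mult else 1
      som <- tissue == "somite" & !psm
      m[som] <- p$somite_mult
      noto <- tissue == "notochord"
      m[noto] <- if (stage > 10) p$notochord_late_mult else 0
    }
    m
  }

  base <- c(
    neural = p$rates[["neural"]],
    chordoneural_hinge = p$rates[["cnh"]],
    notochord = p$rates[["notochord"]],
    somite = p$rates[["somite"]],
    endoderm = p$rates[["endoderm"]],
    psm = p$rates[["psm"]]
  )
  structure(list(base = base, multiplier = multiplier, domains = domains),
            class = "rate_map")
}

#' Per-cell division-competence rate
#'
#' Returns the S-phase entry hazard (per hour) for cells of a simulation
#' state: the compartment base rate times the rate-map multiplier at the
#' current stage and position. Arrested or post-mitotic cells (`cycling =
#' FALSE`) always return 0.
#'
#' @param state A `sim_state` (see [sim_init()]).
#' @param cells Optional integer indices of cells to evaluate (default all).
#' @param ratemap A `rate_map`; defaults to the one stored in `state`.
#' @return Numeric vector of rates per hour.
#' @export
division_rate <- function(state, cells = NULL, ratemap = state$ratemap) {
  cs <- state$cells
  idx <- cells %||% seq_along(cs$id)
  stage <- hpf_to_stage(state$t_hpf)
  base_key <- ifelse(cs$pool[idx] == "psm", "psm", cs$tissue[idx])
  base <- unname(ratemap$base[base_key])
  base[is.na(base)] <- 0
  mult <- ratemap$multiplier(stage, cs$tissue[idx], cs$ap[idx] / state$axis_length,
                             cs$dv[idx], cs$ml[idx], cs$pool[idx])
  rate <- base * mult
  rate[!cs$cycling[idx]] <- 0
  rate
}
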