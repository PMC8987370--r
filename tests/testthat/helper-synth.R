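library(dplyr)

# A nucleus-table row factory with all required columns defaulted.
toy_nuclei <- function(x, y = 0, z = 0, tissue = "neural", edu = TRUE,
                       phh3 = FALSE, floor_plate = FALSE,
                       somite_index = NA_integer_, embryo_id = "a",
                       stage_ss = 7) {
  tibble::tibble(
    id = seq_along(x), x_um = x, y_um = y, z_um = z, ap_um = x,
    tissue = tissue, somite_index = as.integer(somite_index),
    edu = edu, phh3 = phh3, floor_plate = floor_plate,
    embryo_id = embryo_id, stage_ss = stage_ss
  )
}

toy_landmarks <- function(embryo_id, length_um, stage_ss = 7) {
  tibble::tibble(
    embryo_id = embryo_id, stage_ss = stage_ss,
    tip_x = 0, tip_y = 0, tip_z = 0,
    hinge_x = length_um, hinge_y = 0, hinge_z = 0
  )
}

# Synthetic cohort with implanted anterior/posterior proliferative domains:
# labelled nuclei drawn uniformly inside [0, ant_frac*L) and [pos_frac*L, L],
# nothing in between. Ground truth for domain-boundary recovery.
implanted_cohort <- function(n_embryos = 10, ant_frac = 0.15, pos_frac = 0.85,
                             mean_ant = 10, mean_pos = 20) {
  nuc <- list(); lm <- list()
  for (i in seq_len(n_embryos)) {
    em <- sprintf("imp_%02d", i)
    L <- runif(1, 230, 270)
    xa <- runif(rpois(1, mean_ant), 0, ant_frac * L * 0.999)
    xp <- runif(rpois(1, mean_pos), pos_frac * L, L)
    nuc[[i]] <- toy_nuclei(c(xa, xp), embryo_id = em)
    lm[[i]] <- toy_landmarks(em, L)
  }
  list(nuclei = dplyr::bind_rows(nuc), landmarks = dplyr::bind_rows(lm))
}
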