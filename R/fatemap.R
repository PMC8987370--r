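#' Per-tissue labelled-nucleus profiles in evenly sized axial bins
#'
#' Assigns each EdU-positive nucleus a normalised anteroposterior position
#' (axial distance over the embryo's neural-tube length) and counts labelled
#' nuclei per tissue in `n_bins` equal bins of `[0, 1]` (half-open, last bin
#' closed at 1). Floor-plate nuclei are profiled as their own tissue class
#' (`"floor_plate"`) when the nucleus table carries the `floor_plate` flag.
#'
#' @param nuclei Nucleus table (needs `embryo_id`, coordinates, `tissue`,
#'   `edu`; optional logical `floor_plate`).
#' @param landmarks Landmark table (one row per embryo, as produced by the
#'   simulator or [read_nuclei()]).
#' @param n_bins Number of equal bins of the normalised axis (default 10).
#' @param marker Marker column to profile (default `"edu"`).
#' @param split_floorplate Profile floor-plate nuclei separately from the
#'   rest of the neural tube (default `TRUE`).
#' @return Tibble with one row per embryo x tissue x bin: `embryo_id`,
#'   `tissue`, `bin` (1-based), `count`, `total_labeled`.
#' @export
tissue_profiles <- function(nuclei, landmarks, n_bins = 10, marker = "edu",
                            split_floorplate = TRUE) {
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  if (any(is.na(nuclei$tissue))) {
    bad <- nuclei$id[is.na(nuclei$tissue)]
    abort(paste0("Nuclei with missing tissue labels: ",
                 paste(utils::head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }
  lengths <- embryo_lengths(landmarks)
  rows <- list()
  for (i in seq_len(nrow(landmarks))) {
    em <- landmarks$embryo_id[i]
    nuc <- nuclei[nuclei$embryo_id == em & nuclei[[marker]], , drop = FALSE]
    tis <- nuc$tissue
    if (split_floorplate && "floor_plate" %in% names(nuc)) {
      tis[nuc$floor_plate] <- "floor_plate"
    }
    if (nrow(nuc) > 0) {
      d <- axial_distance(nuc, unlist(landmarks[i, c("tip_x", "tip_y", "tip_z")]))
      ap_norm <- normalize_and_scale(d, lengths$length_um[i], 1)
    } else {
      ap_norm <- numeric()
    }
    all_tissues <- unique(c(tis, if (split_floorplate) "floor_plate",
                            unique(nuclei$tissue[nuclei$embryo_id == em])))
    for (tt in sort(all_tissues)) {
      sel <- !is.na(ap_norm) & tis == tt
      counts <- tabulate(pmin(floor(ap_norm[sel] * n_bins), n_bins - 1) + 1,
                         nbins = n_bins)
      rows[[length(rows) + 1]] <- tibble(
        embryo_id = em, tissue = tt, bin = seq_len(n_bins),
        count = counts, total_labeled = sum(counts)
      )
    }
  }
  list_rbind(rows)
}

#' Cohort mean fate-map profiles
#'
#' Arithmetic mean of per-embryo per-tissue bin counts across a cohort of
#' embryos that shared one pulse-chase condition.
#'
#' @inheritParams tissue_profiles
#' @param condition Optional condition label recorded in the output.
#' @return Tibble: `condition`, `tissue`, `bin`, `mean_frequency`,
#'   `n_embryos`.
#' @export
cohort_profiles <- function(nuclei, landmarks, n_bins = 10, marker = "edu",
                            condition = NA_character_,
                            split_floorplate = TRUE) {
  if (nrow(landmarks) < 1) abort("Need at least one embryo.")
  prof <- tissue_profiles(nuclei, landmarks, n_bins, marker, split_floorplate)
  n_emb <- length(unique(landmarks$embryo_id))
  prof %>%
    group_by(.data$tissue, .data$bin) %>%
    summarise(mean_frequency = sum(.data$count) / n_emb, .groups = "drop") %>%
    mutate(condition = condition, n_embryos = n_emb) %>%
    select("condition", "tissue", "bin", "mean_frequency", "n_embryos")
}

#' Floor-plate clone coverage fraction
#'
#' Fraction of the floor plate's anteroposterior extent covered by the
#' labelled clone, measured from the anterior-most labelled floor-plate
#' nucleus to the posterior end (clones extend anteriorly from the
#' chordoneural hinge, so coverage is a contiguous posterior extent).
#' `mode = "count"` instead returns the labelled fraction of floor-plate
#' nuclei.
#'
#' @inheritParams tissue_profiles
#' @param mode `"extent"` (default) or `"count"`.
#' @return Tibble: `embryo_id`, `floorplate_fraction` in `[0, 1]`.
#' @export
floorplate_clone_fraction <- function(nuclei, landmarks, mode = c("extent", "count"),
                                      marker = "edu") {
  mode <- match.arg(mode)
  if (!"floor_plate" %in% names(nuclei)) {
    abort("`nuclei` must carry a logical `floor_plate` column.")
  }
  lengths <- embryo_lengths(landmarks)
  rows <- lapply(seq_len(nrow(landmarks)), function(i) {
    em <- landmarks$embryo_id[i]
    fp <- nuclei[nuclei$embryo_id == em & nuclei$floor_plate, , drop = FALSE]
    if (nrow(fp) == 0) {
      abort(paste0("Embryo ", em, " has no floor-plate-annotated nuclei."))
    }
    d <- axial_distance(fp, unlist(landmarks[i, c("tip_x", "tip_y", "tip_z")]))
    lab <- fp[[marker]]
    frac <- if (!any(lab)) {
      0
    } else if (mode == "extent") {
      extent <- max(d) - min(d)
      if (extent <= 0) 1 else min(1, (max(d) - min(d[lab])) / extent)
    } else {
      mean(lab)
    }
    tibble(embryo_id = em, floorplate_fraction = frac)
  })
  list_rbind(rows)
}

#' Labelled posterior somite count
#'
#' Number of distinct somites containing at least `min_cells` labelled
#' nuclei. Somites are counted from the posterior end; non-contiguous
#' qualifying somites are reported in the `gaps` column.
#'
#' @inheritParams tissue_profiles
#' @param min_cells Minimum labelled nuclei for a somite to count
#'   (default 2, suppressing jitter-induced singletons).
#' @return Tibble: `embryo_id`, `labeled_posterior_somites`, `contiguous`,
#'   `gaps` (comma-separated skipped indices, `""` if none).
#' @export
labeled_somite_count <- function(nuclei, min_cells = 2, marker = "edu") {
  rows <- lapply(unique(nuclei$embryo_id), function(em) {
    som <- nuclei[nuclei$embryo_id == em & nuclei$tissue == "somite" &
                    !is.na(nuclei$somite_index) & nuclei[[marker]], , drop = FALSE]
    if (nrow(som) == 0) {
      return(tibble(embryo_id = em, labeled_posterior_somites = 0L,
                    contiguous = TRUE, gaps = ""))
    }
    tab <- table(som$somite_index)
    qual <- sort(as.integer(names(tab)[tab >= min_cells]))
    if (length(qual) == 0) {
      return(tibble(embryo_id = em, labeled_posterior_somites = 0L,
                    contiguous = TRUE, gaps = ""))
    }
    gaps <- setdiff(seq(min(qual), max(qual)), qual)
    tibble(embryo_id = em, labeled_posterior_somites = length(qual),
           contiguous = length(gaps) == 0,
           gaps = paste(gaps, collapse = ","))
  })
  list_rbind(rows)
}

#' Clone-extent statistics per embryo
#'
#' Combines the floor-plate coverage fraction, the labelled posterior somite
#' count and the normalised position of the anterior-most labelled nucleus.
#'
#' @inheritParams tissue_profiles
#' @inheritParams floorplate_clone_fraction
#' @inheritParams labeled_somite_count
#' @return Tibble: `embryo_id`, `floorplate_fraction`,
#'   `labeled_posterior_somites`, `anteriormost_labeled_ap_norm`.
#' @export
clone_stats <- function(nuclei, landmarks, mode = "extent", min_cells = 2,
                        marker = "edu") {
  fp <- floorplate_clone_fraction(nuclei, landmarks, mode, marker)
  som <- labeled_somite_count(nuclei, min_cells, marker)
  lengths <- embryo_lengths(landmarks)
  ant <- lapply(seq_len(nrow(landmarks)), function(i) {
    em <- landmarks$embryo_id[i]
    nuc <- nuclei[nuclei$embryo_id == em & nuclei[[marker]], , drop = FALSE]
    a <- if (nrow(nuc) == 0) NA_real_ else {
      d <- axial_distance(nuc, unlist(landmarks[i, c("tip_x", "tip_y", "tip_z")]))
      min(normalize_and_scale(d, lengths$length_um[i], 1), na.rm = TRUE)
    }
    tibble(embryo_id = em, anteriormost_labeled_ap_norm = a)
  })
  fp %>%
    left_join(select(som, "embryo_id", "labeled_posterior_somites"),
              by = "embryo_id") %>%
    left_join(list_rbind(ant), by = "embryo_id")
}
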