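#' Axial distance of nuclei from the anterior tip
#'
#' Straight-line 3D Euclidean distance between each nucleus and the anterior
#' tip of the cerebral vesicle. Distances are always straight-line, even for
#' curved embryos; pass positions along a straightened axis to
#' `x`/`y`/`z` if an arc-length measure is wanted.
#'
#' @param nuclei Data frame with numeric `x_um`, `y_um`, `z_um` columns.
#' @param anterior_tip Numeric length-3 vector `(x, y, z)` in um.
#' @return Numeric vector of distances (um), one per nucleus.
#' @examples
#' axial_distance(data.frame(x_um = 3, y_um = 4, z_um = 0), c(0, 0, 0)) # 5
#' @export
axial_distance <- function(nuclei, anterior_tip) {
  stopifnot(length(anterior_tip) == 3)
  xyz <- as.matrix(nuclei[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(xyz)) || !all(is.finite(anterior_tip))) {
    abort("Nucleus and landmark coordinates must be finite.")
  }
  unname(sqrt((xyz[, 1] - anterior_tip[1])^2 +
                (xyz[, 2] - anterior_tip[2])^2 +
                (xyz[, 3] - anterior_tip[3])^2))
}

#' Normalise axial distances to embryo length and rescale to the cohort mean
#'
#' Each distance is divided by the embryo's own neural-tube length (anterior
#' tip to chordoneural hinge) and multiplied by the cohort mean length, so
#' embryos of different sizes are compared on a common axis. Distances that
#' exceed the embryo length by up to 2% (landmark jitter) are clamped to the
#' mean length; larger excesses indicate a landmark/measurement inconsistency
#' and are excluded (`NA`) with a warning.
#'
#' @param d Numeric distances (um).
#' @param length Embryo neural-tube length (um), > 0.
#' @param mean_length Cohort mean neural-tube length (um), > 0.
#' @return Scaled positions in `[0, mean_length]`; excluded values are `NA`.
#' @examples
#' normalize_and_scale(55, 220, 200) # 50
#' @export
normalize_and_scale <- function(d, length, mean_length) {
  if (!is.numeric(length) || length <= 0 || !is.numeric(mean_length) ||
      mean_length <= 0) {
    abort("`length` and `mean_length` must be positive.")
  }
  frac <- d / length
  out <- frac * mean_length
  clamp <- frac > 1 & frac <= 1.02
  out[clamp] <- mean_length
  bad <- frac > 1.02 | frac < 0
  if (any(bad)) {
    warn(sprintf("%d nucleus distance(s) exceed embryo length by > 2%%; excluded.",
                 sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Bin axial positions into fixed-width bins
#'
#' Counts positions in half-open bins `[k*w, (k+1)*w)` anchored at the
#' anterior tip; the terminal (possibly partial) bin is closed at `extent`.
#'
#' @param positions Numeric positions in `[0, extent]` (um). `NA`s dropped.
#' @param bin_width Bin width (um), > 0.
#' @param extent Axis extent (um), > 0. The number of bins is
#'   `ceiling(extent / bin_width)`.
#' @return Integer vector of counts; `sum(counts) == length(positions)`.
#' @examples
#' bin_frequencies(c(5, 19.9, 25), 20, 40) # c(2, 1)
#' @export
bin_frequencies <- function(positions, bin_width, extent) {
  if (!is.numeric(extent) || length(extent) != 1 || !is.finite(extent) ||
      extent <= 0) {
    abort("`extent` must be a single positive number.")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0.")
  positions <- positions[!is.na(positions)]
  if (any(positions < 0 | positions > extent)) {
    abort("All positions must lie within [0, extent].")
  }
  n_bins <- ceiling(extent / bin_width)
  idx <- pmin(floor(positions / bin_width), n_bins - 1) + 1
  tabulate(idx, nbins = n_bins)
}

#' Cohort mean landscape row for one stage
#'
#' For a cohort of same-stage embryos: computes each labelled nucleus's
#' axial distance, normalises to the embryo's length and rescales to the
#' cohort mean length, bins over `[0, mean_length]`, and averages the
#' per-bin counts across embryos ("normalised to embryo number").
#'
#' @param nuclei Nucleus table (columns `embryo_id`, `x_um`, `y_um`, `z_um`,
#'   and the marker columns `edu`/`phh3`).
#' @param landmarks Landmark table: one row per embryo with `embryo_id`,
#'   `stage_ss`, `tip_x/y/z`, `hinge_x/y/z`.
#' @param marker `"edu"` or `"phh3"`.
#' @param bin_width Bin width in um (default 20).
#' @return A tibble with one row per bin: `stage_ss`, `bin_index`,
#'   `bin_start_um`, `marker`, `mean_frequency`, `n_embryos`,
#'   `mean_length_um`, `partial_bin`.
#' @export
cohort_landscape <- function(nuclei, landmarks, marker = c("edu", "phh3"),
                             bin_width = 20) {
  marker <- match.arg(marker)
  if (nrow(landmarks) < 1) abort("Need at least one embryo.")
  stages <- unique(round(landmarks$stage_ss))
  if (length(stages) != 1) {
    abort("All embryos in a cohort must share one somite stage.")
  }
  lengths <- embryo_lengths(landmarks)
  mean_len <- mean(lengths$length_um)
  n_bins <- ceiling(mean_len / bin_width)
  counts <- matrix(0, nrow = nrow(landmarks), ncol = n_bins)
  for (i in seq_len(nrow(landmarks))) {
    em <- landmarks$embryo_id[i]
    nuc <- nuclei[nuclei$embryo_id == em & nuclei[[marker]], , drop = FALSE]
    if (nrow(nuc) == 0) next
    d <- axial_distance(nuc, unlist(landmarks[i, c("tip_x", "tip_y", "tip_z")]))
    s <- normalize_and_scale(d, lengths$length_um[i], mean_len)
    counts[i, ] <- bin_frequencies(s, bin_width, mean_len)
  }
  tibble(
    stage_ss = stages,
    bin_index = seq_len(n_bins) - 1L,
    bin_start_um = (seq_len(n_bins) - 1L) * bin_width,
    marker = marker,
    mean_frequency = colMeans(counts),
    n_embryos = nrow(landmarks),
    mean_length_um = mean_len,
    partial_bin = seq_len(n_bins) * bin_width > mean_len
  )
}

embryo_lengths <- function(landmarks) {
  tibble(
    embryo_id = landmarks$embryo_id,
    length_um = sqrt((landmarks$hinge_x - landmarks$tip_x)^2 +
                       (landmarks$hinge_y - landmarks$tip_y)^2 +
                       (landmarks$hinge_z - landmarks$tip_z)^2)
  )
}

#' Assemble a proliferation landscape across stages
#'
#' Groups embryos by (rounded) somite stage, computes the per-stage cohort
#' landscape for each marker, and stacks them into a stage-ordered tidy
#' table: the stage x axial-bin matrix of mean labelled-nucleus frequencies.
#'
#' @inheritParams cohort_landscape
#' @param markers Character vector of marker columns (default both).
#' @return An object of class `"proliferation_landscape"`: a list with the
#'   tidy `table` (stage_ss, bin_index, bin_start_um, marker, mean_frequency,
#'   n_embryos, mean_length_um, partial_bin) and `bin_width`. Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
assemble_landscape <- function(nuclei, landmarks, markers = c("edu", "phh3"),
                               bin_width = 20) {
  landmarks <- mutate(landmarks, .stage = round(.data$stage_ss))
  rows <- list()
  for (st in sort(unique(landmarks$.stage))) {
    lm <- filter(landmarks, .data$.stage == st)
    for (mk in markers) {
      rows[[length(rows) + 1]] <-
        cohort_landscape(nuclei, select(lm, -".stage"), mk, bin_width)
    }
  }
  structure(list(table = list_rbind(rows) %>% arrange(.data$stage_ss, .data$marker,
                                                      .data$bin_index),
                 bin_width = bin_width),
            class = "proliferation_landscape")
}

#' @export
print.proliferation_landscape <- function(x, ...) {
  st <- unique(x$table$stage_ss)
  cat(sprintf("<proliferation_landscape> %d stage(s) [%s ss], %g um bins, markers: %s\n",
              length(st), paste(range(st), collapse = "-"), x$bin_width,
              paste(unique(x$table$marker), collapse = ", ")))
  print(x$table, n = 6)
  invisible(x)
}

#' Detect contiguous proliferative domains in a landscape row
#'
#' Maximal runs of bins whose frequency is at least `threshold_fraction`
#' times the row maximum, merged across single-bin gaps. Used to recover the
#' polarised mitotic domains from a binned frequency profile.
#'
#' @param row Numeric vector of non-negative per-bin frequencies.
#' @param threshold_fraction Fraction of the row maximum (default 0.25).
#' @param bin_width Optional bin width (um) to add interval coordinates.
#' @return Tibble with one row per domain: `start_bin`, `end_bin` (0-based,
#'   inclusive) and, when `bin_width` is given, `start_um`, `end_um`. An
#'   all-zero row yields zero domains.
#' @examples
#' detect_domains(c(5, 4, 0, 0, 0, 6, 7), 0.5)
#' @export
detect_domains <- function(row, threshold_fraction = 0.25, bin_width = NULL) {
  if (any(row < 0)) abort("`row` must be non-negative.")
  empty <- tibble(start_bin = integer(), end_bin = integer())
  if (length(row) == 0 || max(row) == 0) return(empty)
  hot <- row >= threshold_fraction * max(row)
  # merge across single-bin gaps
  gap <- which(!hot)
  fill <- gap[gap > 1 & gap < length(hot)]
  fill <- fill[hot[fill - 1] & hot[fill + 1]]
  hot[fill] <- TRUE
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- tibble(start_bin = starts[r$values] - 1L, end_bin = ends[r$values] - 1L)
  if (!is.null(bin_width)) {
    out <- mutate(out, start_um = .data$start_bin * bin_width,
                  end_um = (.data$end_bin + 1) * bin_width)
  }
  out
}
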