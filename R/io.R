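NUCLEUS_COLS <- c("embryo_id", "x_um", "y_um", "z_um", "tissue", "edu", "phh3")
LANDMARK_COLS <- c("embryo_id", "tip_x", "tip_y", "tip_z",
                   "hinge_x", "hinge_y", "hinge_z")

parse_strict_logical <- function(x, col) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "1")] <- TRUE
  out[v %in% c("false", "0")] <- FALSE
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("Column `%s`: unparseable boolean at row(s) %s (expected true/false/0/1).",
                  col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  out
}

check_numeric_col <- function(x, col) {
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "")
  if (length(bad) > 0) {
    abort(sprintf("Column `%s`: non-numeric value at row(s) %s.",
                  col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  v
}

#' Read a nucleus table (and landmarks) from CSV
#'
#' Reads the interchange format written by the simulator and the CLI:
#' UTF-8 CSV with a header row and '.' decimals, one row per nucleus.
#' Landmarks (anterior tip and chordoneural hinge per embryo) may live in a
#' sidecar CSV or as constant `tip_*`/`hinge_*` columns of the nucleus table.
#' Booleans are parsed strictly (`true`/`false`/`0`/`1`).
#'
#' @param path Nucleus CSV path.
#' @param landmarks_path Optional landmark sidecar CSV.
#' @return List with `nuclei` and `landmarks` tibbles (landmarks `NULL` when
#'   unavailable).
#' @export
read_nuclei <- function(path, landmarks_path = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(NUCLEUS_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  nuclei <- as_tibble(raw)
  for (col in c("x_um", "y_um", "z_um", "ap_um", "stage_ss")) {
    if (col %in% names(nuclei)) nuclei[[col]] <- check_numeric_col(nuclei[[col]], col)
  }
  for (col in c("edu", "phh3", "floor_plate")) {
    if (col %in% names(nuclei)) nuclei[[col]] <- parse_strict_logical(nuclei[[col]], col)
  }
  if ("somite_index" %in% names(nuclei)) {
    nuclei$somite_index <- as.integer(check_numeric_col(nuclei$somite_index,
                                                        "somite_index"))
  }
  if ("id" %in% names(nuclei)) {
    nuclei$id <- as.integer(check_numeric_col(nuclei$id, "id"))
  }
  landmarks <- NULL
  if (!is.null(landmarks_path)) {
    lm <- readr::read_csv(landmarks_path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(LANDMARK_COLS, names(lm))
    if (length(missing) > 0) {
      abort(paste0("Landmark file missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    landmarks <- as_tibble(lm)
  } else if (all(LANDMARK_COLS %in% names(nuclei))) {
    keep <- intersect(c(LANDMARK_COLS, "stage_ss"), names(nuclei))
    landmarks <- distinct(nuclei[, keep])
    for (col in setdiff(keep, "embryo_id")) {
      landmarks[[col]] <- check_numeric_col(landmarks[[col]], col)
    }
    nuclei <- nuclei[, setdiff(names(nuclei), setdiff(LANDMARK_COLS, "embryo_id"))]
  }
  list(nuclei = nuclei, landmarks = landmarks)
}

#' Write a simulated cohort to disk
#'
#' One nucleus CSV per embryo, a landmarks CSV, and a JSON manifest listing
#' the files, embryo stages and nucleus counts.
#'
#' @param cohort List with `nuclei` and `landmarks` (from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (em in unique(cohort$landmarks$embryo_id)) {
    f <- file.path(dir, paste0(em, ".csv"))
    readr::write_csv(filter(cohort$nuclei, .data$embryo_id == em), f)
    files <- c(files, basename(f))
  }
  readr::write_csv(cohort$landmarks, file.path(dir, "landmarks.csv"))
  manifest <- list(
    n_embryos = length(files),
    embryos = lapply(unique(cohort$landmarks$embryo_id), function(em) {
      list(embryo_id = em,
           file = paste0(em, ".csv"),
           stage_ss = cohort$landmarks$stage_ss[cohort$landmarks$embryo_id == em],
           n_nuclei = sum(cohort$nuclei$embryo_id == em))
    }),
    landmarks = "landmarks.csv"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing per-embryo CSVs, `landmarks.csv` and
#'   `manifest.json`.
#' @return List with `nuclei` and `landmarks`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  nuclei <- list_rbind(map(manifest$embryos, function(e) {
    read_nuclei(file.path(dir, e$file))$nuclei
  }))
  landmarks <- readr::read_csv(file.path(dir, manifest$landmarks),
                               show_col_types = FALSE, progress = FALSE)
  list(nuclei = nuclei, landmarks = as_tibble(landmarks))
}

#' Run configuration files
#'
#' YAML (or JSON) run configuration with strict schema validation: unknown
#' keys are rejected so typos cannot silently fall back to defaults. The
#' schema has four blocks: `seed`, `cohort` (`n_embryos`, `embryo_prefix`),
#' `protocol` (`edu_windows`, `hu_windows`, `fixation_hpf`) and `sim`
#' (overrides of [sim_config()] fields).
#'
#' @param path YAML/JSON file path.
#' @param config A run-config list (from [read_run_config()] or built in R).
#' @return `read_run_config()`: validated list with `seed`, `cohort`,
#'   `protocol` (a [protocol()]), and `sim` (a [sim_config()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  allowed <- c("seed", "cohort", "protocol", "sim")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cohort <- config$cohort %||% list()
  unknown <- setdiff(names(cohort), c("n_embryos", "embryo_prefix"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown cohort key(s): ", paste(unknown, collapse = ", ")))
  }
  pr <- config$protocol %||% list()
  unknown <- setdiff(names(pr), c("edu_windows", "hu_windows", "fixation_hpf"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown protocol key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(pr$fixation_hpf)) abort("Config must set protocol.fixation_hpf.")
  as_windows <- function(w) lapply(w, function(x) as.numeric(unlist(x)))
  list(
    seed = as.integer(config$seed %||% 1L),
    cohort = list(n_embryos = as.integer(cohort$n_embryos %||% 1L),
                  embryo_prefix = cohort$embryo_prefix %||% "embryo"),
    protocol = protocol(as_windows(pr$edu_windows %||% list()),
                        as_windows(pr$hu_windows %||% list()),
                        as.numeric(pr$fixation_hpf)),
    sim = do.call(sim_config, config$sim %||% list())
  )
}
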