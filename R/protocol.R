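#' Experimental protocol: labelling, arrest and fixation times
#'
#' A protocol records the timed events applied to a live embryo: EdU
#' incubation windows (thymidine-analogue labelling of S-phase nuclei, with
#' washout at the window end), hydroxyurea (HU) windows during which entry
#' into S phase is blocked and replication forks stall, and the fixation
#' time at which the embryo is exported as a nucleus table.
#'
#' @param edu_windows List of length-2 numeric vectors `c(start_hpf, end_hpf)`.
#' @param hu_windows List of length-2 numeric vectors `c(start_hpf, end_hpf)`.
#' @param fixation_hpf Time of fixation (hpf). Must not precede the end of
#'   any window unless fixation falls inside that window.
#' @return An object of class `"protocol"`.
#' @examples
#' # 2 h EdU pulse immediately before fixation at the 7-somite stage
#' protocol(edu_windows = list(c(18, 20)), fixation_hpf = 20)
#' @export
protocol <- function(edu_windows = list(), hu_windows = list(), fixation_hpf) {
  check_windows <- function(w, what) {
    for (x in w) {
      if (length(x) != 2 || !is.numeric(x) || x[1] >= x[2]) {
        abort(sprintf("Each %s window must be numeric c(start, end) with start < end.", what))
      }
      if (fixation_hpf < x[2] && fixation_hpf < x[1]) {
        abort(sprintf("Fixation at %g hpf precedes the %s window [%g, %g].",
                      fixation_hpf, what, x[1], x[2]))
      }
    }
  }
  if (!is.numeric(fixation_hpf) || length(fixation_hpf) != 1 || fixation_hpf < 0) {
    abort("`fixation_hpf` must be a single non-negative number.")
  }
  check_windows(edu_windows, "EdU")
  check_windows(hu_windows, "HU")
  structure(
    list(edu_windows = edu_windows, hu_windows = hu_windows,
         fixation_hpf = fixation_hpf),
    class = "protocol"
  )
}

#' @export
print.protocol <- function(x, ...) {
  fmt <- function(w) if (length(w) == 0) "none" else
    paste(vapply(w, function(v) sprintf("[%g, %g]", v[1], v[2]), ""), collapse = ", ")
  cat("<protocol>\n",
      "  EdU windows (hpf): ", fmt(x$edu_windows), "\n",
      "  HU windows (hpf):  ", fmt(x$hu_windows), "\n",
      "  fixation (hpf):    ", x$fixation_hpf, "\n", sep = "")
  invisible(x)
}

# TRUE if any window overlaps the half-open interval [t0, t1)
window_active <- function(windows, t0, t1 = t0) {
  any(vapply(windows, function(w) w[1] < max(t1, t0 + 1e-9) && w[2] > t0, TRUE))
}
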