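# Measurement-series acceptance gate: four criteria, series passes when at
# least three hold.

#' Criterion: species differentiation in at least five charge states
#'
#' At the lowest voltage step the free antibody and the one- and two-peptide
#' complexes must be distinguishable in at least `min_states` charge states:
#' within a charge state, the valley between adjacent species signals must
#' drop to at most `max_valley` (default 50%, boundary inclusive) of the
#' smaller adjacent apex, for both the antibody/complex1 and the
#' complex1/complex2 pairs.
#'
#' @param spectrum Smoothed spectrum at the lowest voltage step.
#' @param antibody_mass,peptide_mass Neutral masses, Da.
#' @param charges Charge states probed (default 23:27).
#' @param tolerance Apex-reading half-window, Th.
#' @param max_valley Maximal valley-to-smaller-apex ratio (default 0.5).
#' @param min_states Required number of resolved charge states (default 5).
#' @param background Background intensity estimate.
#' @param noise Noise-floor estimate forwarded to [read_height()].
#' @return Logical; attribute `resolved_states` carries the count.
#' @export
criterion_resolution <- function(spectrum, antibody_mass, peptide_mass,
                                 charges = 23:27, tolerance = 5,
                                 max_valley = 0.5, min_states = 5,
                                 background = 0, noise = 0) {
  masses <- c(antibody_mass, antibody_mass + peptide_mass,
              antibody_mass + 2 * peptide_mass)
  resolved <- 0L
  for (zz in charges) {
    pos <- mz(masses, zz)
    apex <- vapply(masses, function(m) {
      h <- read_height(spectrum, m, zz, tolerance, background, noise)
      if (is.na(h)) background else as.numeric(h)
    }, 0)
    ok <- TRUE
    for (k in 1:2) {
      lo <- min(pos[k], pos[k + 1]); hi <- max(pos[k], pos[k + 1])
      sel <- spectrum$mz > lo & spectrum$mz < hi
      smaller <- min(apex[k], apex[k + 1])
      if (!any(sel) || smaller <= background) { ok <- FALSE; break }
      valley <- min(spectrum$intensity[sel])
      if (valley > max_valley * smaller) { ok <- FALSE; break }
    }
    if (ok) resolved <- resolved + 1L
  }
  structure(resolved >= min_states, resolved_states = resolved)
}

#' Criterion: no disturbing sodium adduct
#'
#' At the highest voltage step (after smoothing), the doubly charged sodium
#' adduct of the released peptide must not exceed `max_ratio` (default 35%)
#' of the doubly protonated peptide signal. When no peptide signal rises
#' above the background (non-binder series), the criterion is undecidable
#' and recorded as a pass with a warning.
#'
#' @param spectrum Smoothed spectrum at the highest voltage step.
#' @param peptide_mass Peptide mass, Da.
#' @param tolerance Apex-reading half-window, Th.
#' @param max_ratio Threshold ratio (default 0.35; boundary inclusive).
#' @param background Background intensity estimate.
#' @param noise Noise-floor estimate forwarded to [read_height()].
#' @return Logical; attribute `ratio` carries the measured ratio and
#'   `undecidable` flags a background-level peptide signal.
#' @export
criterion_sodium <- function(spectrum, peptide_mass, tolerance = 0.5,
                             max_ratio = 0.35, background = 0, noise = 0) {
  hp <- read_height(spectrum, peptide_mass, 2L, tolerance, background, noise)
  hna <- read_height(spectrum, peptide_mass + mass_table()$sodium_adduct, 2L,
                     tolerance, background, noise)
  hp <- if (is.na(hp)) background else as.numeric(hp)
  hna <- if (is.na(hna)) background else as.numeric(hna)
  if (hp <= background || hp == 0) {
    warning("no released-peptide signal above background; ",
            "sodium-adduct criterion undecidable, recorded as pass",
            call. = FALSE)
    return(structure(TRUE, ratio = NA_real_, undecidable = TRUE))
  }
  ratio <- hna / hp
  structure(ratio <= max_ratio, ratio = ratio, undecidable = FALSE)
}

#' Criterion: Boltzmann fit used every course point
#'
#' @param fit A `boltzmann_fit` (or `boltzmann_nofit`).
#' @return TRUE iff no points were masked for fitting.
#' @export
criterion_outliers <- function(fit) {
  length(fit$excluded %||% integer(0)) == 0L
}

#' Criterion: Boltzmann fit accuracy
#'
#' @param fit A `boltzmann_fit`.
#' @param min_r2 Required regression coefficient (default 0.99, inclusive).
#' @return TRUE iff `R^2 >= min_r2`; FALSE for transition-free courses.
#' @export
criterion_r2 <- function(fit, min_r2 = 0.99) {
  if (!inherits(fit, "boltzmann_fit")) return(FALSE)
  isTRUE(fit$r2 >= min_r2)
}

#' Assemble the quality-control report
#'
#' A measurement series passes when at least three of the four criteria
#' hold.
#'
#' @param resolution,sodium,outliers,r2 Logical criterion outcomes (the
#'   attribute-carrying results of the `criterion_*` functions may be
#'   passed directly).
#' @return Object of class `qc_report` with per-criterion outcomes,
#'   `passed`, and diagnostic details.
#' @export
qc_report <- function(resolution, sodium, outliers, r2) {
  crit <- c(resolution = isTRUE(as.logical(resolution)),
            sodium = isTRUE(as.logical(sodium)),
            outliers = isTRUE(as.logical(outliers)),
            r2 = isTRUE(as.logical(r2)))
  structure(
    list(criteria = crit, passed = sum(crit) >= 3L,
         details = list(
           resolved_states = attr(resolution, "resolved_states"),
           sodium_ratio = attr(sodium, "ratio"),
           sodium_undecidable = isTRUE(attr(sodium, "undecidable")))),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", if (x$passed) "PASSED" else "FAILED",
      sprintf("(%d/4 criteria)\n", sum(x$criteria)))
  for (nm in names(x$criteria)) {
    cat(sprintf("  %-11s %s\n", nm, if (x$criteria[[nm]]) "pass" else "fail"))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A [qc_report()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_qc_json <- function(report, path) {
  jsonlite::write_json(
    list(criteria = as.list(report$criteria), passed = report$passed,
         details = report$details),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
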