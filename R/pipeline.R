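# Pipeline orchestration: configuration, stage commands and file-format
# glue. The thin command-line wrapper at inst/scripts/immunocid.R calls
# these functions.

#' Pipeline run configuration
#'
#' Bundles paths, processing options, thermodynamic constants and the seed.
#' The seed and a configuration digest are embedded in every output so that
#' deterministic stages re-run byte-stably.
#'
#' @param output_dir Output directory.
#' @param antibody_mass,peptide_mass Masses, Da.
#' @param recipe A [simulation_recipe()] (simulation stage).
#' @param process_opts Options from [process_options()].
#' @param thermo_cfg A [thermo_config()].
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir = ".", antibody_mass = 146756.2,
                       peptide_mass = 1813.907,
                       recipe = simulation_recipe(),
                       process_opts = process_options(),
                       thermo_cfg = thermo_config(), seed = 1L) {
  cfg <- list(output_dir = output_dir, antibody_mass = antibody_mass,
              peptide_mass = peptide_mass, recipe = recipe,
              process_opts = process_opts, thermo_cfg = thermo_cfg,
              seed = as.integer(seed))
  cfg$digest <- .config_digest(cfg)
  structure(cfg, class = "run_config")
}

.config_digest <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), "digest")])), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

.stamp <- function(cfg) {
  c(sprintf("# config_digest: %s", cfg$digest),
    sprintf("# seed: %d", cfg$seed))
}

.write_stamped_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stamp(cfg), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written with a configuration stamp
#'
#' @param path CSV path.
#' @return data.frame (stamp comment lines skipped).
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Stage: simulate a synthetic breakdown series
#'
#' Writes the series in the CSV-manifest dialect plus a ground-truth JSON.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(cfg) {
  recipe <- cfg$recipe
  recipe$seed <- cfg$seed
  series <- simulate_series(recipe)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- write_series_csv(series, file.path(cfg$output_dir, "series"))
  gt <- attr(series, "ground_truth")
  jsonlite::write_json(
    list(seed = cfg$seed, config_digest = cfg$digest,
         educt_percent = gt$educt_percent,
         cv_steps = recipe$cv_steps,
         educt_params = as.list(gt$recipe$educt_params)),
    file.path(cfg$output_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  message(sprintf("simulated %d voltage steps -> %s",
                  length(series$steps), mpath))
  invisible(mpath)
}

#' Stage: process a breakdown series
#'
#' Reads a CSV-manifest series, computes envelopes, the educt course and
#' the quality-control report; writes `course.csv`, `envelopes.csv` and
#' `qc.json`.
#'
#' @param cfg A [run_config()].
#' @param manifest Manifest path (default: the simulation stage's output).
#' @return Invisibly, a list with `course`, `qc` and the Boltzmann `fit`.
#' @export
run_process <- function(cfg, manifest = file.path(cfg$output_dir, "series",
                                                  "manifest.csv")) {
  if (!file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  series <- read_series_csv(manifest)
  proc <- process_series(series, cfg$antibody_mass, cfg$peptide_mass,
                         cfg$process_opts)
  fit <- tryCatch(fit_boltzmann(proc$course), error = function(e) NULL)

  first <- series$steps[[1]]
  last <- series$steps[[length(series$steps)]]
  sm <- function(st) {
    sp <- list(mz = st$mz, intensity = st$intensity)
    smooth_spectrum(sp, cfg$process_opts$smooth_window,
                    cfg$process_opts$smooth_passes,
                    cfg$process_opts$smooth_polyorder)
  }
  sp1 <- sm(first); spN <- sm(last)
  bg1 <- estimate_background(sp1, cfg$process_opts$background_windows)
  bgN <- estimate_background(spN, cfg$process_opts$background_windows)
  cr <- criterion_resolution(sp1, cfg$antibody_mass, cfg$peptide_mass,
                             charges = cfg$process_opts$complex_charges,
                             tolerance = cfg$process_opts$tol_complex,
                             background = as.numeric(bg1),
                             noise = attr(bg1, "noise") %||% 0)
  cs <- withCallingHandlers(
    criterion_sodium(spN, cfg$peptide_mass,
                     tolerance = cfg$process_opts$tol_peptide,
                     background = as.numeric(bgN),
                     noise = attr(bgN, "noise") %||% 0),
    warning = function(w) invokeRestart("muffleWarning"))
  co <- if (is.null(fit)) FALSE else criterion_outliers(fit)
  c4 <- if (is.null(fit)) FALSE else criterion_r2(fit)
  qc <- qc_report(cr, cs, co, c4)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  .write_stamped_csv(as.data.frame(proc$course),
                     file.path(cfg$output_dir, "course.csv"), cfg)
  env_df <- do.call(rbind, lapply(seq_along(proc$envelopes), function(i) {
    do.call(rbind, lapply(names(proc$envelopes[[i]]), function(s) {
      g <- proc$envelopes[[i]][[s]]$gaussian
      data.frame(step = i, species = s, apex = g[["apex"]],
                 center = g[["center"]], width = g[["width"]])
    }))
  }))
  .write_stamped_csv(env_df, file.path(cfg$output_dir, "envelopes.csv"), cfg)
  write_qc_json(qc, file.path(cfg$output_dir, "qc.json"))
  message(sprintf("processed %d steps; QC %s", length(series$steps),
                  if (qc$passed) "passed" else "FAILED"))
  invisible(list(course = proc$course, qc = qc, fit = fit,
                 envelopes = proc$envelopes))
}

#' Stage: fit courses and rank binders
#'
#' Boltzmann-fits a set of educt courses, runs the thermodynamic chain and
#' writes course-characteristics and ranking tables.
#'
#' @param cfg A [run_config()].
#' @param courses Named list of [educt_course()] objects.
#' @return Invisibly, a list with `fits`, `thermo`, `course_table`,
#'   `ranking`.
#' @export
run_fit_rank <- function(cfg, courses) {
  fits <- lapply(courses, function(cc) {
    tryCatch(fit_boltzmann(cc), error = function(e) {
      structure(list(reason = conditionMessage(e),
                     initial = cc$fraction[which.min(cc$dcv)],
                     final = cc$fraction[which.max(cc$dcv)],
                     range = diff(range(cc$fraction)), excluded = integer(0)),
                class = "boltzmann_nofit")
    })
  })
  complex_mass <- cfg$antibody_mass + cfg$peptide_mass
  thermo <- lapply(fits, m0g_chain, complex_mass = complex_mass,
                   cfg = cfg$thermo_cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- course_table(fits)
  rk <- rank_binders(thermo)
  .write_stamped_csv(ct, file.path(cfg$output_dir, "courses_fit.csv"), cfg)
  .write_stamped_csv(rk, file.path(cfg$output_dir, "ranking.csv"), cfg)
  message(sprintf("fitted %d courses; groups: %s", length(fits),
                  paste(rk$group, collapse = ", ")))
  invisible(list(fits = fits, thermo = thermo, course_table = ct,
                 ranking = rk))
}

#' Stage: fit ITC titrations
#'
#' @param cfg A [run_config()].
#' @param titrations Named list of [titration()] objects.
#' @return Invisibly, a list with `fits` and the summary table.
#' @export
run_itc <- function(cfg, titrations) {
  fits <- lapply(titrations, fit_independent)
  tab <- itc_table(fits)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  .write_stamped_csv(tab, file.path(cfg$output_dir, "itc_fits.csv"), cfg)
  invisible(list(fits = fits, table = tab))
}

#' Stage: peptide mass report
#'
#' @param cfg A [run_config()].
#' @param peptides Named list of [peptide_variant()] objects.
#' @param charges Charges for the calculated m/z column.
#' @return Invisibly, the report data.frame.
#' @export
run_masses <- function(cfg, peptides = troponin_epitope_panel(),
                       charges = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L)) {
  rep <- mass_report(peptides, charges)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  .write_stamped_csv(rep, file.path(cfg$output_dir, "masses.csv"), cfg)
  invisible(rep)
}
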