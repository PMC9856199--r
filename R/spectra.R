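# Spectrum processing: scan averaging, iterated Savitzky-Golay smoothing,
# species apex-height reading, Gaussian charge-envelope fitting with
# imputation, normalized educt fractions and zero-charge mass deconvolution.

#' Construct a per-voltage spectrum series
#'
#' An ordered set of averaged mass spectra, one per collision cell voltage
#' difference step.
#'
#' @param dcv Strictly increasing voltage differences, V.
#' @param spectra List of spectra, each a list/data.frame with strictly
#'   increasing `mz` (Th) and non-negative `intensity`.
#' @param sample Sample label.
#' @param replicate Replicate identifier.
#' @return Object of class `spectrum_series` with elements `steps` (list of
#'   `list(dcv, mz, intensity)`) and `metadata`.
#' @export
spectrum_series <- function(dcv, spectra, sample = "", replicate = 1L) {
  stopifnot(length(dcv) == length(spectra))
  if (is.unsorted(dcv, strictly = TRUE)) {
    stop("voltage steps must be strictly increasing", call. = FALSE)
  }
  steps <- vector("list", length(dcv))
  for (i in seq_along(dcv)) {
    sp <- spectra[[i]]
    m <- as.numeric(sp$mz); y <- as.numeric(sp$intensity)
    if (length(m) && is.unsorted(m, strictly = TRUE)) {
      stop("m/z values must be strictly increasing within each spectrum",
           call. = FALSE)
    }
    if (any(y < 0)) stop("intensities must be non-negative", call. = FALSE)
    steps[[i]] <- list(dcv = dcv[i], mz = m, intensity = y)
  }
  structure(list(steps = steps,
                 metadata = list(sample = sample, replicate = replicate)),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("spectrum_series: %d voltage steps (%s V), sample '%s'\n",
              length(x$steps),
              paste(vapply(x$steps, `[[`, 0, "dcv"), collapse = ", "),
              x$metadata$sample))
  invisible(x)
}

#' Combine scans into an average spectrum
#'
#' Pointwise mean intensity over the scans recorded during one voltage step.
#' Scans on mismatched m/z grids are first resampled by linear interpolation
#' onto `grid` (default: the first scan's axis).
#'
#' @param scans Non-empty list of spectra (`mz`, `intensity`).
#' @param grid Optional common m/z axis.
#' @return A list with `mz` and `intensity`.
#' @export
combine_scans <- function(scans, grid = NULL) {
  if (length(scans) == 0L) stop("no scans to combine", call. = FALSE)
  if (is.null(grid)) grid <- as.numeric(scans[[1]]$mz)
  same <- all(vapply(scans, function(s) {
    length(s$mz) == length(grid) && isTRUE(all.equal(as.numeric(s$mz), grid))
  }, TRUE))
  ys <- if (same) {
    vapply(scans, function(s) as.numeric(s$intensity), numeric(length(grid)))
  } else {
    vapply(scans, function(s) {
      stats::approx(as.numeric(s$mz), as.numeric(s$intensity), xout = grid,
                    rule = 2)$y
    }, numeric(length(grid)))
  }
  ys <- matrix(ys, nrow = length(grid))
  list(mz = grid, intensity = rowMeans(ys))
}

#' Iterated Savitzky-Golay smoothing
#'
#' Applies a Savitzky-Golay filter `passes` times. A nominal window of 10
#' data points is widened to the next odd length (11), since symmetric
#' Savitzky-Golay kernels require an odd window.
#'
#' @param spectrum A spectrum (`mz`, `intensity`) or a bare intensity vector.
#' @param window Window length in points (default 10, treated as 11).
#' @param passes Number of smoothing cycles (default 20); 0 is the identity.
#' @param polyorder Polynomial order (default 2; must be `< window`).
#' @return Same structure as the input with smoothed intensities.
#' @export
smooth_spectrum <- function(spectrum, window = 10L, passes = 20L,
                            polyorder = 2L) {
  vec <- is.numeric(spectrum)
  y <- if (vec) as.numeric(spectrum) else as.numeric(spectrum$intensity)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (polyorder >= window) stop("polyorder must be below window", call. = FALSE)
  if (passes > 0L && length(y) < window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  for (i in seq_len(passes)) {
    y <- signal::sgolayfilt(y, p = polyorder, n = window)
  }
  if (vec) return(y)
  out <- spectrum
  out$intensity <- y
  out
}

#' Background level from signal-free windows
#'
#' Median intensity inside the configured signal-free m/z windows
#' (default 4400-4700 Th, below the lightest antibody species).
#'
#' @param spectrum A spectrum (`mz`, `intensity`).
#' @param windows Two-column matrix (or length-2 vector) of m/z limits.
#' @return Background intensity (0 if the windows contain no points).
#' @export
estimate_background <- function(spectrum, windows = c(4400, 4700)) {
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2, byrow = TRUE)
  sel <- rep(FALSE, length(spectrum$mz))
  for (i in seq_len(nrow(windows))) {
    sel <- sel | (spectrum$mz >= windows[i, 1] & spectrum$mz <= windows[i, 2])
  }
  if (!any(sel)) return(0)
  structure(stats::median(spectrum$intensity[sel]),
            noise = stats::mad(spectrum$intensity[sel]))
}

#' Read a species apex height
#'
#' Maximum (smoothed) intensity within `mz(species_mass, z)` +/- `tolerance`.
#' If the window holds no recorded points the height is flagged missing
#' (candidate for envelope imputation); if no point exceeds the background,
#' the background estimate is returned.
#'
#' @param spectrum A spectrum (`mz`, `intensity`), normally after smoothing.
#' @param species_mass Neutral species mass, Da.
#' @param z Charge.
#' @param tolerance m/z half-window, Th (> 0).
#' @param background Background intensity estimate.
#' @param noise Noise-floor estimate used to gate the collision check
#'   (default 0: any bimodal window warns).
#' @return Height; `NA` with attribute `missing = TRUE` when the window is
#'   outside the recorded range.
#' @export
read_height <- function(spectrum, species_mass, z, tolerance,
                        background = 0, noise = 0) {
  stopifnot(tolerance > 0)
  target <- mz(species_mass, z)
  sel <- which(spectrum$mz >= target - tolerance & spectrum$mz <= target + tolerance)
  if (length(sel) == 0L) {
    return(structure(NA_real_, missing = TRUE))
  }
  y <- spectrum$intensity[sel]
  if (length(y) >= 3L && max(y) > background + 8 * noise) {
    # two distinct apices inside one reading window mean colliding species;
    # maxima only count as distinct when a valley below 75% of the smaller
    # apex separates them (noise wiggles near one apex are merged)
    inner <- 2:(length(y) - 1L)
    peaks <- inner[y[inner] > y[inner - 1L] & y[inner] >= y[inner + 1L] &
                     y[inner] > background + 0.25 * (max(y) - background)]
    if (length(peaks) >= 2L) {
      distinct <- peaks[1]
      for (pk in peaks[-1]) {
        valley <- min(y[distinct[length(distinct)]:pk])
        if (valley < 0.75 * min(y[pk], y[distinct[length(distinct)]])) {
          distinct <- c(distinct, pk)
        } else if (y[pk] > y[distinct[length(distinct)]]) {
          distinct[length(distinct)] <- pk
        }
      }
      if (length(distinct) >= 2L) {
        warning(sprintf(
          "signal collision: %d apices within %.3g Th of m/z %.2f; tallest used",
          length(distinct), tolerance, target), call. = FALSE)
      }
    }
  }
  max(max(y), background)
}

#' Fit a Gaussian envelope over charge states
#'
#' Least-squares Gaussian `h * exp(-(z - c)^2 / (2 w^2))` over the per-charge
#' apex heights of one molecular species. The fit requires at least five
#' values; if fewer charge states were measured, flanking charge states are
#' appended at the background intensity, alternating below and above the
#' measured range (starting below), and flagged as imputed.
#'
#' @param points Named numeric vector, names = charge state, values = apex
#'   heights.
#' @param background Background intensity used for imputed values.
#' @return Object of class `species_envelope` with `points`, `gaussian`
#'   (`apex`, `center`, `width`), `imputed` (imputed charge states) and
#'   `nondetect` flag. For all-background input the apex equals the
#'   background and the center is undefined (non-detect).
#' @examples
#' fit_envelope(c("23" = 10, "24" = 40, "25" = 100, "26" = 40, "27" = 10))
#' @export
fit_envelope <- function(points, background = 0) {
  stopifnot(length(points) >= 1L, !is.null(names(points)))
  z <- as.numeric(names(points))
  y <- as.numeric(points)
  ok <- is.finite(y)
  z <- z[ok]; y <- y[ok]
  if (length(z) < 1L) stop("no measured points", call. = FALSE)
  imputed <- numeric(0)
  side_low <- TRUE
  while (length(z) < 5L) {
    znew <- if (side_low) min(z, imputed) - 1 else max(z, imputed) + 1
    imputed <- c(imputed, znew)
    z <- c(z, znew); y <- c(y, background)
    side_low <- !side_low
  }
  ord <- order(z); z <- z[ord]; y <- y[ord]

  if (max(y) <= background + 1e-12 * max(background, 1)) {
    return(structure(
      list(points = stats::setNames(y, z),
           gaussian = c(apex = background, center = NA_real_, width = NA_real_),
           imputed = sort(imputed), nondetect = TRUE),
      class = "species_envelope"))
  }

  h0 <- max(y)
  wpos <- pmax(y - background, 0)
  c0 <- if (sum(wpos) > 0) sum(z * wpos) / sum(wpos) else z[which.max(y)]
  w0 <- max(stats::sd(rep(z, times = pmax(round(wpos / max(wpos) * 100), 0))),
            0.8)
  if (!is.finite(w0)) w0 <- 1.5
  dat <- data.frame(z = z, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ h * exp(-(z - cc)^2 / (2 * w^2)), data = dat,
                      start = list(h = h0, cc = c0, w = w0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # coarse grid fallback for degenerate point sets
    grid <- expand.grid(h = h0 * seq(0.5, 1.5, by = 0.05),
                        cc = seq(min(z), max(z), by = 0.05),
                        w = seq(0.3, diff(range(z)), by = 0.1))
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum((y - grid$h[i] * exp(-(z - grid$cc[i])^2 / (2 * grid$w[i]^2)))^2)
    }, 0)
    best <- grid[which.min(sse), ]
    pars <- c(apex = best$h, center = best$cc, width = best$w)
  } else {
    cf <- stats::coef(fit)
    pars <- c(apex = unname(cf[["h"]]), center = unname(cf[["cc"]]),
              width = abs(unname(cf[["w"]])))
  }
  structure(
    list(points = stats::setNames(y, z), gaussian = pars,
         imputed = sort(imputed), nondetect = FALSE),
    class = "species_envelope")
}

#' @export
print.species_envelope <- function(x, ...) {
  if (x$nondetect) {
    cat("species_envelope: non-detect (all points at background)\n")
  } else {
    cat(sprintf("species_envelope: apex %.3g at mean charge %.2f (width %.2f), %d imputed\n",
                x$gaussian[["apex"]], x$gaussian[["center"]],
                x$gaussian[["width"]], length(x$imputed)))
  }
  invisible(x)
}

#' Normalized educt fraction
#'
#' Percentage of the summed species apex heights held by the intact immune
#' complexes: `100 * (complex1 + complex2) / sum(heights)`. By default the
#' denominator covers the free antibody, both complexes and the released
#' peptide; antibody fragment ions are excluded unless requested (they
#' appear only at high collision voltages where counting them would
#' double-count dissociation products).
#'
#' @param heights Named numeric vector with at least `antibody`, `complex1`
#'   and `complex2`; `peptide` and `fragment` are optional.
#' @param include Species included in the denominator.
#' @return Educt fraction in percent.
#' @examples
#' normalized_educt(c(antibody = 10, complex1 = 30, complex2 = 10, peptide = 0))
#' @export
normalized_educt <- function(heights,
                             include = c("antibody", "complex1", "complex2",
                                         "peptide")) {
  need <- c("antibody", "complex1", "complex2")
  if (!all(need %in% names(heights))) {
    stop("heights must include antibody, complex1 and complex2", call. = FALSE)
  }
  denom <- sum(heights[intersect(include, names(heights))], na.rm = TRUE)
  if (denom <= 0) stop("zero total species intensity", call. = FALSE)
  100 * (heights[["complex1"]] + heights[["complex2"]]) / denom
}

#' Zero-charge mass from a multiply charged ion series
#'
#' Infers charge states from adjacent-peak spacing when unknown
#' (`z = round((m2 - proton) / (m1 - m2))` for adjacent peaks `m1 > m2`)
#' and averages `z * (m/z) - z * proton` over the peaks.
#'
#' @param mz_values m/z values of consecutive charge-state peaks.
#' @param z Optional known charges (same length as `mz_values`).
#' @param tol_ppm Maximal allowed spread of per-peak masses; a larger spread
#'   indicates interleaved series from different masses and is rejected.
#' @return List with `mass` (Da) and `sd` (Da; NA for one peak).
#' @examples
#' deconvolute_mass(c(mz(1e5, 20), mz(1e5, 21)))
#' @export
deconvolute_mass <- function(mz_values, z = NULL, tol_ppm = 50) {
  p <- .proton
  m <- sort(as.numeric(mz_values), decreasing = TRUE)
  if (is.null(z)) {
    if (length(m) < 2L) {
      stop("need at least 2 consecutive peaks to infer charge", call. = FALSE)
    }
    zs <- numeric(length(m))
    for (i in seq_len(length(m) - 1L)) {
      zi <- round((m[i + 1L] - p) / (m[i] - m[i + 1L]))
      if (i == 1L) {
        zs[1L] <- zi
      } else if (zi != zs[i]) {
        stop(sprintf(
          "inconsistent charge assignment: pair %d implies %.0f+, expected %.0f+",
          i, zi, zs[i]), call. = FALSE)
      }
      zs[i + 1L] <- zs[i] + 1L
    }
    z <- zs
  } else {
    ord <- order(as.numeric(mz_values), decreasing = TRUE)
    z <- as.numeric(z)[ord]
  }
  if (any(z < 1)) stop("inferred non-positive charge", call. = FALSE)
  masses <- z * m - z * p
  if (length(masses) > 1L) {
    spread <- (max(masses) - min(masses)) / mean(masses) * 1e6
    if (spread > tol_ppm) {
      stop(sprintf(
        "peak series inconsistent: per-peak masses spread %.1f ppm (> %.0f)",
        spread, tol_ppm), call. = FALSE)
    }
  }
  list(mass = mean(masses), sd = if (length(masses) > 1L) stats::sd(masses)
                                 else NA_real_)
}

#' Processing options for breakdown series
#'
#' @param smooth_window,smooth_passes,smooth_polyorder Savitzky-Golay
#'   settings (defaults: 10-point window, 20 cycles, order 2).
#' @param complex_charges Charge states probed for the antibody-containing
#'   species (default 23:27).
#' @param peptide_charges Charge states of the released peptide (default 2:3).
#' @param tol_complex,tol_peptide Apex-reading half-windows, Th.
#' @param background_windows Signal-free m/z windows for the background
#'   estimate.
#' @param include_fragments Include antibody fragment ions in the educt
#'   denominator (default FALSE).
#' @return List of processing options.
#' @export
process_options <- function(smooth_window = 10L, smooth_passes = 20L,
                            smooth_polyorder = 2L,
                            complex_charges = 23:27,
                            peptide_charges = 2:3,
                            tol_complex = 5, tol_peptide = 0.5,
                            background_windows = c(4400, 4700),
                            include_fragments = FALSE) {
  list(smooth_window = smooth_window, smooth_passes = smooth_passes,
       smooth_polyorder = smooth_polyorder,
       complex_charges = complex_charges, peptide_charges = peptide_charges,
       tol_complex = tol_complex, tol_peptide = tol_peptide,
       background_windows = background_windows,
       include_fragments = include_fragments)
}

#' Process a breakdown series into an educt course
#'
#' For every voltage step: smooth the averaged spectrum, read apex heights of
#' the free antibody and the one- and two-peptide complexes over the probed
#' charge states, fit per-species Gaussian charge envelopes (with background
#' imputation below five values), read the released-peptide height at its
#' strongest charge state, and compute the normalized educt fraction.
#'
#' @param series A [spectrum_series()].
#' @param antibody_mass Antibody mass, Da.
#' @param peptide_mass Peptide mass, Da.
#' @param opts Options from [process_options()].
#' @return List with `course` (an [educt_course()]), `envelopes` (per step,
#'   per species), `heights` (matrix of species heights per step) and
#'   `mean_charge` (per-step antibody-series Gaussian centers).
#' @export
process_series <- function(series, antibody_mass, peptide_mass,
                           opts = process_options()) {
  stopifnot(inherits(series, "spectrum_series"))
  species_mass <- c(antibody = antibody_mass,
                    complex1 = antibody_mass + peptide_mass,
                    complex2 = antibody_mass + 2 * peptide_mass)
  nstep <- length(series$steps)
  fractions <- numeric(nstep)
  dcv <- numeric(nstep)
  envs <- vector("list", nstep)
  hmat <- matrix(NA_real_, nrow = nstep, ncol = 4,
                 dimnames = list(NULL, c(names(species_mass), "peptide")))
  mean_charge <- matrix(NA_real_, nrow = nstep, ncol = 3,
                        dimnames = list(NULL, names(species_mass)))
  for (i in seq_len(nstep)) {
    st <- series$steps[[i]]
    dcv[i] <- st$dcv
    sp <- list(mz = st$mz, intensity = st$intensity)
    if (opts$smooth_passes > 0L && length(sp$intensity) >= opts$smooth_window) {
      sp <- smooth_spectrum(sp, opts$smooth_window, opts$smooth_passes,
                            opts$smooth_polyorder)
    }
    bg <- estimate_background(sp, opts$background_windows)
    nz <- attr(bg, "noise") %||% 0
    bg <- as.numeric(bg)
    step_envs <- list()
    for (s in names(species_mass)) {
      pts <- vapply(opts$complex_charges, function(zz) {
        h <- read_height(sp, species_mass[[s]], zz, opts$tol_complex, bg, nz)
        if (is.na(h)) NA_real_ else as.numeric(h)
      }, 0)
      names(pts) <- opts$complex_charges
      pts <- pts[!is.na(pts)]
      if (length(pts) == 0L) {
        env <- structure(list(points = numeric(0),
                              gaussian = c(apex = bg, center = NA_real_,
                                           width = NA_real_),
                              imputed = numeric(0), nondetect = TRUE),
                         class = "species_envelope")
      } else {
        env <- fit_envelope(pts, background = bg)
      }
      step_envs[[s]] <- env
      hmat[i, s] <- env$gaussian[["apex"]]
      mean_charge[i, s] <- env$gaussian[["center"]]
    }
    pep_h <- vapply(opts$peptide_charges, function(zz) {
      h <- read_height(sp, peptide_mass, zz, opts$tol_peptide, bg, nz)
      if (is.na(h)) bg else as.numeric(h)
    }, 0)
    hmat[i, "peptide"] <- max(pep_h)
    envs[[i]] <- step_envs
    include <- c("antibody", "complex1", "complex2", "peptide")
    fractions[i] <- normalized_educt(hmat[i, ], include = include)
  }
  list(course = educt_course(dcv, pmin(pmax(fractions, 0), 100)),
       envelopes = envs, heights = hmat, mean_charge = mean_charge)
}

#' Write a spectrum series as CSV with a manifest
#'
#' One CSV per voltage step (`mz`, `intensity`) plus `manifest.csv` with
#' columns `step`, `delta_cv`, `path`.
#'
#' @param series A [spectrum_series()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_series_csv <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(series$steps)
  paths <- sprintf("step_%02d.csv", seq_len(n))
  for (i in seq_len(n)) {
    utils::write.csv(
      data.frame(mz = series$steps[[i]]$mz,
                 intensity = series$steps[[i]]$intensity),
      file.path(dir, paths[i]), row.names = FALSE)
  }
  manifest <- data.frame(step = seq_len(n),
                         delta_cv = vapply(series$steps, `[[`, 0, "dcv"),
                         path = paths)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a spectrum series from a CSV manifest
#'
#' @param manifest Path to a manifest CSV (`step`, `delta_cv`, `path`); the
#'   per-step paths are resolved relative to the manifest's directory.
#' @param sample,replicate Metadata labels.
#' @return A [spectrum_series()].
#' @export
read_series_csv <- function(manifest, sample = "", replicate = 1L) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("step", "delta_cv", "path") %in% names(man)))
  man <- man[order(man$delta_cv), ]
  base <- dirname(manifest)
  spectra <- lapply(man$path, function(p) {
    utils::read.csv(file.path(base, p))
  })
  spectrum_series(man$delta_cv, spectra, sample = sample,
                  replicate = replicate)
}

#' Read a spectrum series from mzML
#'
#' Reads one spectrum per voltage step from an mzML file via the mzR
#' package; `dcv` supplies the voltage schedule in acquisition order.
#'
#' @param path mzML file.
#' @param dcv Voltage steps matching the stored spectra (in order).
#' @param sample,replicate Metadata labels.
#' @return A [spectrum_series()].
#' @export
read_series_mzml <- function(path, dcv, sample = "", replicate = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  n <- mzR::runInfo(fh)$scanCount
  if (n != length(dcv)) {
    stop(sprintf("mzML holds %d spectra but %d voltage steps were given",
                 n, length(dcv)), call. = FALSE)
  }
  spectra <- lapply(seq_len(n), function(i) {
    pk <- mzR::peaks(fh, i)
    list(mz = pk[, 1], intensity = pk[, 2])
  })
  spectrum_series(dcv, spectra, sample = sample, replicate = replicate)
}
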