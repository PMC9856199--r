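# Synthetic fixture generator: gas-phase breakdown spectrum series and ITC
# titrations with known ground truth.

#' Simulation recipe for a synthetic breakdown series
#'
#' Defaults emulate the study conditions: an intact antibody of 146,756.2 Da
#' carrying up to two copies of the 1813.907 Da wild-type epitope peptide,
#' charge states 23+ to 27+ between m/z 5000 and 7000, and an educt decay
#' over the thirteen collision-voltage steps 2-80 V that follows the
#' Boltzmann law with the wild-type course parameters (initial 77.36%, final
#' 36.24%, center 30.0 V, course constant 15.2 V).
#'
#' Species intensities are bookkept as Gaussian charge-envelope apex
#' heights (the currency in which spectra are read): at each step the free
#' antibody, the two complexes and the released peptide share
#' `total_intensity` exactly.
#'
#' @param antibody_mass,peptide_mass Neutral masses, Da.
#' @param charge_states Integer charge range of the antibody species.
#' @param envelope_center,envelope_width Gaussian charge-envelope center and
#'   width (charge units).
#' @param total_intensity Summed species apex height, counts.
#' @param educt_params Named vector `A1`, `A2` (percent), `x0`, `dx` (V).
#' @param occupancy_split Fraction of educt signal in the one-peptide
#'   complex (default 0.7; the rest is the two-peptide complex).
#' @param cv_steps Strictly increasing voltage schedule, V.
#' @param noise_sd Additive Gaussian noise SD, relative to
#'   `total_intensity`.
#' @param na_adduct_fraction Sodium-adduct satellite height on the released
#'   peptide 2+ signal, relative to the protonated 2+ height (0-1).
#' @param peak_width_mz Gaussian peak SD of antibody-species peaks, Th.
#' @param peptide_peak_width Gaussian peak SD of peptide peaks, Th.
#' @param peptide_charges Charges of the released peptide (default 2+, 3+).
#' @param peptide_ratio3 Height of the 3+ peptide signal relative to 2+.
#' @param released_fraction Released-peptide apex height per unit of
#'   dissociated educt signal (0-1).
#' @param fragment_level Broadband antibody-fragment signal (m/z 1200-2300)
#'   relative to dissociated intensity; default 0 (off).
#' @param grid Optional m/z axis; the default covers 550-1050 Th (0.1 Th)
#'   and 4300-7600 Th (0.5 Th), with exact peak centers inserted.
#' @param seed Integer RNG seed (noise reproducibility).
#' @return Object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(antibody_mass = 146756.2,
                              peptide_mass = 1813.907,
                              charge_states = 23:27,
                              envelope_center = 25,
                              envelope_width = 1.2,
                              total_intensity = 1000,
                              educt_params = c(A1 = 77.36, A2 = 36.24,
                                               x0 = 30.0, dx = 15.2),
                              occupancy_split = 0.7,
                              cv_steps = c(2, 4, 6, 8, 12, 16, 20, 30, 40,
                                           50, 60, 70, 80),
                              noise_sd = 0,
                              na_adduct_fraction = 0,
                              peak_width_mz = 2.5,
                              peptide_peak_width = 0.1,
                              peptide_charges = c(2L, 3L),
                              peptide_ratio3 = 0.45,
                              released_fraction = 0.5,
                              fragment_level = 0,
                              grid = NULL,
                              seed = 1L) {
  ep <- educt_params
  stopifnot(all(c("A1", "A2", "x0", "dx") %in% names(ep)))
  if (!(ep[["A2"]] >= 0 && ep[["A1"]] >= ep[["A2"]] && ep[["A1"]] <= 100)) {
    stop("educt_params must satisfy 0 <= A2 <= A1 <= 100", call. = FALSE)
  }
  if (ep[["dx"]] <= 0) stop("dx must be positive", call. = FALSE)
  if (is.unsorted(cv_steps, strictly = TRUE)) {
    stop("cv_steps must be strictly increasing", call. = FALSE)
  }
  if (na_adduct_fraction < 0 || na_adduct_fraction > 1) {
    stop("na_adduct_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(antibody_mass = antibody_mass, peptide_mass = peptide_mass,
         charge_states = as.integer(charge_states),
         envelope_center = envelope_center, envelope_width = envelope_width,
         total_intensity = total_intensity, educt_params = ep,
         occupancy_split = occupancy_split, cv_steps = cv_steps,
         noise_sd = noise_sd, na_adduct_fraction = na_adduct_fraction,
         peak_width_mz = peak_width_mz,
         peptide_peak_width = peptide_peak_width,
         peptide_charges = as.integer(peptide_charges),
         peptide_ratio3 = peptide_ratio3,
         released_fraction = released_fraction,
         fragment_level = fragment_level, grid = grid, seed = as.integer(seed)),
    class = "simulation_recipe")
}

# low- and high-mass ranges are sampled at the same points-per-peak density
# (peak sd / grid step), as a time-of-flight analyser approximately does;
# iterated smoothing then attenuates all species' apexes alike and height
# ratios survive processing.
.default_grid <- function(recipe, centers) {
  step_lo <- recipe$peptide_peak_width / 5
  step_hi <- recipe$peak_width_mz / 5
  g <- c(seq(550, 1050, by = step_lo), seq(4300, 7600, by = step_hi))
  sort(unique(c(g, centers)))
}

.add_peak <- function(y, grid, center, height, width) {
  if (height <= 0) return(y)
  lo <- findInterval(center - 8 * width, grid) + 1L
  hi <- findInterval(center + 8 * width, grid)
  if (hi < lo) return(y)
  idx <- lo:hi
  y[idx] <- y[idx] + height * exp(-(grid[idx] - center)^2 / (2 * width^2))
  y
}

#' Simulate a gas-phase breakdown spectrum series
#'
#' Renders, for every voltage step, the multiply charged free antibody,
#' one- and two-peptide complex envelopes and the released-peptide 2+/3+
#' signals as Gaussian peaks; the educt share follows the recipe's Boltzmann
#' parameters, the released-peptide signal grows with the dissociated share,
#' optional sodium-adduct satellites flank the peptide 2+ signal, and
#' additive Gaussian noise is drawn under the recipe seed (deterministic).
#'
#' @param recipe A [simulation_recipe()].
#' @return A [spectrum_series()] with a `ground_truth` attribute (per-step
#'   educt fractions and species apex heights).
#' @export
simulate_series <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  r <- recipe
  ep <- r$educt_params
  masses <- c(antibody = r$antibody_mass,
              complex1 = r$antibody_mass + r$peptide_mass,
              complex2 = r$antibody_mass + 2 * r$peptide_mass)
  centers <- c(
    unlist(lapply(masses, function(m) mz(m, r$charge_states))),
    mz(r$peptide_mass, r$peptide_charges),
    mz(r$peptide_mass + mass_table()$sodium_adduct, 2L))
  grid <- if (is.null(r$grid)) .default_grid(r, centers) else
    sort(unique(c(r$grid, centers)))

  f <- boltzmann_value(r$cv_steps, ep[["A1"]], ep[["A2"]], ep[["x0"]],
                       ep[["dx"]]) / 100
  Tt <- r$total_intensity
  c1 <- r$occupancy_split * f * Tt
  c2 <- (1 - r$occupancy_split) * f * Tt
  pep <- pmin(r$released_fraction * pmax(ep[["A1"]] / 100 - f, 0) * Tt,
              (1 - f) * Tt)
  ab <- (1 - f) * Tt - pep

  heights <- cbind(antibody = ab, complex1 = c1, complex2 = c2, peptide = pep)
  spectra <- withr::with_seed(r$seed, {
    lapply(seq_along(r$cv_steps), function(i) {
      y <- numeric(length(grid))
      for (s in names(masses)) {
        for (zz in r$charge_states) {
          hz <- heights[i, s] *
            exp(-(zz - r$envelope_center)^2 / (2 * r$envelope_width^2))
          y <- .add_peak(y, grid, mz(masses[[s]], zz), hz, r$peak_width_mz)
        }
      }
      pz <- r$peptide_charges
      ph <- heights[i, "peptide"] *
        c(1, r$peptide_ratio3)[seq_along(pz)]
      for (k in seq_along(pz)) {
        y <- .add_peak(y, grid, mz(r$peptide_mass, pz[k]), ph[k],
                       r$peptide_peak_width)
      }
      if (r$na_adduct_fraction > 0 && heights[i, "peptide"] > 0) {
        y <- .add_peak(y, grid,
                       mz(r$peptide_mass + mass_table()$sodium_adduct, 2L),
                       r$na_adduct_fraction * heights[i, "peptide"],
                       r$peptide_peak_width)
      }
      if (r$fragment_level > 0) {
        frag <- r$fragment_level * (1 - f[i]) * Tt
        sel <- grid >= 1200 & grid <= 2300
        y[sel] <- y[sel] + frag
      }
      if (r$noise_sd > 0) {
        y <- pmax(y + stats::rnorm(length(y), 0, r$noise_sd * Tt), 0)
      }
      list(mz = grid, intensity = y)
    })
  })
  out <- spectrum_series(r$cv_steps, spectra,
                         sample = sprintf("synthetic(seed=%d)", r$seed))
  attr(out, "ground_truth") <- list(educt_percent = 100 * f,
                                    heights = heights, recipe = r)
  out
}

#' Simulate an ITC titration
#'
#' Per-injection heats from the single-site (Wiseman) isotherm with
#' perfusion (displaced-volume) dilution accounting, plus optional Gaussian
#' heat noise. Deterministic given the seed.
#'
#' @param KA Association constant, 1/M.
#' @param dH Binding enthalpy, kJ/mol.
#' @param n_sites Stoichiometry (sites per cell macromolecule).
#' @param cell_conc Cell (macromolecule) concentration, uM.
#' @param syringe_conc Syringe (ligand) concentration, uM.
#' @param cell_volume Cell volume, uL.
#' @param injection_volumes Injection volumes, uL.
#' @param noise_sd Heat noise SD, uJ.
#' @param temperature Kelvin.
#' @param seed Integer RNG seed.
#' @return A [titration()] with simulated heats.
#' @export
simulate_itc <- function(KA, dH, n_sites = 1, cell_conc, syringe_conc,
                         cell_volume, injection_volumes, noise_sd = 0,
                         temperature = 298, seed = 1L) {
  stopifnot(KA > 0, cell_conc > 0, syringe_conc > 0, cell_volume > 0,
            all(injection_volumes > 0))
  t0 <- titration(cell_volume, cell_conc, syringe_conc, injection_volumes,
                  heats = rep(0, length(injection_volumes)),
                  temperature = temperature)
  q <- predicted_heats(c(KA = KA, dH = dH, n = n_sites), t0)
  if (noise_sd > 0) {
    q <- withr::with_seed(seed, q + stats::rnorm(length(q), 0, noise_sd))
  }
  t0$injections$heat <- q
  t0
}
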