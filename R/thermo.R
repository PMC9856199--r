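# Apparent kinetic/thermodynamic chain for gas-phase immune complex
# dissociation (Eyring-Polanyi, Arrhenius, Gibbs-Helmholtz, van't Hoff),
# extrapolated to the resting, neutral complex ("m0g" reference state:
# mean charge, zero excess energy, gas phase), and binder-group
# classification.

#' Thermodynamic configuration and physical constants
#'
#' @param T_amb Ambient reference temperature, K (default 298).
#' @param T_source Ion source temperature, K (default 313).
#' @param R Gas constant, J/(mol K).
#' @param kB Boltzmann constant, J/K.
#' @param h Planck constant, J s.
#' @param e_charge Elementary charge, C.
#' @param N_A Avogadro constant, 1/mol.
#' @param n_atoms Atom count of the antibody used for the internal-energy
#'   partition (default 20,000, the count of a sequence-known IgG1).
#' @param gas_mass Collision gas mass, Da (default argon, 39.948).
#' @param residence_time Collision-cell residence time, s (default 1 ms).
#' @param n_collisions Effective collision multiplier (default 1).
#' @return List of class `thermo_config`.
#' @export
thermo_config <- function(T_amb = 298, T_source = 313, R = 8.314,
                          kB = 1.380649e-23, h = 6.62607015e-34,
                          e_charge = 1.602176634e-19, N_A = 6.02214076e23,
                          n_atoms = 20000L, gas_mass = 39.948,
                          residence_time = 1e-3, n_collisions = 1L) {
  cfg <- list(T_amb = T_amb, T_source = T_source, R = R, kB = kB, h = h,
              e_charge = e_charge, N_A = N_A, n_atoms = n_atoms,
              gas_mass = gas_mass, residence_time = residence_time,
              n_collisions = n_collisions)
  if (any(unlist(cfg) <= 0)) stop("all constants must be positive",
                                  call. = FALSE)
  structure(cfg, class = "thermo_config")
}

#' Center-of-mass collision energy
#'
#' Molar center-of-mass frame energy available to a `z`-charged complex
#' accelerated through the collision-voltage difference:
#' `z * e * dcv * N_A * m_gas / (m_gas + M) * n_collisions`, in kJ/mol.
#'
#' @param z Charge state(s).
#' @param dcv Collision voltage difference(s), V.
#' @param complex_mass Complex mass, Da.
#' @param cfg A [thermo_config()].
#' @return Energy in kJ/mol.
#' @examples
#' com_energy(25, 30, 148570)
#' @export
com_energy <- function(z, dcv, complex_mass, cfg = thermo_config()) {
  com <- cfg$gas_mass / (cfg$gas_mass + complex_mass)
  z * cfg$e_charge * dcv * cfg$N_A * com * cfg$n_collisions / 1000
}

#' Effective internal temperature after collisional heating
#'
#' Partitions the deposited energy over the complex's `3N - 6` vibrational
#' degrees of freedom on top of the source temperature:
#' `T_source + E / ((3 n_atoms - 6) R)`.
#'
#' @param E Deposited energy, kJ/mol.
#' @param cfg A [thermo_config()].
#' @return Effective temperature, K.
#' @export
effective_temperature <- function(E, cfg = thermo_config()) {
  cfg$T_source + E * 1000 / ((3 * cfg$n_atoms - 6) * cfg$R)
}

#' Arrhenius / van't Hoff linear regression
#'
#' Weighted linear regression of `ln(y)` against `1/T`: the slope equals
#' `-Ea/R` (rate constants, Arrhenius) or `-dH/R` (equilibrium constants,
#' van't Hoff); the intercept is `ln A` or `dS/R`.
#'
#' @param T_eff Effective temperatures, K (at least two distinct values).
#' @param y Rate or equilibrium constants (positive).
#' @param weights Optional regression weights.
#' @return List with `slope`, `intercept`, `energy_kJ` (`-slope * R / 1000`)
#'   and the underlying `lm` fit.
#' @export
arrhenius_vant_hoff <- function(T_eff, y, weights = NULL) {
  stopifnot(length(T_eff) == length(y))
  if (length(unique(T_eff)) < 2L) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  if (any(y <= 0)) stop("rate/equilibrium constants must be positive",
                        call. = FALSE)
  df <- data.frame(invT = 1 / T_eff, lny = log(y))
  fit <- if (is.null(weights)) stats::lm(lny ~ invT, data = df)
         else stats::lm(lny ~ invT, data = df, weights = weights)
  cf <- stats::coef(fit)
  R <- thermo_config()$R
  list(slope = unname(cf[["invT"]]), intercept = unname(cf[["(Intercept)"]]),
       energy_kJ = -unname(cf[["invT"]]) * R / 1000, fit = fit)
}

#' Gibbs energy from an equilibrium constant
#'
#' `-R * T * ln(K) / 1000` in kJ/mol, with `K` referenced to 1 M.
#'
#' @param K Equilibrium constant (dimensionless).
#' @param T Temperature, K.
#' @param R Gas constant, J/(mol K).
#' @return kJ/mol.
#' @examples
#' gibbs_energy(4.55e-12)  # dissociation: large positive barrier
#' @export
gibbs_energy <- function(K, T = 298, R = 8.314) {
  -R * T * log(K) / 1000
}

#' Classify a peptide's binder group
#'
#' Group IV ("non-binder") when no complex ions exist at the lowest voltage
#' step; group III ("weak/unorthodox binder") when complexes form but the
#' dissociation course shows no valid transition; among orthodox binders,
#' group I ("very strong binder") when the apparent dissociation enthalpy
#' exceeds -2 kJ/mol and group II ("strong binder") otherwise.
#'
#' @param initial Initial educt fraction, percent.
#' @param has_fit Was a valid Boltzmann fit obtained?
#' @param dH Apparent dissociation enthalpy, kJ/mol (orthodox binders).
#' @param nonbinder_threshold Initial fraction (percent) below which the
#'   complex is considered absent (default 0.5).
#' @return Group label `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
classify_binder <- function(initial, has_fit, dH = NA_real_,
                            nonbinder_threshold = 0.5) {
  if (initial <= nonbinder_threshold) return("IV")
  if (!isTRUE(has_fit)) return("III")
  if (!is.finite(dH)) return("III")
  if (dH > -2) "I" else "II"
}

#' Binder-group descriptions
#'
#' @return Named character vector mapping group labels to descriptions.
#' @export
binder_groups <- function() {
  c(I = "very strong binder", II = "strong binder",
    III = "weak/unorthodox binder", IV = "non-binder")
}

.thermo_result <- function(kD = NA_real_, KD = NA_real_, dG = NA_real_,
                           dH = NA_real_, TdS = NA_real_, group,
                           mode = "ladder", points = NULL) {
  structure(list(kD_m0g = kD, KD_m0g = KD, dG_m0g = dG, dH_m0g = dH,
                 TdS_m0g = TdS, group = group, mode = mode, points = points),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("thermo_result: group %s (%s)\n", x$group,
              binder_groups()[[x$group]]))
  if (is.finite(x$dG_m0g)) {
    cat(sprintf("  kD = %.3g 1/s, KD = %.3g, dG = %.2f, dH = %.2f, TdS = %.2f kJ/mol\n",
                x$kD_m0g, x$KD_m0g, x$dG_m0g, x$dH_m0g, x$TdS_m0g))
  } else {
    cat("  numeric values not determined\n")
  }
  invisible(x)
}

#' Apparent kinetic/thermodynamic chain to the resting neutral complex
#'
#' Reconstructs the published chain of extrapolations from a fitted
#' dissociation course. Normalized educt survival along the voltage ladder
#' yields first-order rate constants `k = -ln(s)/tau` (collision-cell
#' residence time `tau`); each (charge state, voltage) pair deposits a
#' center-of-mass collision energy that raises the complex's effective
#' internal temperature over the source temperature; the Eyring-Polanyi
#' relation converts rates to activation equilibrium constants
#' `K = k h / (kB T)`; an Arrhenius regression over the effective
#' temperature series extrapolates the rate constant to the ambient
#' temperature (`kD_m0g`), and a van't Hoff regression yields the apparent
#' dissociation enthalpy (`dH_m0g`) and, extrapolated to 298 K, the
#' apparent dissociation constant (`KD_m0g`). `dG_m0g = -R T ln KD / 1000`
#' and `TdS_m0g = dH_m0g - dG_m0g`, so the Gibbs-Helmholtz identity and
#' `KD = exp(-dG 1000 / (R T))` hold exactly by construction.
#'
#' @param fit A `boltzmann_fit` (orthodox course), a `boltzmann_nofit`
#'   (weak/unorthodox course) or `NULL`.
#' @param complex_mass Complex mass, Da.
#' @param charges Charge states contributing energy points; defaults to the
#'   rounded mean charge only.
#' @param mean_charge Mean charge state (used when `charges` is NULL).
#' @param cfg A [thermo_config()].
#' @param cv_steps Voltage ladder evaluated (defaults to the fitted
#'   course's steps).
#' @param survival_range Normalized survival window retained for the
#'   regressions (default 5%-95%, excluding the plateaus).
#' @return A `thermo_result`; groups III/IV carry undetermined numeric
#'   fields.
#' @export
m0g_chain <- function(fit, complex_mass, charges = NULL, mean_charge = 25,
                      cfg = thermo_config(), cv_steps = NULL,
                      survival_range = c(0.05, 0.95)) {
  if (is.null(fit) || inherits(fit, "boltzmann_nofit")) {
    initial <- if (is.null(fit)) 0 else fit$initial
    group <- classify_binder(initial, has_fit = FALSE)
    return(.thermo_result(group = group, mode = "none"))
  }
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (is.null(charges)) charges <- round(mean_charge)
  xs <- cv_steps %||% fit$data$dcv
  s_all <- (boltzmann_value(xs, fit$A1, fit$A2, fit$x0, fit$dx) - fit$A2) /
    (fit$A1 - fit$A2)
  keep <- s_all >= survival_range[1] & s_all <= survival_range[2]
  xs <- xs[keep]; s <- s_all[keep]
  pts <- do.call(rbind, lapply(charges, function(zz) {
    E <- com_energy(zz, xs, complex_mass, cfg)
    Tf <- effective_temperature(E, cfg)
    k <- -log(s) / cfg$residence_time
    data.frame(z = zz, dcv = xs, survival = s, energy_kJ = E, T_eff = Tf,
               k = k, K = k * cfg$h / (cfg$kB * Tf))
  }))
  if (is.null(pts) || length(unique(pts$T_eff)) < 2L) {
    # single-point fallback: midpoint rate only, no van't Hoff step
    k50 <- log(2) / cfg$residence_time
    return(.thermo_result(kD = k50, group = classify_binder(
      fit$initial, TRUE, NA_real_), mode = "single_point"))
  }
  arr <- arrhenius_vant_hoff(pts$T_eff, pts$k)
  vh <- arrhenius_vant_hoff(pts$T_eff, pts$K)
  kD <- exp(arr$intercept + arr$slope / cfg$T_amb)
  lnK_amb <- vh$intercept + vh$slope / cfg$T_amb
  KD <- exp(lnK_amb)
  dH <- vh$energy_kJ
  dG <- -cfg$R * cfg$T_amb * lnK_amb / 1000
  TdS <- dH - dG
  .thermo_result(kD = kD, KD = KD, dG = dG, dH = dH, TdS = TdS,
                 group = classify_binder(fit$initial, TRUE, dH),
                 mode = "ladder", points = pts)
}

#' Tabulate and rank thermodynamic results
#'
#' Orders peptides by apparent dissociation enthalpy (least negative
#' first, i.e. strongest gas-phase binder first) with group labels.
#'
#' @param results Named list of `thermo_result` objects.
#' @return data.frame with columns `peptide`, `kD_m0g`, `KD_m0g`, `dG_m0g`,
#'   `dH_m0g`, `TdS_m0g`, `group`, `group_label`, ordered by rank.
#' @export
rank_binders <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(peptide = nm, kD_m0g = r$kD_m0g, KD_m0g = r$KD_m0g,
               dG_m0g = r$dG_m0g, dH_m0g = r$dH_m0g, TdS_m0g = r$TdS_m0g,
               group = r$group, group_label = binder_groups()[[r$group]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(match(df$group, c("I", "II", "III", "IV")), -df$dH_m0g,
               na.last = TRUE)
  df[ord, , drop = FALSE]
}
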