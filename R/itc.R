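# Independent (single-site, Wiseman) binding-model analysis of isothermal
# titration calorimetry injection heats.

#' Construct an ITC titration
#'
#' @param cell_volume Sample cell volume, uL.
#' @param cell_conc Cell macromolecule concentration, uM.
#' @param syringe_conc Syringe ligand concentration, uM.
#' @param injection_volumes Injection volumes, uL.
#' @param heats Integrated injection heats, uJ (same length).
#' @param temperature Kelvin (default 298).
#' @return Object of class `titration`.
#' @export
titration <- function(cell_volume, cell_conc, syringe_conc,
                      injection_volumes, heats, temperature = 298) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0),
            length(injection_volumes) == length(heats))
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injections = data.frame(volume = injection_volumes, heat = heats),
         temperature = temperature),
    class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf(
    "titration: %d injections, cell %.0f uL @ %.2f uM, syringe %.1f uM, T = %g K\n",
    nrow(x$injections), x$cell_volume, x$cell_conc, x$syringe_conc,
    x$temperature))
  invisible(x)
}

#' Molar ratios reached after each injection
#'
#' Ligand-to-macromolecule concentration ratio in the cell after each
#' injection, under the perfusion (constant-volume overflow) dilution
#' model.
#'
#' @param t A [titration()].
#' @return Numeric vector of molar ratios.
#' @export
molar_ratios <- function(t) {
  .itc_concentrations(t)$L / .itc_concentrations(t)$M
}

# cell concentrations after each injection under the perfusion model:
# each injection of volume v displaces v of the mixed cell content, so both
# species are diluted by (1 - v/V0) and ligand L0 * v/V0 is added.
.itc_concentrations <- function(t) {
  v0 <- t$cell_volume
  M <- numeric(nrow(t$injections)); L <- numeric(nrow(t$injections))
  m <- t$cell_conc; l <- 0
  for (i in seq_len(nrow(t$injections))) {
    d <- 1 - t$injections$volume[i] / v0
    m <- m * d
    l <- l * d + t$syringe_conc * t$injections$volume[i] / v0
    M[i] <- m; L[i] <- l
  }
  list(M = M, L = L)
}

#' Predicted injection heats of the independent binding model
#'
#' Bound-site fraction from the single-site quadratic
#' `Theta^2 - Theta (1 + L/(n M) + 1/(n KA M)) + L/(n M) = 0` (smaller
#' root), total heat content `Q_i = n Theta_i M_i V0 dH`, and per-injection
#' heat with the displaced-volume correction
#' `q_i = Q_i - Q_{i-1} + (v_i/V0) (Q_i + Q_{i-1})/2`.
#'
#' @param params Named vector/list with `KA` (1/M), `dH` (kJ/mol), `n`.
#' @param t A [titration()].
#' @return Heats in uJ, one per injection.
#' @export
predicted_heats <- function(params, t) {
  KA <- params[["KA"]]; dH <- params[["dH"]]; n <- params[["n"]]
  stopifnot(KA > 0, n > 0)
  conc <- .itc_concentrations(t)
  v0 <- t$cell_volume
  nI <- nrow(t$injections)
  if (nI == 0L) return(numeric(0))
  # concentrations in M for the binding polynomial
  Mm <- conc$M * 1e-6; Lm <- conc$L * 1e-6
  b <- 1 + Lm / (n * Mm) + 1 / (n * KA * Mm)
  disc <- b^2 - 4 * Lm / (n * Mm)
  if (any(disc < 0)) stop("non-physical binding root", call. = FALSE)
  theta <- (b - sqrt(disc)) / 2
  if (any(theta < -1e-9 | theta > 1 + 1e-9)) {
    stop("bound fraction outside [0, 1]; inconsistent inputs", call. = FALSE)
  }
  # heat content of the cell after each injection, uJ
  # (uM * uL * kJ/mol = 1e-3 uJ)
  Q <- n * theta * conc$M * v0 * dH * 1e-3
  q <- numeric(nI)
  qprev <- 0
  for (i in seq_len(nI)) {
    vi <- t$injections$volume[i]
    q[i] <- Q[i] - qprev + (vi / v0) * (Q[i] + qprev) / 2
    qprev <- Q[i]
  }
  q
}

#' Fit the independent binding model to a titration
#'
#' Least-squares fit of `(KA, dH, n)` against the integrated injection
#' heats (first injection excluded by default, standard practice for
#' diffusion across the syringe tip). Flat heat traces are refused and
#' reported as not binding. Derived quantities are computed by their exact
#' identities: `KD = 1/KA`, `dG = -R T ln(KA)/1000` (KA referenced to 1 M)
#' and `TdS = dH - dG`.
#'
#' @param t A [titration()].
#' @param fix_n Optional fixed stoichiometry (otherwise fitted).
#' @param exclude_first Drop the first injection from the objective
#'   (default TRUE).
#' @param flat_threshold Heat standard deviation (uJ) below which the trace
#'   is declared flat / not binding (default 0.05).
#' @return Object of class `itc_fit` (fields `KA`, `dH`, `n`, `KD`, `dG`,
#'   `TdS`, `fitted`, `residuals`) or `itc_nobind`.
#' @export
fit_independent <- function(t, fix_n = NULL, exclude_first = TRUE,
                            flat_threshold = 0.05) {
  stopifnot(inherits(t, "titration"))
  nI <- nrow(t$injections)
  if (nI < 5L) stop("need at least 5 injections to fit", call. = FALSE)
  heats <- t$injections$heat
  keep <- if (exclude_first) 2:nI else seq_len(nI)
  if (stats::sd(heats[keep]) < flat_threshold &&
      abs(mean(heats[keep])) < flat_threshold) {
    return(structure(list(reason = "flat heats: not binding"),
                     class = "itc_nobind"))
  }

  # starting values: assume near-saturation by the last injection
  q_tot <- sum(heats[keep])
  n0 <- if (is.null(fix_n)) 1 else fix_n
  dH0 <- q_tot / (n0 * t$cell_conc * t$cell_volume * 1e-3)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -40
  KA0 <- 100 / (t$cell_conc * 1e-6)  # c-value of order 100

  obj <- function(par) {
    KA <- exp(par[["lKA"]]); dH <- par[["dH"]]
    n <- if (is.null(fix_n)) exp(par[["ln"]]) else fix_n
    pred <- tryCatch(predicted_heats(c(KA = KA, dH = dH, n = n), t),
                     error = function(e) rep(1e6, nI))
    heats[keep] - pred[keep]
  }
  par0 <- c(lKA = log(KA0), dH = dH0)
  if (is.null(fix_n)) par0 <- c(par0, ln = log(n0))
  fit <- minpack.lm::nls.lm(par = par0, fn = obj,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- fit$par
  KA <- exp(par[["lKA"]]); dH <- par[["dH"]]
  n <- if (is.null(fix_n)) exp(par[["ln"]]) else fix_n
  Rgas <- 8.314
  dG <- -Rgas * t$temperature * log(KA) / 1000
  pred <- predicted_heats(c(KA = KA, dH = dH, n = n), t)
  structure(
    list(KA = KA, dH = dH, n = n, KD = 1 / KA, dG = dG, TdS = dH - dG,
         temperature = t$temperature, fitted = pred,
         residuals = heats - pred, excluded_first = exclude_first,
         convergence = fit$info),
    class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "independent-model ITC fit: KA = %.3g 1/M (KD = %.3g M), n = %.2f\n",
    x$KA, x$KD, x$n))
  cat(sprintf("  dH = %.2f, dG = %.2f, TdS = %.2f kJ/mol at %g K\n",
              x$dH, x$dG, x$TdS, x$temperature))
  invisible(x)
}

#' @export
print.itc_nobind <- function(x, ...) {
  cat("ITC: not binding (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Read a titration from CSV
#'
#' Expects columns `injection_index`, `volume_uL`, `heat_uJ`; the
#' experiment geometry is supplied separately.
#'
#' @param path CSV file.
#' @inheritParams titration
#' @return A [titration()].
#' @export
read_titration_csv <- function(path, cell_volume, cell_conc, syringe_conc,
                               temperature = 298) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("injection_index", "volume_uL", "heat_uJ") %in% names(df)))
  df <- df[order(df$injection_index), ]
  titration(cell_volume, cell_conc, syringe_conc, df$volume_uL, df$heat_uJ,
            temperature)
}

#' Write a titration to CSV
#'
#' @param t A [titration()].
#' @param path Output CSV.
#' @return Invisibly, the path.
#' @export
write_titration_csv <- function(t, path) {
  utils::write.csv(
    data.frame(injection_index = seq_len(nrow(t$injections)),
               volume_uL = t$injections$volume,
               heat_uJ = t$injections$heat),
    path, row.names = FALSE)
  invisible(path)
}

#' Tabulate ITC fits in solution-thermodynamics layout
#'
#' @param fits Named list of `itc_fit` / `itc_nobind` objects.
#' @return data.frame with columns `peptide`, `KD`, `KA`, `dG`, `dH`,
#'   `TdS`, `n` (`NA` for non-binding rows).
#' @export
itc_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "itc_fit")) {
      data.frame(peptide = nm, KD = f$KD, KA = f$KA, dG = f$dG, dH = f$dH,
                 TdS = f$TdS, n = f$n, stringsAsFactors = FALSE)
    } else {
      data.frame(peptide = nm, KD = NA_real_, KA = NA_real_, dG = NA_real_,
                 dH = NA_real_, TdS = NA_real_, n = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
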