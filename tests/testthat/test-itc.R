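# study-geometry titration: 190 uL cell, 1.95 uM sites, 40 uM peptide,
# 19 x 2 uL injections at 298 K
reference_titration <- function(KA = 4.58e6, dH = -60.40, n = 1, noise = 0,
                            seed = 1L) {
  simulate_itc(KA, dH, n_sites = n, cell_conc = 1.95, syringe_conc = 40,
               cell_volume = 190, injection_volumes = rep(2, 19),
               noise_sd = noise, seed = seed)
}

test_that("predicted heats obey the stoichiometric and null limits", {
  t0 <- titration(190, 5, 100, rep(2, 15), rep(0, 15))
  q <- predicted_heats(c(KA = 1e12, dH = -50, n = 1), t0)
  expect_equal(q[1], -50 * 100 * 2 * 1e-3, tolerance = 0.02 * 10)
  expect_lt(max(abs(q[8:15])), 0.02 * abs(q[1]))
  expect_equal(predicted_heats(c(KA = 1e6, dH = 0, n = 1), t0),
               rep(0, 15))
  # total heat approaches n * M * V0 * dH at saturation
  expect_equal(sum(q), 1 * 5 * 190 * -50 * 1e-3, tolerance = 0.02 * 95)
})

test_that("predicted heats match a mass-action bisection oracle", {
  t0 <- reference_titration()
  q <- predicted_heats(c(KA = 4.58e6, dH = -60.4, n = 2), t0)
  # independent equilibrium solver: free ligand by bisection at each step
  v0 <- 190; Mconc <- 1.95; Lsyr <- 40
  m <- Mconc; l <- 0
  Qprev <- 0
  for (i in 1:19) {
    d <- 1 - 2 / v0
    m <- m * d; l <- l * d + Lsyr * 2 / v0
    nM <- 2 * m * 1e-6; Lt <- l * 1e-6; KA <- 4.58e6
    lo <- 0; hi <- Lt
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      bound <- nM * KA * mid / (1 + KA * mid)
      if (bound + mid > Lt) hi <- mid else lo <- mid
    }
    Lf <- (lo + hi) / 2
    bound <- nM * KA * Lf / (1 + KA * Lf)
    Q <- bound * 1e6 * v0 * -60.4 * 1e-3      # uJ
    qi <- Q - Qprev + (2 / v0) * (Q + Qprev) / 2
    expect_equal(q[i], qi, tolerance = 1e-9 * max(abs(q)))
    Qprev <- Q
  }
})

test_that("noise-free fits recover the generating parameters and identities", {
  t0 <- reference_titration(n = 2)
  fit <- fit_independent(t0)
  expect_equal(fit$KA, 4.58e6, tolerance = 1e-3 * 4.58e6)
  expect_equal(fit$dH, -60.40, tolerance = 1e-3 * 60.4)
  expect_equal(fit$n, 2, tolerance = 1e-3 * 2)
  # exact identities
  expect_equal(fit$KD * fit$KA, 1, tolerance = 1e-12)
  expect_equal(fit$dG, fit$dH - fit$TdS, tolerance = 1e-12)
  expect_equal(fit$dG, -8.314 * 298 * log(fit$KA) / 1000, tolerance = 1e-12)
})

test_that("gibbs energies from association constants match tabulated values", {
  # formation: -R 298 ln(KA); dissociation barrier: -R 298 ln(KD)
  expect_equal(gibbs_energy(4.58e6), -38.05, tolerance = 0.05)
  expect_equal(gibbs_energy(4.12e6), -37.77, tolerance = 0.05)
  expect_equal(gibbs_energy(4.55e-12), 64.70, tolerance = 0.1)
})

test_that("flat heat traces are reported as not binding", {
  t0 <- titration(190, 1.95, 40, rep(2, 18), rnorm(18, 0, 0.01))
  expect_s3_class(fit_independent(t0), "itc_nobind")
})

test_that("parameter recovery stays within module tolerances under heat noise", {
  errs <- sapply(1:100, function(i) {
    tt <- reference_titration(noise = 0.02 * 4.6, seed = 1000 + i)
    fit <- fit_independent(tt)
    if (inherits(fit, "itc_nobind")) return(c(NA, NA))
    c(abs(fit$dH + 60.40) / 60.40, abs(fit$KA - 4.58e6) / 4.58e6)
  })
  expect_lt(median(errs[1, ], na.rm = TRUE), 0.05)
  expect_lt(median(errs[2, ], na.rm = TRUE), 0.15)
})

test_that("titrations round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  t0 <- reference_titration(n = 2)
  write_titration_csv(t0, tmp)
  back <- read_titration_csv(tmp, cell_volume = 190, cell_conc = 1.95,
                             syringe_conc = 40)
  expect_equal(back$injections$heat, t0$injections$heat)
  fit <- fit_independent(back)
  expect_equal(fit$KA, 4.58e6, tolerance = 1e-3 * 4.58e6)
})

test_that("molar ratios span the working range of the titration design", {
  t0 <- reference_titration()
  mr <- molar_ratios(t0)
  expect_true(all(diff(mr) > 0))
  expect_lt(mr[1], 0.5)
  expect_gt(mr[19], 4)
})

test_that("itc tables mix fitted and non-binding rows", {
  fits <- list(p1 = fit_independent(reference_titration(n = 2)),
               p8 = structure(list(reason = "flat"), class = "itc_nobind"))
  tab <- itc_table(fits)
  expect_identical(tab$peptide, c("p1", "p8"))
  expect_true(is.na(tab$KA[2]))
  expect_equal(tab$dH[1], -60.4, tolerance = 0.1)
})
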