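test_that("center-of-mass collision energy follows the unit-conversion oracle", {
  cfg <- thermo_config()
  expect_equal(com_energy(0, 30, 148570, cfg), 0)
  # z = 1, 1 V, com factor ~ 1: the Faraday constant in kJ/mol
  expect_equal(com_energy(1, 1, 1e-12, cfg), 96.485, tolerance = 1e-4)
  # independent constant set (CODATA values written out)
  eV_per_V <- 1.602176634e-19
  avogadro <- 6.02214076e23
  com <- 39.948 / (39.948 + 148570)
  oracle <- 25 * eV_per_V * 30 * avogadro * com / 1000
  expect_equal(com_energy(25, 30, 148570, cfg), oracle,
               tolerance = 1e-9 * oracle)
})

test_that("effective temperature partitions energy over 3N - 6 modes", {
  cfg <- thermo_config()
  expect_equal(effective_temperature(0, cfg), cfg$T_source)
  E100 <- (3 * cfg$n_atoms - 6) * cfg$R * 100 / 1000
  expect_equal(effective_temperature(E100, cfg), cfg$T_source + 100,
               tolerance = 1e-9)
})

test_that("linearized Arrhenius/van't Hoff regression recovers energies", {
  cfg <- thermo_config()
  Ts <- c(320, 340, 360, 380, 400)
  Ea <- 50  # kJ/mol
  k <- 1e8 * exp(-Ea * 1000 / (cfg$R * Ts))
  av <- arrhenius_vant_hoff(Ts, k)
  expect_equal(av$energy_kJ, Ea, tolerance = 1e-6)
  expect_equal(exp(av$intercept), 1e8, tolerance = 1e-4 * 1e8)
  # two-point fit equals the closed-form slope
  av2 <- arrhenius_vant_hoff(Ts[c(1, 5)], k[c(1, 5)])
  closed <- (log(k[5]) - log(k[1])) / (1 / Ts[5] - 1 / Ts[1])
  expect_equal(av2$slope, closed, tolerance = 1e-9)
  # 1% multiplicative noise: energy within 5%
  set.seed(17)
  knoisy <- k * exp(rnorm(5, 0, 0.01))
  expect_equal(arrhenius_vant_hoff(Ts, knoisy)$energy_kJ, Ea,
               tolerance = 0.05 * Ea)
  expect_error(arrhenius_vant_hoff(rep(300, 3), c(1, 2, 3)), "distinct")
  expect_error(arrhenius_vant_hoff(Ts, -k), "positive")
})

test_that("forward-generated van't Hoff ladders round-trip exactly", {
  cfg <- thermo_config()
  dH <- -1.91; dS_R <- -26.9   # slope/intercept parameterization
  Ts <- seq(313, 360, length.out = 8)
  K <- exp(dS_R - dH * 1000 / (cfg$R * Ts))
  vh <- arrhenius_vant_hoff(Ts, K)
  expect_equal(vh$energy_kJ, dH, tolerance = 1e-6 * abs(dH))
  expect_equal(vh$intercept, dS_R, tolerance = 1e-6 * abs(dS_R))
})

test_that("the extrapolation chain yields exact thermodynamic identities", {
  cfg <- thermo_config()
  f <- fit_boltzmann(wt_course())
  res <- m0g_chain(f, complex_mass = 146756.2 + 1813.907, charges = 23:27,
                   cfg = cfg)
  expect_s3_class(res, "thermo_result")
  expect_equal(res$dG_m0g, res$dH_m0g - res$TdS_m0g, tolerance = 1e-9)
  expect_equal(res$KD_m0g, exp(-res$dG_m0g * 1000 / (cfg$R * cfg$T_amb)),
               tolerance = 1e-9 * res$KD_m0g)
  expect_true(res$kD_m0g > 0)
  # deterministic: identical inputs give identical results
  res2 <- m0g_chain(f, complex_mass = 146756.2 + 1813.907, charges = 23:27,
                    cfg = cfg)
  expect_identical(res$dH_m0g, res2$dH_m0g)
})

test_that("higher midpoint voltages never rank as weaker gas-phase binders", {
  cfg <- thermo_config()
  x <- cv13()
  dgs <- sapply(c(25, 30, 35), function(x0) {
    y <- boltzmann_value(x, 77.36, 36.24, x0, 15.2)
    f <- fit_boltzmann(educt_course(x, y))
    m0g_chain(f, complex_mass = 148570, charges = 23:27, cfg = cfg)$dG_m0g
  })
  expect_true(all(diff(dgs) > 0))
})

test_that("binder groups follow the enthalpy rule and the course evidence", {
  expect_identical(classify_binder(77.36, TRUE, -1.91), "I")
  expect_identical(classify_binder(41.60, TRUE, -2.25), "II")
  expect_identical(classify_binder(15.37, FALSE), "III")
  expect_identical(classify_binder(0, FALSE), "IV")
  # chain integration: transition-free course -> group III, all values open
  weak <- fit_boltzmann(educt_course(cv13(), seq(15.37, 5.9,
                                                 length.out = 13)))
  resIII <- m0g_chain(weak, complex_mass = 148570)
  expect_identical(resIII$group, "III")
  expect_true(is.na(resIII$dG_m0g))
  resIV <- m0g_chain(NULL, complex_mass = 148570)
  expect_identical(resIV$group, "IV")
})

test_that("rankings order groups first and enthalpy within groups", {
  mk <- function(dH, group) {
    structure(list(kD_m0g = 1, KD_m0g = 1e-12, dG_m0g = 64,
                   dH_m0g = dH, TdS_m0g = dH - 64, group = group,
                   mode = "ladder", points = NULL),
              class = "thermo_result")
  }
  res <- list(p4 = mk(-2.25, "II"), p1 = mk(-1.91, "I"),
              p7 = m0g_chain(fit_boltzmann(
                educt_course(cv13(), seq(15.37, 5.9, length.out = 13))),
                complex_mass = 148570),
              p2 = mk(-1.57, "I"))
  tab <- rank_binders(res)
  expect_identical(tab$peptide, c("p2", "p1", "p4", "p7"))
  expect_identical(tab$group, c("I", "I", "II", "III"))
  expect_identical(tab$group_label[4], "weak/unorthodox binder")
})
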