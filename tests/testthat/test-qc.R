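# builds a spectrum with explicit apex and valley levels for the three
# antibody-containing species at the given charge states
valley_spectrum <- function(antibody_mass, peptide_mass, charges,
                            apex = 100, valley_ratio = 0.5) {
  mzs <- c(); ys <- c()
  for (zz in charges) {
    pos <- mz(antibody_mass + 0:2 * peptide_mass, zz)
    mid <- (pos[-3] + pos[-1]) / 2
    mzs <- c(mzs, pos, mid)
    ys <- c(ys, rep(apex, 3), rep(valley_ratio * apex, 2))
  }
  ord <- order(mzs)
  list(mz = mzs[ord], intensity = ys[ord])
}

test_that("resolution criterion counts charge states with a 50% valley, boundary inclusive", {
  ab <- 146756.2; pep <- 1813.907
  exactly50 <- valley_spectrum(ab, pep, 23:27, valley_ratio = 0.5)
  cr <- criterion_resolution(exactly50, ab, pep, tolerance = 2)
  expect_true(as.logical(cr))
  expect_identical(attr(cr, "resolved_states"), 5L)

  over50 <- valley_spectrum(ab, pep, 23:27, valley_ratio = 0.51)
  expect_false(as.logical(criterion_resolution(over50, ab, pep, tolerance = 2)))

  # only four resolvable charge states is not enough
  four <- valley_spectrum(ab, pep, 24:27, valley_ratio = 0.3)
  cr4 <- criterion_resolution(four, ab, pep, charges = 24:27, tolerance = 2)
  expect_false(as.logical(cr4))
  expect_identical(attr(cr4, "resolved_states"), 4L)
})

test_that("resolution criterion follows peak width on simulated series", {
  r <- simulation_recipe()
  s <- simulate_series(r)
  sp <- smooth_spectrum(list(mz = s$steps[[1]]$mz,
                             intensity = s$steps[[1]]$intensity))
  expect_true(as.logical(criterion_resolution(sp, r$antibody_mass,
                                              r$peptide_mass)))
  rb <- simulation_recipe(peak_width_mz = 60)
  sb <- simulate_series(rb)
  spb <- smooth_spectrum(list(mz = sb$steps[[1]]$mz,
                              intensity = sb$steps[[1]]$intensity))
  expect_false(as.logical(criterion_resolution(spb, rb$antibody_mass,
                                               rb$peptide_mass)))
})

test_that("sodium criterion applies the 35% threshold at the final step", {
  pep <- 1813.907
  mk <- function(ratio) {
    pos2 <- mz(pep, 2); posna <- mz(pep + mass_table()$sodium_adduct, 2)
    grid <- seq(900, 925, by = 0.01)
    y <- 100 * exp(-(grid - pos2)^2 / (2 * 0.05^2)) +
      ratio * 100 * exp(-(grid - posna)^2 / (2 * 0.05^2))
    list(mz = grid, intensity = y)
  }
  expect_true(as.logical(criterion_sodium(mk(0.34), pep)))
  expect_false(as.logical(criterion_sodium(mk(0.36), pep)))
  expect_true(as.logical(criterion_sodium(mk(0.35), pep)))  # inclusive

  # adduct-free synthetic series passes
  r <- simulation_recipe(na_adduct_fraction = 0)
  s <- simulate_series(r)
  last <- s$steps[[length(s$steps)]]
  cs <- criterion_sodium(list(mz = last$mz, intensity = last$intensity),
                         r$peptide_mass)
  expect_true(as.logical(cs))
  expect_lt(attr(cs, "ratio"), 0.01)
})

test_that("non-binder series make the sodium criterion undecidable but passing", {
  r <- simulation_recipe(educt_params = c(A1 = 0, A2 = 0, x0 = 30, dx = 15.2))
  s <- simulate_series(r)
  last <- s$steps[[length(s$steps)]]
  expect_warning(
    cs <- criterion_sodium(list(mz = last$mz, intensity = last$intensity),
                           r$peptide_mass),
    "undecidable")
  expect_true(as.logical(cs))
  expect_true(attr(cs, "undecidable"))
})

test_that("outlier and fit-accuracy criteria read the Boltzmann fit", {
  f <- fit_boltzmann(wt_course())
  expect_true(criterion_outliers(f))
  expect_true(criterion_r2(f))
  fm <- fit_boltzmann(wt_course(), exclude = 4L)
  expect_false(criterion_outliers(fm))
  lowr2 <- structure(list(r2 = 0.989, excluded = integer(0)),
                     class = "boltzmann_fit")
  expect_false(criterion_r2(lowr2))
  boundary <- structure(list(r2 = 0.99, excluded = integer(0)),
                        class = "boltzmann_fit")
  expect_true(criterion_r2(boundary))
})

test_that("the gate passes on three of four criteria and is monotone", {
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE), d = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cmb <- unlist(combos[i, ])
    rep <- qc_report(cmb[1], cmb[2], cmb[3], cmb[4])
    expect_identical(rep$passed, sum(cmb) >= 3L)
    # flipping any FALSE to TRUE never revokes a pass
    for (j in which(!cmb)) {
      up <- cmb; up[j] <- TRUE
      rep2 <- qc_report(up[1], up[2], up[3], up[4])
      expect_true(rep2$passed >= rep$passed)
    }
  }
})

test_that("QC reports serialize to JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  rep <- qc_report(TRUE, TRUE, FALSE, TRUE)
  write_qc_json(rep, tmp)
  back <- jsonlite::read_json(tmp)
  expect_true(back$passed)
  expect_false(back$criteria$outliers)
})
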