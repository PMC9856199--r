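trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("scan combination averages pointwise and preserves ion current", {
  grid <- seq(100, 110, by = 0.1)
  s1 <- list(mz = grid, intensity = rep(0, length(grid)))
  s2 <- list(mz = grid, intensity = rep(2, length(grid)))
  avg <- combine_scans(list(s1, s2))
  expect_equal(avg$intensity, rep(1, length(grid)))
  # idempotence
  peak <- list(mz = grid, intensity = exp(-(grid - 105)^2))
  expect_equal(combine_scans(list(peak, peak))$intensity, peak$intensity)
  expect_error(combine_scans(list()), "no scans")
  # mismatched grids: resample then average; TIC preserved within 1%
  g2 <- seq(100.05, 109.95, by = 0.07)
  peak2 <- list(mz = g2, intensity = exp(-(g2 - 105)^2))
  avg2 <- combine_scans(list(peak, peak2))
  expect_equal(trapz(avg2$mz, avg2$intensity), trapz(peak$mz, peak$intensity),
               tolerance = 0.01)
})

test_that("iterated Savitzky-Golay smoothing is exact on low-degree polynomials", {
  x <- seq_len(200)
  y <- 3 + 0.5 * x - 0.01 * x^2      # degree 2 = filter order
  sm <- smooth_spectrum(y, window = 10, passes = 20, polyorder = 2)
  expect_equal(sm, y, tolerance = 1e-9)
  expect_identical(smooth_spectrum(y, passes = 0), y)
  expect_error(smooth_spectrum(y[1:5], window = 10, passes = 1), "shorter")
  expect_error(smooth_spectrum(y, window = 3, polyorder = 5, passes = 1),
               "polyorder")
})

test_that("single-spike response matches an explicit kernel convolution oracle", {
  # independent oracle: project onto degree-2 polynomials over an 11-point
  # window and convolve the center row explicitly
  A <- outer(-5:5, 0:2, `^`)
  H <- A %*% solve(t(A) %*% A) %*% t(A)
  kern <- H[6, ]
  n <- 101
  y <- numeric(n); y[51] <- 7
  oracle <- y
  for (p in 1:3) oracle <- as.numeric(stats::filter(oracle, kern, sides = 2))
  sm <- smooth_spectrum(y, window = 10, passes = 3, polyorder = 2)
  interior <- 21:81
  expect_equal(sm[interior], oracle[interior], tolerance = 1e-10)
})

test_that("apex reading returns heights, background floors, and flags misses", {
  grid <- seq(5800, 6000, by = 0.25)
  target <- mz(146756.2, 25)
  y <- 1000 * exp(-(grid - target)^2 / (2 * 2.5^2)) + 10
  sp <- list(mz = grid, intensity = y)
  expect_equal(as.numeric(read_height(sp, 146756.2, 25, 5)), 1010,
               tolerance = 1e-5)
  flat <- list(mz = grid, intensity = rep(10, length(grid)))
  expect_equal(as.numeric(read_height(flat, 146756.2, 25, 5)), 10)
  miss <- read_height(sp, 50000, 3, 5)
  expect_true(is.na(miss))
  expect_true(attr(miss, "missing"))
  expect_error(read_height(sp, 146756.2, 25, 0), "tolerance")
})

test_that("colliding species inside one window warn and yield the taller apex", {
  grid <- seq(599, 612, by = 0.01)
  y <- 100 * exp(-(grid - 605.64)^2 / (2 * 0.05^2)) +
    60 * exp(-(grid - 605.94)^2 / (2 * 0.05^2))
  sp <- list(mz = grid, intensity = y)
  expect_warning(h <- read_height(sp, 1813.907, 3, 0.5), "collision")
  expect_equal(as.numeric(h), 100, tolerance = 1e-6)
})

test_that("envelope fitting recovers center, apex and imputes to five points", {
  sym <- fit_envelope(c("23" = 10, "24" = 40, "25" = 100, "26" = 40,
                        "27" = 10), background = 1)
  expect_equal(sym$gaussian[["center"]], 25, tolerance = 0.01)
  expect_equal(sym$gaussian[["apex"]], 100, tolerance = 0.1 * 100)
  expect_length(sym$imputed, 0L)

  # exact Gaussian points are recovered essentially exactly
  z <- 23:27
  ytrue <- 480 * exp(-(z - 25.3)^2 / (2 * 1.1^2))
  ex <- fit_envelope(setNames(ytrue, z))
  expect_equal(ex$gaussian[["apex"]], 480, tolerance = 1e-6)
  expect_equal(ex$gaussian[["center"]], 25.3, tolerance = 1e-6)

  # three measured points gain two imputed flanks at background
  imp <- fit_envelope(c("24" = 50, "25" = 120, "26" = 60), background = 2)
  expect_length(imp$imputed, 2L)
  expect_setequal(imp$imputed, c(23, 27))
  expect_false(imp$nondetect)

  # all-background points: non-detect with apex at background
  nd <- fit_envelope(c("24" = 2, "25" = 2, "26" = 2), background = 2)
  expect_true(nd$nondetect)
  expect_equal(nd$gaussian[["apex"]], 2)
  expect_true(is.na(nd$gaussian[["center"]]))
})

test_that("envelope fit agrees with a brute-force grid-search oracle", {
  pts <- c("23" = 5, "24" = 30, "25" = 100, "26" = 60, "27" = 8)
  fit <- fit_envelope(pts)
  oracle <- envelope_oracle(23:27, as.numeric(pts))
  expect_equal(fit$gaussian[["center"]], oracle[["center"]], tolerance = 0.05)
  expect_equal(fit$gaussian[["apex"]], oracle[["apex"]],
               tolerance = 0.01 * oracle[["apex"]])
})

test_that("normalized educt fraction follows the species-height formula", {
  expect_equal(normalized_educt(c(antibody = 10, complex1 = 30,
                                  complex2 = 10, peptide = 0)), 80)
  expect_equal(normalized_educt(c(antibody = 50, complex1 = 0, complex2 = 0,
                                  peptide = 50)), 0)
  h <- c(antibody = 13, complex1 = 41, complex2 = 17, peptide = 29)
  expect_equal(normalized_educt(h * 7.3), normalized_educt(h))
  expect_error(normalized_educt(c(antibody = 0, complex1 = 0, complex2 = 0)),
               "zero total")
  expect_error(normalized_educt(c(complex1 = 5, complex2 = 5)), "antibody")
})

test_that("zero-charge deconvolution round-trips and rejects interleaved series", {
  # forward-generate then invert across the working mass range
  for (M in c(5e4, 1e5, 146756.2, 2e5)) {
    zz <- 24:26
    d <- deconvolute_mass(mz(M, zz))
    expect_equal(d$mass, M, tolerance = 1e-6 * M)  # 1 ppm
  }
  two <- deconvolute_mass(c(mz(1e5, 20), mz(1e5, 21)))
  expect_equal(two$mass, 1e5, tolerance = 0.1)
  # single peak with known charge: algebraic inversion
  one <- deconvolute_mass(5001.00728, z = 25)
  expect_equal(one$mass, 25 * 5001.00728 - 25 * 1.007276, tolerance = 1e-6)
  expect_error(deconvolute_mass(5001.0), "at least 2")
  # interleaved peaks from two different masses
  bad <- sort(c(mz(1e5, 20:21), mz(1.4e5, 27:28)), decreasing = TRUE)
  expect_error(deconvolute_mass(bad), "inconsistent|spread")
})
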