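# shared fixtures: the thirteen-step voltage schedule and the wild-type
# course parameters used as simulation ground truth throughout

cv13 <- function() c(2, 4, 6, 8, 12, 16, 20, 30, 40, 50, 60, 70, 80)

wt_params <- function() c(A1 = 77.36, A2 = 36.24, x0 = 30.0, dx = 15.2)

wt_course <- function(noise_pp = 0) {
  x <- cv13()
  p <- wt_params()
  y <- boltzmann_value(x, p[["A1"]], p[["A2"]], p[["x0"]], p[["dx"]])
  if (noise_pp > 0) y <- y + rnorm(length(x), 0, noise_pp)
  educt_course(x, pmin(pmax(y, 0), 100))
}

# printed course characteristics of the six orthodox peptides:
# initial %, final %, dx V, tabulated tangent slope %/V
orthodox_rows <- function() {
  data.frame(
    peptide = 1:6,
    initial = c(77.36, 87.39, 52.55, 41.60, 58.77, 58.83),
    final = c(36.24, 47.63, 32.68, 23.12, 29.41, 23.33),
    dx = c(15.2, 11.7, 12.3, 13.2, 13.0, 11.8),
    slope = c(-0.67, -0.85, -0.40, -0.35, -0.57, -0.75)
  )
}

# brute-force Gaussian grid-search oracle over (height, center, width)
envelope_oracle <- function(z, y, h_range = NULL, step_c = 0.01) {
  if (is.null(h_range)) h_range <- c(0.5, 1.5) * max(y)
  best <- NULL
  bsse <- Inf
  for (h in seq(h_range[1], h_range[2], length.out = 151)) {
    for (cc in seq(min(z), max(z), by = step_c)) {
      for (w in seq(0.4, diff(range(z)), by = 0.02)) {
        sse <- sum((y - h * exp(-(z - cc)^2 / (2 * w^2)))^2)
        if (sse < bsse) {
          bsse <- sse
          best <- c(apex = h, center = cc, width = w)
        }
      }
    }
  }
  best
}

# sigmoid grid-search oracle: (A1, A2) profiled out by closed-form linear
# least squares at each (x0, dx) grid node, then Nelder-Mead refinement
boltzmann_oracle <- function(x, y) {
  n <- length(y)
  sy <- sum(y)
  sse_of <- function(x0, dx) {
    u <- 1 / (1 + exp((x - x0) / dx))
    su <- sum(u); suu <- sum(u * u); suy <- sum(u * y)
    det <- n * suu - su * su
    if (det < 1e-12) return(list(sse = Inf))
    b <- (n * suy - su * sy) / det
    a <- (sy - b * su) / n
    list(sse = sum((y - a - b * u)^2), A1 = a + b, A2 = a)
  }
  best <- NULL
  bsse <- Inf
  for (x0 in seq(min(x), max(x), by = 1)) {
    for (dx in exp(seq(log(0.5), log(10 * diff(range(x))), length.out = 40))) {
      r <- sse_of(x0, dx)
      if (r$sse < bsse) {
        bsse <- r$sse
        best <- c(x0 = x0, dx = dx)
      }
    }
  }
  opt <- optim(best, function(p) sse_of(p[1], p[2])$sse)
  r <- sse_of(opt$par[1], opt$par[2])
  c(A1 = r$A1, A2 = r$A2, x0 = unname(opt$par[1]), dx = unname(opt$par[2]))
}
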