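# Boltzmann sigmoid fitting of normalized educt dissociation courses and
# tangent/midpoint extraction.

#' Boltzmann sigmoid value
#'
#' Evaluates `A2 + (A1 - A2) / (1 + exp((x - x0)/dx))`, the dissociation
#' course model: `A1` is the initial (low-voltage) plateau in percent, `A2`
#' the final plateau, `x0` the midpoint collision-voltage difference
#' (the half-dissociation voltage) and `dx` the course constant in volts.
#'
#' @param x Collision cell voltage difference(s), V.
#' @param A1,A2 Initial and final plateau, percent.
#' @param x0 Curve center, V.
#' @param dx Course constant, V (nonzero).
#' @return Educt fraction(s) in percent.
#' @examples
#' boltzmann_value(30, 77.36, 36.24, 30, 15.2)  # midpoint = (A1 + A2)/2
#' @export
boltzmann_value <- function(x, A1, A2, x0, dx) {
  if (any(dx == 0)) stop("dx must be nonzero", call. = FALSE)
  A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
}

#' Tangent slope at the Boltzmann curve center
#'
#' The slope of the sigmoid at its midpoint `x0`, `-(A1 - A2)/(4 dx)`,
#' in percent per volt. The tangent line there is
#' `y = (A1 + A2)/2 + slope * (x - x0)`.
#'
#' @inheritParams boltzmann_value
#' @return Slope in %/V.
#' @examples
#' tangent_slope(77.36, 36.24, 15.2)  # -0.676
#' @export
tangent_slope <- function(A1, A2, dx) {
  -(A1 - A2) / (4 * dx)
}

#' Construct an educt dissociation course
#'
#' Normalized educt fraction (percent of summed species heights held by the
#' one- and two-peptide complexes) versus collision voltage difference,
#' optionally with replicate summary statistics.
#'
#' @param dcv Strictly increasing collision voltage differences, V.
#' @param fraction Normalized educt fraction, percent, one per step.
#' @param sd Replicate standard deviations (optional).
#' @param n Number of replicates per step.
#' @return A data.frame of class `educt_course`.
#' @export
educt_course <- function(dcv, fraction, sd = NA_real_, n = 1L) {
  stopifnot(length(dcv) == length(fraction), !is.unsorted(dcv, strictly = TRUE))
  if (any(fraction < -1e-9 | fraction > 100 + 1e-9)) {
    stop("educt fractions must lie in [0, 100]", call. = FALSE)
  }
  structure(
    data.frame(dcv = dcv, fraction = fraction, sd = sd, n = n),
    class = c("educt_course", "data.frame")
  )
}

#' Average replicate educt courses
#'
#' @param courses List of [educt_course()] objects on identical voltage steps.
#' @return An `educt_course` whose `fraction` is the replicate mean and `sd`
#'   the replicate standard deviation.
#' @export
combine_courses <- function(courses) {
  stopifnot(length(courses) >= 1L)
  dcv <- courses[[1]]$dcv
  for (cc in courses) {
    if (!isTRUE(all.equal(cc$dcv, dcv))) {
      stop("replicate courses must share voltage steps", call. = FALSE)
    }
  }
  mat <- sapply(courses, function(cc) cc$fraction)
  mat <- matrix(mat, nrow = length(dcv))
  educt_course(dcv,
               fraction = rowMeans(mat),
               sd = apply(mat, 1, stats::sd),
               n = length(courses))
}

#' Fit a Boltzmann sigmoid to an educt course
#'
#' Least-squares fit of the four-parameter sigmoid to the replicate-mean
#' course. Courses whose dynamic range is below `flat_range` percentage
#' points show no dissociation transition and are refused (a
#' `boltzmann_nofit` result is returned instead, as for weak/unorthodox
#' binders). Points may be masked via `exclude`; any exclusion is recorded
#' and fails the corresponding quality-control criterion.
#'
#' @param course An [educt_course()] (or data.frame with `dcv`, `fraction`).
#' @param exclude Integer indices of masked points (default none).
#' @param weights `"none"` (default, fit on means as recorded) or
#'   `"inv_var"` for 1/sd^2 weighting where replicate SDs are available.
#' @param flat_range Minimal dynamic range (percentage points) below which
#'   the course is declared transition-free. Default 10.
#' @return A `boltzmann_fit` (fields `A1`, `A2`, `x0`, `dx`, `r2`, `slope`,
#'   `excluded`, `covariance`, `data`) or a `boltzmann_nofit`.
#' @examples
#' x <- c(2, 4, 6, 8, 12, 16, 20, 30, 40, 50, 60, 70, 80)
#' y <- boltzmann_value(x, 77.36, 36.24, 30, 15.2)
#' fit_boltzmann(educt_course(x, y))
#' @export
fit_boltzmann <- function(course, exclude = integer(0),
                          weights = c("none", "inv_var"), flat_range = 10) {
  weights <- match.arg(weights)
  df <- as.data.frame(course)
  stopifnot(all(c("dcv", "fraction") %in% names(df)))
  keep <- setdiff(seq_len(nrow(df)), exclude)
  x <- df$dcv[keep]
  y <- df$fraction[keep]
  if (length(x) < 5L) stop("need at least 5 course points", call. = FALSE)
  rng <- diff(range(y))
  if (rng < flat_range) {
    return(structure(
      list(reason = "no transition", initial = y[which.min(x)],
           final = y[which.max(x)], range = rng, excluded = exclude),
      class = "boltzmann_nofit"
    ))
  }

  a1 <- max(y); a2 <- min(y)
  mid <- (a1 + a2) / 2
  # first downward crossing of the midpoint, linearly interpolated
  x0 <- NA_real_
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] >= mid && y[i + 1L] < mid) {
      x0 <- x[i] + (y[i] - mid) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  if (!is.finite(x0)) x0 <- stats::median(x)
  dx0 <- diff(range(x)) / 10

  w <- NULL
  if (weights == "inv_var" && "sd" %in% names(df) &&
      all(is.finite(df$sd[keep])) && all(df$sd[keep] > 0)) {
    w <- 1 / df$sd[keep]^2
  }
  dat <- data.frame(x = x, y = y)
  # plateaus are percentages and the midpoint must lie inside the probed
  # voltage window; bounding the solver keeps noisy 13-point courses from
  # collapsing into degenerate optima
  args <- list(
    y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
    data = dat,
    start = list(A1 = a1, A2 = a2, x0 = x0, dx = dx0),
    lower = c(A1 = 0, A2 = 0, x0 = min(x), dx = 0.1),
    upper = c(A1 = 100, A2 = 100, x0 = max(x), dx = 10 * diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(w)) args$weights <- w
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  # normalize the sign ambiguity: (A1, A2, dx) and (A2, A1, -dx) give the
  # same curve; report the dissociation orientation (dx > 0, A1 >= A2)
  if (cf[["dx"]] < 0) {
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
    cf[["dx"]] <- -cf[["dx"]]
  }
  pred <- boltzmann_value(x, cf[["A1"]], cf[["A2"]], cf[["x0"]], cf[["dx"]])
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(
    list(A1 = unname(cf[["A1"]]), A2 = unname(cf[["A2"]]),
         x0 = unname(cf[["x0"]]), dx = unname(cf[["dx"]]),
         r2 = r2, slope = tangent_slope(cf[["A1"]], cf[["A2"]], cf[["dx"]]),
         excluded = exclude, covariance = covm, data = df,
         initial = df$fraction[which.min(df$dcv)],
         final = df$fraction[which.max(df$dcv)]),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit: A1 = %.2f%%, A2 = %.2f%%, x0 = %.1f V, dx = %.1f V\n",
    x$A1, x$A2, x$x0, x$dx))
  cat(sprintf("  slope %.2f %%/V, R^2 = %.4f, excluded points: %d\n",
              x$slope, x$r2, length(x$excluded)))
  invisible(x)
}

#' @export
print.boltzmann_nofit <- function(x, ...) {
  cat(sprintf("No dissociation transition (range %.2f pp): %s\n",
              x$range, x$reason))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dcv else newdata$dcv %||% newdata
  boltzmann_value(x, object$A1, object$A2, object$x0, object$dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate Boltzmann fits in course-characteristics layout
#'
#' @param fits Named list of `boltzmann_fit` / `boltzmann_nofit` objects.
#' @return data.frame with columns `peptide`, `initial`, `final`, `dcv50`,
#'   `dx`, `slope`, `r2` (NA for transition-free courses).
#' @export
course_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "boltzmann_fit")) {
      data.frame(peptide = nm, initial = f$initial, final = f$final,
                 dcv50 = f$x0, dx = f$dx, slope = f$slope, r2 = f$r2,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(peptide = nm,
                 initial = f$initial %||% NA_real_,
                 final = f$final %||% NA_real_,
                 dcv50 = NA_real_, dx = NA_real_, slope = NA_real_,
                 r2 = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
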