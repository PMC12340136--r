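#' Fit a DiFMU fluorescence standard curve
#'
#' Ordinary least-squares line of fluorescence against product concentration,
#' as used with the 0-100 uM DiFMU standards of the phosphatase activity
#' assay.
#'
#' @param standards Data.frame with columns `concentration_uM` and `value`
#'   (fluorescence), or a two-column numeric data.frame in that order.
#' @return A `standard_curve` object: `slope` (fluorescence per uM),
#'   `intercept`, `r2`, and the concentration `range` fitted.
#' @export
fit_standard_curve <- function(standards) {
  xy <- as_xy(standards)
  if (length(unique(xy$x)) < 2L) stop("need at least 2 distinct concentrations")
  fit <- stats::lm(y ~ x, data = xy)
  co <- stats::coef(fit)
  sstot <- sum((xy$y - mean(xy$y))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::resid(fit)^2) / sstot else 1
  structure(list(slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
                 r2 = r2, range = range(xy$x)),
            class = "standard_curve")
}

as_xy <- function(d) {
  if (all(c("concentration_uM", "value") %in% names(d))) {
    data.frame(x = d$concentration_uM, y = d$value)
  } else {
    stopifnot(ncol(d) >= 2)
    data.frame(x = d[[1]], y = d[[2]])
  }
}

#' Convert fluorescence to product concentration via a standard curve
#'
#' Inverts the line of best fit: `(fluorescence - intercept) / slope`.
#' Values outside the fitted standard range are flagged as extrapolated.
#'
#' @param fluorescence Numeric vector of fluorescence readings.
#' @param curve A [fit_standard_curve()] object.
#' @return Data.frame `fluorescence`, `concentration_uM`, `extrapolated`.
#' @export
interpolate_product <- function(fluorescence, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve slope is zero; cannot invert")
  conc <- (fluorescence - curve$intercept) / curve$slope
  # small guard so exact boundary values are not flagged by roundoff
  tol <- 1e-9 * max(1, diff(curve$range))
  data.frame(fluorescence = fluorescence, concentration_uM = conc,
             extrapolated = conc < curve$range[1] - tol |
                            conc > curve$range[2] + tol)
}

#' Fit a one-phase exponential decay dose-response
#'
#' Model `Y(c) = plateau + (y0 - plateau) * exp(-k * c)` for activity as a
#' function of inhibitor concentration, fitted by nonlinear least squares
#' with multi-start initialization: `k` from a log-spaced grid scaled to the
#' dose range, `y0`/`plateau` from the data extremes. Constraints `k >= 0`,
#' `plateau >= 0`. `r2 = 1 - SSres/SStot` about the mean (graphing-software
#' convention); constant data yield `r2 = 0`.
#'
#' @param points Data.frame with columns `concentration_uM` and `value`
#'   (activity), or two columns in that order. At least 4 points over at
#'   least 3 distinct concentrations.
#' @param n_starts Number of log-spaced `k` starting values (default 12).
#' @return A `decay_fit` object: `y0`, `plateau`, `k`, `r2`, `ss_res`,
#'   `fitted` (predictions at the data concentrations).
#' @export
fit_one_phase_decay <- function(points, n_starts = 12) {
  xy <- as_xy(points)
  if (nrow(xy) < 4L) stop("need at least 4 points")
  if (length(unique(xy$x)) < 3L) stop("need at least 3 distinct concentrations")
  sstot <- sum((xy$y - mean(xy$y))^2)

  if (sstot == 0) { # constant activity: degenerate flat fit
    return(structure(list(y0 = xy$y[1], plateau = xy$y[1], k = 0, r2 = 0,
                          ss_res = 0, fitted = xy$y), class = "decay_fit"))
  }

  xspan <- max(xy$x) - min(xy$x)
  kgrid <- 10^seq(log10(0.01 / xspan * 5), log10(100 / xspan * 5),
                  length.out = n_starts)
  y_at_min <- mean(xy$y[xy$x == min(xy$x)])
  y_at_max <- mean(xy$y[xy$x == max(xy$x)])

  best <- NULL
  best_ss <- Inf
  for (k0 in kgrid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ plateau + (y0 - plateau) * exp(-k * x),
        data = xy,
        start = list(y0 = y_at_min, plateau = max(y_at_max, 0), k = k0),
        lower = c(y0 = -Inf, plateau = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best)) {
    stop("one-phase decay fit failed to converge from all ", n_starts,
         " starts (best residual Inf)")
  }
  co <- stats::coef(best)
  pred <- stats::predict(best)
  structure(list(y0 = unname(co[["y0"]]), plateau = unname(co[["plateau"]]),
                 k = unname(co[["k"]]), r2 = 1 - best_ss / sstot,
                 ss_res = best_ss, fitted = as.numeric(pred)),
            class = "decay_fit")
}

#' Evaluate a one-phase decay model
#'
#' @param fit A `decay_fit` object (or list with `y0`, `plateau`, `k`).
#' @param concentration Numeric vector of concentrations.
#' @return Predicted activity values.
#' @export
predict_decay <- function(fit, concentration) {
  fit$plateau + (fit$y0 - fit$plateau) * exp(-fit$k * concentration)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("DiFMU standard curve: slope %.4g /uM, intercept %.4g, r2 %.4f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("One-phase decay: y0 %.4g, plateau %.4g, k %.4g /uM, r2 %.4f\n",
              x$y0, x$plateau, x$k, x$r2))
  invisible(x)
}
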