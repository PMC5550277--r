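# Nonlinear least squares for the first-order kinetics of the assays.
# All fits are unweighted; initial guesses are derived from the data
# (k from the half-rise/half-decay time, amplitude and offset from the range).

.fit_se <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  se
}

#' Fit a single-exponential buildup or decay, optionally with a linear term
#'
#' Model forms (t in the trace's time unit):
#' \describe{
#'   \item{buildup}{`y(t) = offset + amplitude * (1 - exp(-k t)) [+ slope t]`}
#'   \item{decay}{`y(t) = offset + amplitude * exp(-k t) [+ slope t]`}
#' }
#' The buildup form describes closure/FRET rise and product accumulation; the
#' decay form describes reopening. The optional linear term absorbs a slow
#' steady-state drift on top of the exponential phase.
#'
#' @param trace a [kinetic_trace()] with at least 4 points (5 with the linear
#'   term).
#' @param with_linear_term add a `slope * t` term.
#' @param direction `"buildup"` or `"decay"`.
#' @return an object of class `exp_fit`: coefficients (`offset`, `amplitude`,
#'   `k`, optionally `linear_slope`), standard errors, `rss`, `converged`,
#'   the model `direction` and the trace's `time_unit` (so `k` is per that
#'   unit).
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' tr <- kinetic_trace(t, 0.8 * (1 - exp(-0.16 * t)), "min", "delta_fret")
#' coef(fit_exponential(tr))
#' @export
fit_exponential <- function(trace, with_linear_term = FALSE,
                            direction = c("buildup", "decay")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  direction <- match.arg(direction)
  n_par <- 3L + as.integer(with_linear_term)
  tt <- trace$times
  y <- trace$values
  if (length(tt) < n_par + 1L)
    stop("need at least ", n_par + 1L, " points for this model", call. = FALSE)

  out <- list(direction = direction, with_linear_term = with_linear_term,
              time_unit = trace$time_unit, kind = trace$kind, n = length(tt))

  rng <- diff(range(y))
  if (rng <= 1e-12 * max(1, max(abs(y)))) {
    # no kinetics: amplitude 0, offset = mean, k unidentifiable -> 0
    cf <- c(offset = mean(y), amplitude = 0, k = 0)
    if (with_linear_term) cf <- c(cf, linear_slope = 0)
    out$coefficients <- cf
    out$se <- cf * 0
    out$rss <- sum((y - mean(y))^2)
    out$converged <- TRUE
    out$fitted <- rep(mean(y), length(y))
    return(structure(out, class = "exp_fit"))
  }

  t0 <- tt - tt[1]
  if (direction == "buildup") {
    off0 <- y[1]; amp0 <- y[length(y)] - y[1]
    half <- off0 + amp0 / 2
    ih <- if (amp0 >= 0) which(y >= half)[1] else which(y <= half)[1]
  } else {
    off0 <- y[length(y)]; amp0 <- y[1] - off0
    half <- off0 + amp0 / 2
    ih <- if (amp0 >= 0) which(y <= half)[1] else which(y >= half)[1]
  }
  th <- if (!is.na(ih) && t0[ih] > 0) t0[ih] else max(t0) / 4
  k0 <- log(2) / th

  fm <- if (direction == "buildup") {
    if (with_linear_term)
      y ~ offset + amplitude * (1 - exp(-k * t0)) + linear_slope * t0
    else y ~ offset + amplitude * (1 - exp(-k * t0))
  } else {
    if (with_linear_term)
      y ~ offset + amplitude * exp(-k * t0) + linear_slope * t0
    else y ~ offset + amplitude * exp(-k * t0)
  }
  start <- list(offset = off0, amplitude = amp0, k = k0)
  lower <- c(-Inf, -Inf, 0)
  if (with_linear_term) { start$linear_slope <- 0; lower <- c(lower, -Inf) }

  fit <- tryCatch(
    minpack.lm::nlsLM(fm, data = data.frame(y = y, t0 = t0), start = start,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    warning("exponential fit did not converge: ", conditionMessage(fit),
            call. = FALSE)
    cf <- unlist(start)
    out$coefficients <- cf
    out$se <- rep(NA_real_, length(cf))
    names(out$se) <- names(cf)
    out$rss <- NA_real_
    out$converged <- FALSE
    out$fitted <- rep(NA_real_, length(y))
    return(structure(out, class = "exp_fit"))
  }

  cf <- stats::coef(fit)
  out$coefficients <- cf
  out$se <- .fit_se(fit)
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- isTRUE(fit$convInfo$isConv)
  if (!out$converged)
    warning("optimizer reported non-convergence; parameters are reported anyway",
            call. = FALSE)
  out$fitted <- stats::fitted(fit)
  out$t_origin <- tt[1]
  structure(out, class = "exp_fit")
}

#' @export
coef.exp_fit <- function(object, ...) object$coefficients

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential %s fit%s (k per %s)%s\n", x$direction,
              if (x$with_linear_term) " + linear term" else "",
              x$time_unit, if (x$converged) "" else "  [NOT CONVERGED]"))
  m <- rbind(estimate = x$coefficients, std.error = x$se)
  print(m)
  cat(sprintf("rss = %g on %d points\n", x$rss, x$n))
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, times, ...) {
  cf <- as.list(object$coefficients)
  t0 <- times - (object$t_origin %||% times[1])
  base <- if (object$direction == "buildup")
    cf$offset + cf$amplitude * (1 - exp(-cf$k * t0))
  else cf$offset + cf$amplitude * exp(-cf$k * t0)
  if (object$with_linear_term) base <- base + cf$linear_slope * t0
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Hill equation to a titration
#'
#' `response = baseline + response_max * c^n / (half_max^n + c^n)`, the
#' standard cooperative binding isotherm used for ATP-induced closure
#' titrations. By definition the response at `c = half_max` is
#' `baseline + response_max / 2`.
#'
#' @param concentrations ligand concentrations (uM), non-negative, not all
#'   equal; at least 5 points.
#' @param responses signal at each concentration.
#' @return an object of class `hill_fit` with coefficients `baseline`,
#'   `response_max`, `half_max` (uM), `hill_n`, their standard errors, `rss`
#'   and `converged`.
#' @export
fit_hill <- function(concentrations, responses) {
  stopifnot(is.numeric(concentrations), is.numeric(responses),
            length(concentrations) == length(responses))
  if (length(concentrations) < 5L)
    stop("need at least 5 titration points", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (diff(range(concentrations)) == 0)
    stop("concentrations must not all be equal", call. = FALSE)
  rng <- diff(range(responses))
  if (rng <= 1e-12 * max(1, max(abs(responses))))
    stop("flat response: nothing to titrate against", call. = FALSE)

  ord <- order(concentrations)
  cc <- concentrations[ord]; rr <- responses[ord]
  base0 <- min(rr); rmax0 <- diff(range(rr))
  half <- base0 + rmax0 / 2
  ih <- which(rr >= half)[1]
  k0 <- if (!is.na(ih) && cc[ih] > 0) cc[ih] else stats::median(cc[cc > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      rr ~ baseline + response_max * cc^hill_n / (half_max^hill_n + cc^hill_n),
      start = list(baseline = base0, response_max = rmax0,
                   half_max = k0, hill_n = 1),
      lower = c(-Inf, -Inf, .Machine$double.eps, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Hill fit failed: ", conditionMessage(fit), call. = FALSE)

  structure(list(coefficients = stats::coef(fit), se = .fit_se(fit),
                 rss = sum(stats::resid(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 n = length(cc)),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit%s\n", if (x$converged) "" else "  [NOT CONVERGED]"))
  print(rbind(estimate = x$coefficients, std.error = x$se))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, concentrations, ...) {
  cf <- as.list(object$coefficients)
  cf$baseline + cf$response_max * concentrations^cf$hill_n /
    (cf$half_max^cf$hill_n + concentrations^cf$hill_n)
}

#' Initial rate from the linear regime of a kinetic trace
#'
#' Finds the longest prefix of the trace whose linear fit has
#' `R^2 >= r2_threshold` (at least `min_points` long) and reports its slope.
#' This encodes "slope within the linear regime" as an explicit, reproducible
#' rule. If no prefix qualifies, the first `min_points` points are used with
#' a warning.
#'
#' @param trace a [kinetic_trace()].
#' @param r2_threshold minimum R-squared for a prefix to count as linear.
#' @param min_points smallest admissible window.
#' @return an object of class `initial_rate` with `slope` (signal per time
#'   unit), `se`, `window` (index range used), `r2` and the units involved.
#' @export
initial_rate <- function(trace, r2_threshold = 0.995, min_points = 5L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n <- length(trace$times)
  if (n < min_points)
    stop("trace shorter than min_points", call. = FALSE)
  tt <- trace$times; y <- trace$values

  best <- NA_integer_
  for (m in seq.int(min_points, n)) {
    ti <- tt[1:m]; yi <- y[1:m]
    f <- stats::lm.fit(cbind(1, ti), yi)
    rss <- sum(f$residuals^2)
    tss <- sum((yi - mean(yi))^2)
    r2 <- if (tss <= .Machine$double.eps * max(1, sum(yi^2))) 1 else 1 - rss / tss
    if (r2 >= r2_threshold) best <- m
  }
  if (is.na(best)) {
    warning("no prefix reached R^2 >= ", r2_threshold,
            "; falling back to the first ", min_points, " points",
            call. = FALSE)
    best <- min_points
  }
  fit <- stats::lm(y[1:best] ~ tt[1:best])
  sm <- summary(fit)$coefficients
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y[1:best] - mean(y[1:best]))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = unname(sm[2, "Std. Error"]),
                 intercept = unname(stats::coef(fit)[1]),
                 window = c(1L, best),
                 r2 = if (tss == 0) 1 else 1 - rss / tss,
                 signal_kind = trace$kind, time_unit = trace$time_unit),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("initial rate: %g +/- %g %s per %s (points %d..%d, R^2 = %.4f)\n",
              x$slope, x$se, x$signal_kind, x$time_unit,
              x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' Phosphate-sensor standard curve with a detector-linearity cap
#'
#' Fits `RFU = intercept + slope * [Pi]` by least squares to standards whose
#' fluorescence lies strictly below the detector linearity cap; points at or
#' above the cap are excluded from the fit and reported. Applying the
#' calibration inverts the line to convert a raw fluorescence trace to
#' phosphate concentration.
#'
#' @param pi_concentrations standard phosphate concentrations (uM).
#' @param rfu measured fluorescence for each standard.
#' @param linear_cap detector-linearity limit in RFU; default 20000.
#' @return an object of class `phosphate_calibration` with `slope`
#'   (RFU per uM), `intercept` (RFU at zero phosphate), `linear_cap`,
#'   `points_used` and the indices of excluded standards.
#' @export
fit_phosphate_calibration <- function(pi_concentrations, rfu,
                                      linear_cap = 20000) {
  stopifnot(is.numeric(pi_concentrations), is.numeric(rfu),
            length(pi_concentrations) == length(rfu))
  keep <- rfu < linear_cap
  if (sum(keep) < 3L)
    stop("need at least 3 standards below the linearity cap", call. = FALSE)
  fit <- stats::lm(rfu[keep] ~ pi_concentrations[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 se = c(intercept = unname(sm[1, "Std. Error"]),
                        slope = unname(sm[2, "Std. Error"])),
                 linear_cap = linear_cap, points_used = sum(keep),
                 excluded = which(!keep)),
            class = "phosphate_calibration")
}

#' @export
print.phosphate_calibration <- function(x, ...) {
  cat(sprintf("phosphate calibration: RFU = %.4g + %.4g * [Pi uM] (cap %g RFU, %d points used, %d excluded)\n",
              x$intercept, x$slope, x$linear_cap, x$points_used,
              length(x$excluded)))
  invisible(x)
}

#' @rdname fit_phosphate_calibration
#' @param cal a `phosphate_calibration`.
#' @param trace a raw fluorescence [kinetic_trace()] (kind `"rfu"`). Values at
#'   or above the cap are outside the detector's linear range and are set to
#'   `NA` with a warning.
#' @return [apply_calibration()] returns a [kinetic_trace()] of kind
#'   `"concentration_uM"`.
#' @export
apply_calibration <- function(cal, trace) {
  stopifnot(inherits(cal, "phosphate_calibration"),
            inherits(trace, "kinetic_trace"))
  if (trace$kind != "rfu")
    stop("calibration applies to raw fluorescence (kind 'rfu') traces",
         call. = FALSE)
  v <- trace$values
  over <- v >= cal$linear_cap
  conc <- (v - cal$intercept) / cal$slope
  if (any(over)) {
    warning(sum(over), " point(s) at or above the linearity cap set to NA",
            call. = FALSE)
    conc[over] <- NA_real_
  }
  kinetic_trace(trace$times, conc, time_unit = trace$time_unit,
                kind = "concentration_uM", label = trace$label)
}

#' Convert an NADH-coupled absorbance slope to an ATPase rate
#'
#' In the enzyme-coupled assay each ATP hydrolyzed consumes one NADH, whose
#' disappearance is followed by absorbance; Beer-Lambert then gives
#' `rate = |slope| / (extinction * pathlength)`, reported positive in uM per
#' the slope's time unit.
#'
#' @param slope absorbance change per time unit (negative for NADH loss).
#' @param pathlength_cm optical path length in cm (> 0).
#' @param extinction molar extinction coefficient of NADH at 340 nm in
#'   M^-1 cm^-1; the standard value 6220 is the default.
#' @return rate in uM per the slope's time unit.
#' @examples
#' nadh_slope_to_atpase(-0.00622, 1) # 1 uM/min for a per-minute slope
#' @export
nadh_slope_to_atpase <- function(slope, pathlength_cm, extinction = 6220) {
  if (!is.numeric(pathlength_cm) || pathlength_cm <= 0)
    stop("pathlength must be positive", call. = FALSE)
  stopifnot(is.numeric(slope), extinction > 0)
  abs(slope) / (extinction * pathlength_cm) * 1e6
}
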