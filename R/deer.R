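# Two-conformer decomposition of DEER distance distributions.
#
# The artifact starts from P(r) (the output of dipolar-signal processing);
# the buckled and straight conformers of the closed dimer produce two peaks
# (~22 A and ~41 A for the MD:CTD label pair used here) modeled as a
# two-component Gaussian mixture.

#' Normalized distance distribution on a uniform r-grid
#'
#' @param r strictly increasing, uniformly spaced distances in A.
#' @param p non-negative densities; renormalized to trapezoidal integral 1
#'   when `normalize = TRUE`, otherwise required to integrate to 1 within
#'   1e-6.
#' @param normalize renormalize instead of validating.
#' @return an object of class `distance_distribution`.
#' @export
distance_distribution <- function(r, p, normalize = FALSE) {
  r <- as.numeric(r); p <- as.numeric(p)
  stopifnot(length(r) == length(p), length(r) >= 10L)
  dr <- diff(r)
  if (any(dr <= 0)) stop("r must be strictly increasing", call. = FALSE)
  if (diff(range(dr)) > 1e-6 * mean(dr))
    stop("r grid must be uniformly spaced", call. = FALSE)
  if (any(p < 0)) {
    if (normalize) p <- pmax(p, 0)
    else stop("densities must be non-negative", call. = FALSE)
  }
  integ <- sum((p[-1] + p[-length(p)]) / 2 * dr)
  if (normalize) {
    if (integ <= 0) stop("cannot normalize an all-zero density", call. = FALSE)
    p <- p / integ
  } else if (abs(integ - 1) > 1e-6) {
    stop("density must integrate to 1 within 1e-6 (got ", signif(integ, 6),
         "); use normalize = TRUE", call. = FALSE)
  }
  structure(list(r = r, p = p), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance distribution: %d points on [%g, %g] A\n",
              length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, fit = NULL, ...) {
  graphics::plot(x$r, x$p, type = "l", xlab = "r (A)", ylab = "P(r)", ...)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "two_state_fit"))
    graphics::lines(x$r, predict(fit, x$r), col = 2, lty = 2)
  }
  invisible(x)
}

#' @rdname distance_distribution
#' @param file CSV with columns `r_angstrom,p`.
#' @export
read_pr_csv <- function(file, normalize = TRUE) {
  d <- utils::read.csv(file)
  if (!all(c("r_angstrom", "p") %in% names(d)))
    stop("P(r) CSV needs columns r_angstrom,p", call. = FALSE)
  distance_distribution(d$r_angstrom, d$p, normalize = normalize)
}

#' @rdname distance_distribution
#' @param dist a `distance_distribution`.
#' @export
write_pr_csv <- function(dist, file) {
  stopifnot(inherits(dist, "distance_distribution"))
  utils::write.csv(data.frame(r_angstrom = dist$r, p = dist$p), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

.find_two_peaks <- function(r, p, min_sep = 5) {
  n <- length(p)
  loc <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  if (!length(loc)) loc <- which.max(p)
  loc <- loc[order(p[loc], decreasing = TRUE)]
  first <- loc[1]
  second <- loc[abs(r[loc] - r[first]) >= min_sep][1]
  if (is.na(second)) {
    # unimodal: seed the second component off-peak toward the heavier tail
    side <- if (sum(p[r > r[first]]) > sum(p[r < r[first]])) 1 else -1
    return(c(r[first], r[first] + side * max(min_sep, diff(range(r)) / 4)))
  }
  sort(c(r[first], r[second]))
}

#' Fit a two-Gaussian mixture to a distance distribution
#'
#' Least squares on the grid for
#' `P(r) = w N(mu1, sigma1) + (1 - w) N(mu2, sigma2)`, initialized from the
#' two highest well-separated local maxima. Component order is fixed
#' post-fit (`mu1 <= mu2`) and the weights live on the simplex by
#' construction. Centers closer than 2 A are flagged degenerate (a
#' effectively unimodal distribution).
#'
#' @param dist a [distance_distribution()] with at least 50 grid points.
#' @param init optional named list of starting values (`mu1`, `mu2`,
#'   `sigma1`, `sigma2`, `w1`).
#' @return an object of class `two_state_fit`: `centers` (A, ascending),
#'   `widths` (A), `weights` (sum 1), `se`, `rss`, `converged`,
#'   `degenerate`.
#' @export
fit_two_gaussians <- function(dist, init = NULL) {
  stopifnot(inherits(dist, "distance_distribution"))
  r <- dist$r; p <- dist$p
  if (length(r) < 50L)
    stop("grid too coarse: need >= 50 points across the support",
         call. = FALSE)
  pk <- .find_two_peaks(r, p)
  span <- diff(range(r))
  dr <- r[2] - r[1]
  # distribution moments, used by the fallback split-peak initialization
  mass <- sum(p) * dr
  m1 <- sum(r * p) * dr / mass
  sd1 <- sqrt(max(sum((r - m1)^2 * p) * dr / mass, dr^2))
  starts <- list(
    list(mu1 = pk[1], mu2 = pk[2], sigma1 = span / 15, sigma2 = span / 15,
         w1 = 0.5),
    list(mu1 = m1 - 0.7 * sd1, mu2 = m1 + 0.7 * sd1,
         sigma1 = 0.7 * sd1, sigma2 = 0.7 * sd1, w1 = 0.5))
  if (!is.null(init)) {
    s0 <- starts[[1]]; s0[names(init)] <- init
    starts <- c(list(s0), starts)
  }
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ w1 * stats::dnorm(r, mu1, sigma1) +
          (1 - w1) * stats::dnorm(r, mu2, sigma2),
        start = start,
        lower = c(min(r), min(r), dr / 2, dr / 2, 0),
        upper = c(max(r), max(r), span, span, 1),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    stop("two-Gaussian fit failed: ", conditionMessage(fit), call. = FALSE)
  cf <- stats::coef(fit)
  se <- .fit_se(fit)
  centers <- c(cf[["mu1"]], cf[["mu2"]])
  widths <- c(cf[["sigma1"]], cf[["sigma2"]])
  weights <- c(cf[["w1"]], 1 - cf[["w1"]])
  se_centers <- c(se[["mu1"]], se[["mu2"]])
  se_widths <- c(se[["sigma1"]], se[["sigma2"]])
  se_w <- rep(se[["w1"]], 2)
  if (centers[1] > centers[2]) {
    centers <- rev(centers); widths <- rev(widths); weights <- rev(weights)
    se_centers <- rev(se_centers); se_widths <- rev(se_widths)
  }
  structure(list(centers = centers, widths = widths, weights = weights,
                 se = list(centers = se_centers, widths = se_widths,
                           weights = se_w),
                 rss = sum(stats::resid(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 degenerate = abs(diff(centers)) < 2),
            class = "two_state_fit")
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(mu1 = object$centers[1], mu2 = object$centers[2],
    sigma1 = object$widths[1], sigma2 = object$widths[2],
    w1 = object$weights[1], w2 = object$weights[2])
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("two-Gaussian conformer fit%s%s\n",
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$degenerate) "  [DEGENERATE: centers within 2 A]" else ""))
  cat(sprintf("  component 1: center %.2f A, width %.2f A, weight %.3f\n",
              x$centers[1], x$widths[1], x$weights[1]))
  cat(sprintf("  component 2: center %.2f A, width %.2f A, weight %.3f\n",
              x$centers[2], x$widths[2], x$weights[2]))
  invisible(x)
}

#' @export
predict.two_state_fit <- function(object, r, ...) {
  object$weights[1] * stats::dnorm(r, object$centers[1], object$widths[1]) +
    object$weights[2] * stats::dnorm(r, object$centers[2], object$widths[2])
}

#' Assign mixture components to the buckled and straight conformers
#'
#' Each fitted component is assigned to the nearer of the two reference
#' distances; the conformer fractions are the component weights. The default
#' references are the two observed MD:CTD spin-label peaks (22 A buckled,
#' 41 A straight); both are overridable since label-linker offsets shift
#' absolute distances.
#'
#' @param fit a [fit_two_gaussians()] result (non-degenerate).
#' @param ref_buckled,ref_straight reference distances in A.
#' @return list with `f_buckled`, `f_straight`, the component-to-conformer
#'   `assignment`, and an `ambiguous` flag (both components nearer the same
#'   reference).
#' @export
conformer_fractions <- function(fit, ref_buckled = 22, ref_straight = 41) {
  stopifnot(inherits(fit, "two_state_fit"))
  if (fit$degenerate)
    stop("degenerate fit: conformer fractions are undefined", call. = FALSE)
  nearer <- ifelse(abs(fit$centers - ref_buckled) <=
                     abs(fit$centers - ref_straight), "buckled", "straight")
  if (nearer[1] == nearer[2]) {
    warning("ambiguous assignment: both components nearer the ", nearer[1],
            " reference", call. = FALSE)
    return(list(f_buckled = NA_real_, f_straight = NA_real_,
                assignment = nearer, ambiguous = TRUE))
  }
  list(f_buckled = fit$weights[nearer == "buckled"],
       f_straight = fit$weights[nearer == "straight"],
       assignment = nearer, ambiguous = FALSE)
}
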