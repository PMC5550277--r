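# Time units are never implicit anywhere in the package: every trace and rate
# carries its unit and conversions are explicit operations.

.TIME_SECONDS <- c(s = 1, min = 60, hr = 3600, day = 86400)

.check_time_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% names(.TIME_SECONDS))
    stop("time unit must be one of: ", paste(names(.TIME_SECONDS), collapse = ", "),
         call. = FALSE)
  unit
}

#' Convert a time value between units
#'
#' @param x numeric time value(s).
#' @param from,to source and target units, one of `"s"`, `"min"`, `"hr"`, `"day"`.
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_time(1485.5, "hr", "day") # ~61.9 days
#' @export
convert_time <- function(x, from, to) {
  .check_time_unit(from); .check_time_unit(to)
  x * .TIME_SECONDS[[from]] / .TIME_SECONDS[[to]]
}

#' Convert a first-order rate constant between time units
#'
#' A rate in `from^-1` becomes a rate in `to^-1`.
#'
#' @inheritParams convert_time
#' @return rate expressed per `to` unit.
#' @export
convert_rate <- function(x, from, to) {
  .check_time_unit(from); .check_time_unit(to)
  x * .TIME_SECONDS[[to]] / .TIME_SECONDS[[from]]
}

#' Rate constant with declared unit and per-site/per-dimer basis
#'
#' @param value non-negative rate value.
#' @param unit time unit of the reciprocal (e.g. `"hr"` for a per-hour rate).
#' @param basis `"per_site"`, `"per_dimer"`, or `"none"`.
#' @return an object of class `rate_constant`.
#' @examples
#' rate_constant(0.5808, "hr", "per_site")
#' @export
rate_constant <- function(value, unit = "hr", basis = c("none", "per_site", "per_dimer")) {
  basis <- match.arg(basis)
  .check_time_unit(unit)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value < 0) stop("rate constant must be >= 0", call. = FALSE)
  structure(list(value = value, unit = unit, basis = basis),
            class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("rate constant: %g %s^-1 (%s)\n", x$value, x$unit, x$basis))
  invisible(x)
}

#' Convert a rate constant between per-site and per-dimer bases
#'
#' The dimer carries `sites_per_dimer` active sites, so the per-dimer rate is
#' the per-site rate times the number of sites; the inverse direction divides.
#' The time unit is preserved and the conversion is an exact involution.
#'
#' @param rate a [rate_constant()] with basis `"per_site"` or `"per_dimer"`.
#' @param sites_per_dimer number of active sites per dimer (2 for Hsp90-family
#'   homodimers).
#' @return a [rate_constant()] on the other basis.
#' @examples
#' convert_rate_basis(rate_constant(0.5808, "hr", "per_site")) # 1.1616 per dimer
#' @export
convert_rate_basis <- function(rate, sites_per_dimer = 2) {
  stopifnot(inherits(rate, "rate_constant"))
  if (rate$basis == "none")
    stop("basis conversions are only defined between per_site and per_dimer",
         call. = FALSE)
  stopifnot(sites_per_dimer > 0)
  if (rate$basis == "per_site")
    rate_constant(rate$value * sites_per_dimer, rate$unit, "per_dimer")
  else
    rate_constant(rate$value / sites_per_dimer, rate$unit, "per_site")
}

#' Time for a first-order process to reach a given converted fraction
#'
#' For an exponential decay/consumption with rate constant `k`, the time at
#' which a fraction `f` of the substrate has reacted is `t = -ln(1 - f) / k`,
#' so e.g. t90 = ln(10)/k.
#'
#' @param k a [rate_constant()] (or a bare positive number, interpreted in
#'   `unit`).
#' @param fraction converted fraction, strictly between 0 and 1 (0.9 gives
#'   the t90).
#' @param unit time unit when `k` is given as a bare number.
#' @return time in the rate constant's time unit, with a `"unit"` attribute.
#' @examples
#' t_fraction(rate_constant(0.00155, "hr"), 0.9) # 1485.5 hr, i.e. ~62 days
#' @export
t_fraction <- function(k, fraction = 0.9, unit = "hr") {
  if (inherits(k, "rate_constant")) {
    unit <- k$unit
    k <- k$value
  }
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k <= 0) stop("t_fraction requires k > 0", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  structure(-log(1 - fraction) / k, unit = unit)
}

#' Report a duration as a rounded whole number of some unit
#'
#' Presentation helper: converts and rounds (half-to-even, the base R
#' convention) to the nearest integer. Never used inside computations.
#'
#' @param t duration carrying a `"unit"` attribute (as returned by
#'   [t_fraction()]) or a bare number in `from`.
#' @param to target unit.
#' @param from source unit when `t` has no unit attribute.
#' @return integer number of `to` units.
#' @examples
#' report_duration(t_fraction(rate_constant(0.5808, "hr"), 0.9), "hr") # 4
#' @export
report_duration <- function(t, to, from = NULL) {
  u <- attr(t, "unit")
  if (is.null(u)) u <- from
  if (is.null(u)) stop("source unit unknown; supply `from`", call. = FALSE)
  as.integer(round(convert_time(as.numeric(t), u, to)))
}
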