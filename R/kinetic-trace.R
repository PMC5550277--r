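.TRACE_KINDS <- c("fret_ratio", "delta_fret", "rfu", "absorbance",
                  "fraction_hydrolyzed", "concentration_uM")

#' Timestamped assay signal with declared units
#'
#' The common currency of all kinetic fitting: an ordered time series with an
#' explicit time unit and signal kind (FRET ratio, raw fluorescence,
#' absorbance, hydrolyzed fraction, or concentration).
#'
#' @param times strictly increasing numeric time points.
#' @param values numeric signal values, same length as `times`.
#' @param time_unit one of `"s"`, `"min"`, `"hr"`, `"day"`.
#' @param kind signal kind, one of `r paste0('\x60', .TRACE_KINDS, '\x60', collapse = ", ")`.
#' @param label free-text label carried through analyses.
#' @return an object of class `kinetic_trace` (list with `times`, `values`,
#'   `time_unit`, `kind`, `label`).
#' @export
kinetic_trace <- function(times, values, time_unit = "min",
                          kind = "rfu", label = "") {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (length(times) < 2L)
    stop("a trace needs at least 2 points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  .check_time_unit(time_unit)
  kind <- match.arg(kind, .TRACE_KINDS)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 time_unit = time_unit, kind = kind,
                 label = as.character(label)[1]),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("kinetic trace%s: %d points over [%g, %g] %s, signal = %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), min(x$times), max(x$times),
              x$time_unit, x$kind))
  invisible(x)
}

#' @export
length.kinetic_trace <- function(x) length(x$times)

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  out <- data.frame(time = x$times, value = x$values)
  names(out) <- c(paste0("time_", x$time_unit), paste0("value_", x$kind))
  out
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$times, x$values,
                 xlab = paste0("time (", x$time_unit, ")"),
                 ylab = x$kind, main = x$label, ...)
  invisible(x)
}

#' Read and write kinetic traces as CSV
#'
#' The on-disk format is a two-column UTF-8 CSV with '.' decimal separator and
#' a mandatory header `time_<unit>,value_<kind>` encoding the units, e.g.
#' `time_min,value_rfu`.
#'
#' @param file path to a CSV file.
#' @param label optional label attached on read.
#' @return [read_trace_csv()] returns a [kinetic_trace()];
#'   [write_trace_csv()] invisibly returns `file`.
#' @export
read_trace_csv <- function(file, label = "") {
  d <- utils::read.csv(file, check.names = FALSE)
  if (ncol(d) < 2L) stop("trace CSV needs two columns", call. = FALSE)
  nm <- names(d)[1:2]
  tm <- regmatches(nm[1], regexec("^time_(s|min|hr|day)$", nm[1]))[[1]]
  vm <- regmatches(nm[2], regexec("^value_([a-zA-Z_]+)$", nm[2]))[[1]]
  if (length(tm) < 2L || length(vm) < 2L)
    stop("header must be time_<unit>,value_<kind>; got: ",
         paste(nm, collapse = ","), call. = FALSE)
  kinetic_trace(d[[1]], d[[2]], time_unit = tm[2], kind = vm[2], label = label)
}

#' @rdname read_trace_csv
#' @param trace a [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, file) {
  stopifnot(inherits(trace, "kinetic_trace"))
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' FRET ratio change relative to time zero
#'
#' The relative FRET efficiency is the ratio of acceptor to donor intensity;
#' the reported change in FRET is that ratio minus its value at the first
#' time point, so every output trace starts at exactly 0 and is invariant
#' under a common rescaling of both channels.
#'
#' @param donor,acceptor [kinetic_trace()]s on identical time grids; donor
#'   values must be strictly positive.
#' @return a [kinetic_trace()] of kind `"delta_fret"`.
#' @export
fret_ratio_trace <- function(donor, acceptor) {
  stopifnot(inherits(donor, "kinetic_trace"), inherits(acceptor, "kinetic_trace"))
  if (length(donor$times) != length(acceptor$times) ||
      any(donor$times != acceptor$times) || donor$time_unit != acceptor$time_unit)
    stop("donor and acceptor must share an identical time grid", call. = FALSE)
  if (any(donor$values <= 0))
    stop("donor values must be strictly positive", call. = FALSE)
  ratio <- acceptor$values / donor$values
  kinetic_trace(donor$times, ratio - ratio[1], time_unit = donor$time_unit,
                kind = "delta_fret",
                label = paste0(donor$label, if (nzchar(donor$label)) " " else "",
                               "delta FRET"))
}
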