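# Binomial deconvolution of dimer-exchange mixing experiments.
#
# Mixing wild-type and hydrolysis-dead subunits at total fraction f of
# wild type and letting dimers re-assort gives binomial species fractions
# f^2 : (1-f)^2 : 2f(1-f) for WT:WT, mut:mut and heterodimer. The total
# steady-state activity is the species-weighted sum; with the WT and mutant
# homodimer activities anchored at f = 1 and f = 0, the heterodimer activity
# is the single remaining parameter and the fit is linear in it.

#' Binomial dimer species fractions at a given wild-type subunit fraction
#'
#' @param f_wildtype wild-type subunit fraction(s) in \[0, 1\].
#' @return data frame with columns `p_ww = f^2`, `p_mm = (1-f)^2`,
#'   `p_het = 2 f (1-f)`; the three sum to 1 exactly.
#' @export
species_fractions <- function(f_wildtype) {
  f <- as.numeric(f_wildtype)
  if (any(f < 0 | f > 1)) stop("f_wildtype must lie in [0, 1]", call. = FALSE)
  data.frame(f_wildtype = f, p_ww = f^2, p_mm = (1 - f)^2,
             p_het = 2 * f * (1 - f))
}

#' Total activity of a binomially re-assorted dimer mixture
#'
#' Default convention weights the heterodimer by its binomial species
#' fraction `2 f (1-f)`; `include_factor_two = FALSE` gives the literal
#' weight `f (1-f)` instead (the two conventions differ only in the scale on
#' which the heterodimer activity is expressed). The default is the one
#' consistent with the independence construction, where a heterodimer whose
#' sites act independently has activity `(v_wt + v_mut)/2` and the total
#' becomes exactly linear in `f`.
#'
#' @param f_wildtype wild-type subunit fraction(s) in \[0, 1\].
#' @param v_wt,v_mut,v_het activities of the wild-type homodimer, mutant
#'   homodimer and heterodimer (per total dimer).
#' @param include_factor_two use the binomial factor 2 on the heterodimer
#'   term (default) or the literal `f (1-f)` weight.
#' @return total activity at each `f_wildtype`.
#' @export
total_activity <- function(f_wildtype, v_wt, v_mut, v_het,
                           include_factor_two = TRUE) {
  sf <- species_fractions(f_wildtype)
  het_w <- if (include_factor_two) sf$p_het else sf$p_het / 2
  v_wt * sf$p_ww + v_mut * sf$p_mm + v_het * het_w
}

#' Expected mixture activity if the two sites act independently
#'
#' If each protomer hydrolyzes independently the heterodimer activity is the
#' average of the two homodimer activities and the total reduces to the
#' straight line `v_wt * f + v_mut * (1 - f)`.
#'
#' @inheritParams total_activity
#' @return expected activity at each `f_wildtype`.
#' @export
independent_expectation <- function(f_wildtype, v_wt, v_mut) {
  f <- as.numeric(f_wildtype)
  if (any(f < 0 | f > 1)) stop("f_wildtype must lie in [0, 1]", call. = FALSE)
  v_wt * f + v_mut * (1 - f)
}

#' Mixing-ratio activity table
#'
#' @param f_wildtype wild-type subunit fractions in \[0, 1\] (at least 3
#'   distinct values for fitting).
#' @param v_total measured total activity at each mixing ratio.
#' @param sd optional replicate standard deviations.
#' @return an object of class `mix_table` (a data frame).
#' @export
mix_table <- function(f_wildtype, v_total, sd = NULL) {
  f <- as.numeric(f_wildtype)
  if (any(f < 0 | f > 1)) stop("f_wildtype must lie in [0, 1]", call. = FALSE)
  stopifnot(length(f) == length(v_total))
  if (length(unique(f)) < 3L)
    stop("need at least 3 distinct mixing ratios", call. = FALSE)
  d <- data.frame(f_wildtype = f, v_total = as.numeric(v_total))
  if (!is.null(sd)) d$sd <- as.numeric(sd)
  class(d) <- c("mix_table", "data.frame")
  d
}

#' @rdname mix_table
#' @param file path to a CSV file with columns `f_wildtype,v_total[,sd]`.
#' @export
read_mix_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("f_wildtype", "v_total") %in% names(d)))
    stop("mixing CSV needs columns f_wildtype,v_total", call. = FALSE)
  mix_table(d$f_wildtype, d$v_total, sd = d$sd)
}

#' @rdname mix_table
#' @param table a `mix_table`.
#' @export
write_mix_csv <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Solve a mixing table for the heterodimer activity
#'
#' One-parameter unweighted least squares: with `v_wt` and `v_mut` fixed from
#' the pure end points, the residual `v_total - v_wt f^2 - v_mut (1-f)^2` is
#' linear in `v_het` with regressor `2 f (1-f)` (default convention), so the
#' estimate and its standard error are closed-form. The result also reports
#' whether the heterodimer falls below the independence value
#' `(v_wt + v_mut)/2` (sub-additivity: both ATPs must turn over for
#' efficient cycling).
#'
#' @param table a [mix_table()] containing interior mixing ratios.
#' @param v_wt,v_mut fixed homodimer activities (measured anchors at
#'   `f = 1` and `f = 0`).
#' @inheritParams total_activity
#' @return an object of class `mix_fit` with `v_het`, its standard error,
#'   `rss`, the fixed anchors, the convention flag, the independence value
#'   and a `sub_additive` flag.
#' @export
fit_heterodimer_activity <- function(table, v_wt, v_mut,
                                     include_factor_two = TRUE) {
  stopifnot(inherits(table, "mix_table"))
  f <- table$f_wildtype
  y <- table$v_total
  interior <- f > 0 & f < 1
  if (!any(interior))
    stop("mixing table has no interior points; v_het is unidentifiable",
         call. = FALSE)
  g <- if (include_factor_two) 2 * f * (1 - f) else f * (1 - f)
  resid0 <- y - v_wt * f^2 - v_mut * (1 - f)^2
  v_het <- sum(g * resid0) / sum(g^2)
  r <- resid0 - v_het * g
  rss <- sum(r^2)
  dof <- length(y) - 1L
  se <- sqrt(rss / dof / sum(g^2))
  indep <- (v_wt + v_mut) / 2
  # on the literal (no factor 2) scale the independence value doubles
  if (!include_factor_two) indep <- indep * 2
  structure(list(v_het = v_het, se = se, rss = rss,
                 v_wt = v_wt, v_mut = v_mut,
                 include_factor_two = include_factor_two,
                 independence_value = indep,
                 sub_additive = v_het < indep,
                 n = length(y)),
            class = "mix_fit")
}

#' @export
coef.mix_fit <- function(object, ...) {
  c(v_wt = object$v_wt, v_mut = object$v_mut, v_het = object$v_het)
}

#' @export
print.mix_fit <- function(x, ...) {
  cat(sprintf("binomial mixing fit (%s convention)\n",
              if (x$include_factor_two) "binomial-weight" else "literal"))
  cat(sprintf("  v_wt  = %g (fixed)\n  v_mut = %g (fixed)\n", x$v_wt, x$v_mut))
  cat(sprintf("  v_het = %g +/- %g\n", x$v_het, x$se))
  cat(sprintf("  independence value = %g -> heterodimer is %s\n",
              x$independence_value,
              if (x$sub_additive) "sub-additive" else "not sub-additive"))
  invisible(x)
}

#' @export
predict.mix_fit <- function(object, f_wildtype, ...) {
  total_activity(f_wildtype, object$v_wt, object$v_mut, object$v_het,
                 include_factor_two = object$include_factor_two)
}
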