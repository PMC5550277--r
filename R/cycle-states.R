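# The dimer ATPase cycle as a finite labeled state machine.
#
# A dimer state is (conformation, nucleotide on protomer 1, nucleotide on
# protomer 2, buckled protomer). The cycle is: ATP-saturated closure with
# random buckling -> hydrolysis by the buckled protomer -> Pi-release-driven
# flip of the asymmetry -> hydrolysis of the second ATP by the newly buckled
# protomer -> reopening from the ADP/ADP state. Protomer-specific variants
# remove hydrolysis edges (hydrolysis-dead, e.g. E115A) or pin a protomer to
# the straight conformation (gamma-sensor broken, e.g. R402A, an ADP-state
# mimic).

#' Protomer specification for cycle variants
#'
#' @param hydrolysis_competent `FALSE` models an active-site mutation that
#'   binds but cannot hydrolyze ATP (E115A-like).
#' @param gamma_sensor_intact `FALSE` models loss of the gamma-phosphate
#'   sensing arginine (R402A/R417A-like): the protomer is pinned to the
#'   straight, ADP-like conformation and can never buckle.
#' @param labeled carries the conformational reporter (at most one protomer
#'   per dimer) used by [buckled_fraction()].
#' @return an object of class `protomer_spec`.
#' @export
protomer_spec <- function(hydrolysis_competent = TRUE,
                          gamma_sensor_intact = TRUE,
                          labeled = FALSE) {
  structure(list(hydrolysis_competent = isTRUE(hydrolysis_competent),
                 gamma_sensor_intact = isTRUE(gamma_sensor_intact),
                 labeled = isTRUE(labeled)),
            class = "protomer_spec")
}

#' Dimer variant: a pair of protomer specifications
#'
#' @param p1,p2 [protomer_spec()]s for the two protomers.
#' @return an object of class `dimer_variant` with vectors
#'   `hydrolysis_competent`, `gamma_sensor_intact`, `labeled` (length 2).
#' @export
dimer_variant <- function(p1 = protomer_spec(), p2 = protomer_spec()) {
  stopifnot(inherits(p1, "protomer_spec"), inherits(p2, "protomer_spec"))
  v <- list(hydrolysis_competent = c(p1$hydrolysis_competent,
                                     p2$hydrolysis_competent),
            gamma_sensor_intact = c(p1$gamma_sensor_intact,
                                    p2$gamma_sensor_intact),
            labeled = c(p1$labeled, p2$labeled))
  if (sum(v$labeled) > 1L)
    stop("at most one protomer may carry the conformational label",
         call. = FALSE)
  if (!any(v$gamma_sensor_intact))
    stop("both protomers pinned straight: no closed state is possible",
         call. = FALSE)
  structure(v, class = "dimer_variant")
}

#' @rdname dimer_variant
#' @param labeled_protomer index (1 or 2) of the labeled protomer, or 0 for
#'   none.
#' @export
variant_wildtype <- function(labeled_protomer = 1) {
  dimer_variant(protomer_spec(labeled = labeled_protomer == 1),
                protomer_spec(labeled = labeled_protomer == 2))
}

#' @rdname dimer_variant
#' @details `variant_hemi_dead()` is the +/E115A-like heterodimer: protomer 2
#'   binds but cannot hydrolyze ATP.
#' @export
variant_hemi_dead <- function(labeled_protomer = 1) {
  dimer_variant(protomer_spec(labeled = labeled_protomer == 1),
                protomer_spec(hydrolysis_competent = FALSE,
                              labeled = labeled_protomer == 2))
}

#' @rdname dimer_variant
#' @details `variant_dead_dead()` has both sites hydrolysis-dead.
#' @export
variant_dead_dead <- function() {
  dimer_variant(protomer_spec(hydrolysis_competent = FALSE),
                protomer_spec(hydrolysis_competent = FALSE))
}

#' @rdname dimer_variant
#' @param label_on for the sensor-broken heterodimer (+/R402A-like): put the
#'   reporter on the `"intact"` protomer (trans; expected always buckled when
#'   closed) or on the `"broken"` one (cis; pinned straight).
#' @export
variant_sensor_broken <- function(label_on = c("intact", "broken")) {
  label_on <- match.arg(label_on)
  dimer_variant(protomer_spec(labeled = label_on == "intact"),
                protomer_spec(gamma_sensor_intact = FALSE,
                              labeled = label_on == "broken"))
}

#' Rate parameterization of the dimer cycle
#'
#' All rates are first order, expressed per the declared time unit. Two
#' regimes carry defaults:
#' \describe{
#'   \item{`"mg"`}{turnover conditions (per minute): closure 0.16/min with
#'     hydrolysis, flip and reopening fast enough that closure is
#'     rate-limiting for the wild type.}
#'   \item{`"mg_free"`}{Mg2+-free conditions (per hour): closure 6.95/hr,
#'     buckled-protomer hydrolysis 0.5808/hr, so the first hydrolysis is
#'     rate-limiting and the closed state accumulates.}
#' }
#'
#' @param regime `"mg"` or `"mg_free"`; selects the default rate set and unit.
#' @param k_close ATP-saturated closure rate (ATP binding is folded in).
#' @param k_hyd_buckled hydrolysis rate of the buckled protomer.
#' @param k_hyd_straight hydrolysis rate of the straight protomer; 0 in
#'   solution regimes, used by the crystal mode.
#' @param k_flip rate of the Pi-release-driven asymmetry flip; `Inf` makes
#'   the flip instantaneous upon hydrolysis.
#' @param k_swap buckling-exchange rate within the closed ATP/ATP state
#'   (each direction). Random buckling with symmetric exchange keeps the
#'   50:50 conformer partition while letting every closed dimer eventually
#'   present its competent protomer in the buckled position.
#' @param k_open_dd reopening rate from the ADP/ADP closed state.
#' @param k_open_leak residual reopening rate from all other closed states
#'   (default 0; the hemi-hydrolyzed dimer reopens very slowly).
#' @param unit time unit of all rates; defaults to the regime's.
#' @return an object of class `cycle_rates`.
#' @export
cycle_rates <- function(regime = c("mg", "mg_free"),
                        k_close = NULL, k_hyd_buckled = NULL,
                        k_hyd_straight = 0, k_flip = NULL, k_swap = NULL,
                        k_open_dd = NULL, k_open_leak = 0, unit = NULL) {
  regime <- match.arg(regime)
  def <- if (regime == "mg") {
    list(k_close = 0.16, k_hyd_buckled = 1.5, k_flip = 10, k_swap = 2,
         k_open_dd = 2, unit = "min")
  } else {
    list(k_close = 6.95, k_hyd_buckled = 0.5808, k_flip = 10, k_swap = 10,
         k_open_dd = 2, unit = "hr")
  }
  r <- list(k_close = k_close %||% def$k_close,
            k_hyd_buckled = k_hyd_buckled %||% def$k_hyd_buckled,
            k_hyd_straight = k_hyd_straight,
            k_flip = k_flip %||% def$k_flip,
            k_swap = k_swap %||% def$k_swap,
            k_open_dd = k_open_dd %||% def$k_open_dd,
            k_open_leak = k_open_leak,
            regime = regime,
            unit = .check_time_unit(unit %||% def$unit))
  num <- unlist(r[1:7])
  if (any(!is.na(num) & num < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(r, class = "cycle_rates")
}

#' @rdname cycle_rates
#' @details `crystal_rates()` parameterizes the in-crystal mode, where the
#'   lattice fixes both the closed state and the conformation: only the two
#'   hydrolysis rates act, with the straight protomer much slower.
#' @export
crystal_rates <- function(k_hyd_buckled = 1, k_hyd_straight = 0.05,
                          unit = "day") {
  cycle_rates(regime = "mg_free", k_close = 0,
              k_hyd_buckled = k_hyd_buckled,
              k_hyd_straight = k_hyd_straight,
              k_flip = 0, k_swap = 0, k_open_dd = 0, k_open_leak = 0,
              unit = unit)
}

#' @export
print.cycle_rates <- function(x, ...) {
  cat(sprintf("cycle rates (%s regime, per %s):\n", x$regime, x$unit))
  for (nm in c("k_close", "k_hyd_buckled", "k_hyd_straight", "k_flip",
               "k_swap", "k_open_dd", "k_open_leak"))
    cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}

.state_key <- function(conf, n1, n2, b) paste(conf, n1, n2, b, sep = ".")

.state_class <- function(conf, n1, n2, b) {
  if (conf == "open") {
    nT <- sum(c(n1, n2) == "T")
    return(paste0("open_", nT, "T"))
  }
  n <- c(n1, n2)
  nb <- n[b]; ns <- n[3 - b]
  if (all(n == "T")) return("closed_tt")
  if (setequal(n, c("T", "D"))) return(if (nb == "D") "hemi_pre" else "hemi_post")
  if (all(n == "D")) return("closed_dd")
  if ("T" %in% n) return("closed_te")
  "closed_spent"
}

#' Enumerate the cycle state space and transition list
#'
#' Breadth-first construction of the reachable labeled state graph for a
#' variant under a rate set and operating mode:
#' \describe{
#'   \item{`"multiple_turnover"`}{saturating nucleotide; any reopening
#'     exchanges ADP for ATP instantaneously, so there is a single open
#'     state.}
#'   \item{`"single_turnover"`}{no pool replenishment; on reopening ADP is
#'     released and any remaining ATP re-equilibrates between the two sites
#'     at the next closure. The open state with no ATP left is absorbing.}
#'   \item{`"crystal"`}{the lattice fixes the closed conformation: closure,
#'     buckling exchange, flip and reopening are all disabled and only the
#'     two hydrolysis rates act.}
#' }
#'
#' @param rates a [cycle_rates()].
#' @param variant a [dimer_variant()].
#' @param mode operating mode, see Details.
#' @return an object of class `cycle_graph`: `states` (data frame with
#'   `id`, `conf`, `n1`, `n2`, `buckled`, `class`), `edges` (data frame with
#'   `from`, `to`, `rate`, `type`), the generator matrix `Q`, the per-state
#'   hydrolysis outflow `hyd_out`, and the inputs.
#' @export
enumerate_states <- function(rates, variant,
                             mode = c("multiple_turnover", "single_turnover",
                                      "crystal")) {
  stopifnot(inherits(rates, "cycle_rates"), inherits(variant, "dimer_variant"))
  mode <- match.arg(mode)
  pinned <- !variant$gamma_sensor_intact
  competent <- variant$hydrolysis_competent
  r <- rates
  flip_inf <- is.infinite(r$k_flip)
  in_crystal <- mode == "crystal"

  # canonical open state for a given multiset of retained nucleotides
  open_state <- function(nT) {
    if (mode == "multiple_turnover") return(list("open", "T", "T", 0L))
    switch(as.character(nT),
           "2" = list("open", "T", "T", 0L),
           "1" = list("open", "T", "E", 0L),
           "0" = list("open", "E", "E", 0L))
  }

  # closure transitions out of an open state: place nucleotides, assign
  # buckling by fair coin (all mass to the partner of a pinned protomer)
  close_edges <- function(n1, n2) {
    bs <- which(!pinned)
    wb <- 1 / length(bs)
    placements <- if (mode == "single_turnover" && sum(c(n1, n2) == "T") == 1L) {
      list(c("T", "E"), c("E", "T"))  # the remaining ATP rebinds either site
    } else list(c(n1, n2))
    wp <- 1 / length(placements)
    out <- list()
    for (pl in placements) for (b in bs)
      out[[length(out) + 1L]] <- list(target = list("closed", pl[1], pl[2], b),
                                      rate = r$k_close * wb * wp,
                                      type = "close")
    out
  }

  expand <- function(st) {
    conf <- st[[1]]; n1 <- st[[2]]; n2 <- st[[3]]; b <- st[[4]]
    out <- list()
    if (conf == "open") {
      nT <- sum(c(n1, n2) == "T")
      if (!in_crystal && nT > 0L && r$k_close > 0)
        out <- close_edges(n1, n2)
      return(out)
    }
    n <- c(n1, n2)
    s <- 3L - b
    add <- function(n1x, n2x, bx, rate, type)
      out[[length(out) + 1L]] <<- list(target = list("closed", n1x, n2x, bx),
                                       rate = rate, type = type)
    # hydrolysis by the buckled protomer; with an instantaneous flip the
    # product state lands directly on the flipped asymmetry
    if (n[b] == "T" && competent[b] && r$k_hyd_buckled > 0) {
      nn <- n; nn[b] <- "D"
      bx <- if (!in_crystal && flip_inf && nn[s] == "T" && !pinned[s]) s else b
      add(nn[1], nn[2], bx, r$k_hyd_buckled, "hydrolysis")
    }
    # residual hydrolysis by the straight protomer (crystal mode)
    if (n[s] == "T" && competent[s] && r$k_hyd_straight > 0) {
      nn <- n; nn[s] <- "D"
      add(nn[1], nn[2], b, r$k_hyd_straight, "hydrolysis")
    }
    # Pi-release-driven asymmetry flip
    if (!in_crystal && !flip_inf && r$k_flip > 0 &&
        n[b] == "D" && n[s] == "T" && !pinned[s])
      add(n1, n2, s, r$k_flip, "flip")
    # buckling exchange, confined to the pre-hydrolysis ATP/ATP state
    if (!in_crystal && r$k_swap > 0 && all(n == "T") && !pinned[s])
      add(n1, n2, s, r$k_swap, "swap")
    # reopening
    if (!in_crystal) {
      nT <- sum(n == "T")
      if (nT == 0L) {
        if (r$k_open_dd > 0) {
          op <- open_state(0L)
          out[[length(out) + 1L]] <- list(target = op, rate = r$k_open_dd,
                                          type = "reopen")
        }
      } else if (r$k_open_leak > 0) {
        op <- open_state(nT)
        out[[length(out) + 1L]] <- list(target = op, rate = r$k_open_leak,
                                        type = "leak")
      }
    }
    out
  }

  init <- if (in_crystal) {
    b0 <- if (pinned[1]) 2L else 1L
    list("closed", "T", "T", b0)
  } else list("open", "T", "T", 0L)

  ids <- new.env(parent = emptyenv())
  states <- list()
  add_state <- function(st) {
    k <- .state_key(st[[1]], st[[2]], st[[3]], st[[4]])
    if (!is.null(ids[[k]])) return(ids[[k]])
    id <- length(states) + 1L
    ids[[k]] <- id
    states[[id]] <<- st
    id
  }
  add_state(init)
  edges <- list()
  qi <- 1L
  while (qi <= length(states)) {
    st <- states[[qi]]
    for (tr in expand(st)) {
      to <- add_state(tr$target)
      edges[[length(edges) + 1L]] <- list(from = qi, to = to,
                                          rate = tr$rate, type = tr$type)
    }
    qi <- qi + 1L
  }

  sdf <- data.frame(
    id = seq_along(states),
    conf = vapply(states, `[[`, "", 1),
    n1 = vapply(states, `[[`, "", 2),
    n2 = vapply(states, `[[`, "", 3),
    buckled = vapply(states, function(s) as.integer(s[[4]]), 0L),
    stringsAsFactors = FALSE)
  sdf$key <- with(sdf, .state_key(conf, n1, n2, buckled))
  sdf$class <- mapply(.state_class, sdf$conf, sdf$n1, sdf$n2,
                      pmax(sdf$buckled, 1L))
  edf <- if (length(edges)) {
    data.frame(from = vapply(edges, `[[`, 0L, "from"),
               to = vapply(edges, `[[`, 0L, "to"),
               rate = vapply(edges, `[[`, 0, "rate"),
               type = vapply(edges, `[[`, "", "type"),
               stringsAsFactors = FALSE)
  } else data.frame(from = integer(), to = integer(), rate = numeric(),
                    type = character())

  n <- nrow(sdf)
  Q <- matrix(0, n, n, dimnames = list(sdf$key, sdf$key))
  hyd_out <- numeric(n)
  for (i in seq_len(nrow(edf))) {
    Q[edf$from[i], edf$to[i]] <- Q[edf$from[i], edf$to[i]] + edf$rate[i]
    if (edf$type[i] == "hydrolysis") hyd_out[edf$from[i]] <- hyd_out[edf$from[i]] + edf$rate[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)

  structure(list(states = sdf, edges = edf, Q = Q, hyd_out = hyd_out,
                 initial = 1L, rates = rates, variant = variant, mode = mode),
            class = "cycle_graph")
}

#' @export
print.cycle_graph <- function(x, ...) {
  cat(sprintf("cycle state graph (%s): %d states, %d transitions\n",
              x$mode, nrow(x$states), nrow(x$edges)))
  print(x$states[, c("id", "conf", "n1", "n2", "buckled", "class")],
        row.names = FALSE)
  invisible(x)
}

#' Export a state graph as JSON for inspection
#'
#' @param graph a [enumerate_states()] result.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_state_graph_json <- function(graph, file) {
  stopifnot(inherits(graph, "cycle_graph"))
  jsonlite::write_json(
    list(mode = graph$mode,
         states = graph$states[, c("id", "conf", "n1", "n2", "buckled", "class")],
         edges = graph$edges),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
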