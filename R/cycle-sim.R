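# Twin engines on the enumerated state graph: an exact stochastic simulation
# (Gillespie) of independent dimers and the deterministic master equation.
# Both report the same observables so they can cross-validate each other.

.initial_distribution <- function(graph, init) {
  n <- nrow(graph$states)
  if (is.numeric(init)) {
    stopifnot(length(init) == n, all(init >= 0), abs(sum(init) - 1) < 1e-9)
    return(init / sum(init))
  }
  p <- numeric(n)
  if (identical(init, "default")) {
    p[graph$initial] <- 1
  } else if (identical(init, "closed_tt")) {
    # synchronized closed ATP/ATP population, buckling assigned by the coin
    idx <- which(graph$states$class == "closed_tt")
    if (!length(idx)) stop("graph has no closed ATP/ATP state", call. = FALSE)
    p[idx] <- 1 / length(idx)
  } else stop("unknown initial condition: ", init, call. = FALSE)
  p
}

.sim_observables <- function(graph, times, occupancy, pi_per_dimer) {
  sdf <- graph$states
  closed <- sdf$conf == "closed"
  obs <- data.frame(time = times,
                    fraction_closed = rowSums(occupancy[, closed, drop = FALSE]),
                    pi_per_dimer = pi_per_dimer)
  if (graph$mode == "single_turnover")
    obs$hydrolyzed_fraction <- pi_per_dimer / 2
  lab <- which(graph$variant$labeled)
  if (length(lab) == 1L) {
    den <- rowSums(occupancy[, closed, drop = FALSE])
    num <- rowSums(occupancy[, closed & sdf$buckled == lab, drop = FALSE])
    obs$frac_buckled_labeled <- ifelse(den > 1e-12, num / den, NA_real_)
  }
  obs
}

.new_cycle_sim <- function(graph, times, occupancy, pi_per_dimer, engine,
                           n_dimers = NA_integer_, seed = NA_integer_,
                           first_closure_buckled = NULL) {
  structure(list(times = times, occupancy = occupancy,
                 states = graph$states, graph = graph,
                 observables = .sim_observables(graph, times, occupancy,
                                                pi_per_dimer),
                 engine = engine, mode = graph$mode,
                 rates = graph$rates, variant = graph$variant,
                 n_dimers = n_dimers, seed = seed,
                 first_closure_buckled = first_closure_buckled),
            class = "cycle_sim")
}

#' @export
print.cycle_sim <- function(x, ...) {
  cat(sprintf("cycle simulation (%s engine, %s mode): %d states, t in [%g, %g] %s",
              x$engine, x$mode, nrow(x$states), min(x$times), max(x$times),
              x$rates$unit))
  if (!is.na(x$n_dimers)) cat(sprintf(", %d dimers", x$n_dimers))
  cat("\n")
  last <- x$observables[nrow(x$observables), ]
  cat(sprintf("  final fraction closed: %.4f, cumulative Pi per dimer: %.4f\n",
              last$fraction_closed, last$pi_per_dimer))
  if (!is.null(last$hydrolyzed_fraction))
    cat(sprintf("  hydrolyzed fraction of initially bound ATP: %.4f\n",
                last$hydrolyzed_fraction))
  invisible(x)
}

#' @export
plot.cycle_sim <- function(x, what = c("fraction_closed", "pi_per_dimer",
                                       "hydrolyzed_fraction"), ...) {
  what <- match.arg(what)
  if (is.null(x$observables[[what]]))
    stop("observable not available for this mode: ", what, call. = FALSE)
  graphics::plot(x$times, x$observables[[what]], type = "l",
                 xlab = paste0("time (", x$rates$unit, ")"), ylab = what, ...)
  invisible(x)
}

#' Deterministic master-equation simulation of the dimer cycle
#'
#' Solves dP/dt = P Q on the enumerated state space, together with the
#' expected cumulative number of hydrolysis events per dimer (the integrated
#' hydrolysis flux, i.e. released Pi).
#'
#' @param rates a [cycle_rates()].
#' @param variant a [dimer_variant()].
#' @param t_grid strictly increasing output times starting at 0, in the rate
#'   unit.
#' @param mode operating mode, see [enumerate_states()].
#' @param init `"default"` (the mode's natural start: open for solution
#'   modes, closed ATP/ATP for crystal), `"closed_tt"` (a synchronized closed
#'   population), or a probability vector over states.
#' @param graph optionally, a pre-built [enumerate_states()] result.
#' @return an object of class `cycle_sim` with `times`, the state
#'   `occupancy` matrix and an `observables` data frame (`fraction_closed`,
#'   cumulative `pi_per_dimer`, `hydrolyzed_fraction` in single-turnover
#'   mode, and the labeled protomer's conditional buckled fraction).
#' @export
simulate_master <- function(rates, variant, t_grid,
                            mode = "multiple_turnover", init = "default",
                            graph = NULL) {
  g <- graph %||% enumerate_states(rates, variant, mode)
  stopifnot(inherits(g, "cycle_graph"))
  t_grid <- as.numeric(t_grid)
  stopifnot(length(t_grid) >= 2L, all(diff(t_grid) > 0))
  if (t_grid[1] != 0) t_grid <- c(0, t_grid)
  n <- nrow(g$states)
  p0 <- .initial_distribution(g, init)
  Q <- g$Q
  hyd <- g$hyd_out
  deriv <- function(t, y, parms) {
    P <- y[1:n]
    list(c(as.vector(P %*% Q), sum(P * hyd)))
  }
  sol <- deSolve::lsoda(c(p0, 0), t_grid, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  if (nrow(sol) < length(t_grid))
    stop("master-equation solver failed before t_max; try a finer or shorter ",
         "time grid", call. = FALSE)
  occ <- sol[, 2:(n + 1), drop = FALSE]
  colnames(occ) <- g$states$key
  drift <- max(abs(rowSums(occ) - 1))
  if (drift > 1e-9)
    warning(sprintf("probability conservation drift %.2e exceeds 1e-9", drift),
            call. = FALSE)
  .new_cycle_sim(g, sol[, 1], occ, sol[, n + 2], engine = "master")
}

#' Exact stochastic simulation (Gillespie) of independent dimers
#'
#' Each dimer performs a continuous-time Markov jump process on the
#' enumerated state graph; buckling at closure is assigned by a fair coin
#' (all mass to the partner of a conformation-pinned protomer). States with
#' zero total propensity are absorbing and simply persist to `t_max`.
#'
#' @inheritParams simulate_master
#' @param n_dimers number of independent dimers (>= 1).
#' @param t_max simulation horizon in the rate unit.
#' @param seed integer seed; the run is exactly reproducible.
#' @param n_out number of equally spaced output times (ignored when `t_grid`
#'   is given).
#' @param t_grid optional explicit output grid starting at 0.
#' @return a `cycle_sim` (see [simulate_master()]) whose occupancy rows are
#'   empirical state fractions; additionally carries
#'   `first_closure_buckled`, the protomer index buckled at each dimer's
#'   first entry into the closed ATP/ATP state (`NA` if it never closed).
#' @export
simulate_ssa <- function(rates, variant, n_dimers = 1000, t_max = NULL,
                         seed = 1, mode = "multiple_turnover",
                         init = "default", n_out = 101L, t_grid = NULL,
                         graph = NULL) {
  g <- graph %||% enumerate_states(rates, variant, mode)
  stopifnot(inherits(g, "cycle_graph"))
  stopifnot(n_dimers >= 1)
  if (is.null(t_grid)) {
    stopifnot(!is.null(t_max), t_max > 0)
    t_grid <- seq(0, t_max, length.out = n_out)
  }
  t_grid <- as.numeric(t_grid)
  stopifnot(all(diff(t_grid) > 0))
  if (t_grid[1] != 0) t_grid <- c(0, t_grid)

  ns <- nrow(g$states)
  edf <- g$edges
  K <- max(1L, max(table(factor(edf$from, levels = seq_len(ns)))))
  TRG <- matrix(1L, ns, K)
  CPR <- matrix(1, ns, K)    # cumulative jump probabilities, padded with 1
  HYD <- matrix(0, ns, K)
  tot <- numeric(ns)
  for (i in seq_len(ns)) {
    e <- edf[edf$from == i, , drop = FALSE]
    if (!nrow(e)) next
    tot[i] <- sum(e$rate)
    cp <- cumsum(e$rate) / tot[i]
    TRG[i, seq_len(nrow(e))] <- e$to
    CPR[i, seq_len(nrow(e))] <- cp
    if (nrow(e) < K) CPR[i, (nrow(e) + 1L):K] <- 1
    HYD[i, seq_len(nrow(e))] <- as.numeric(e$type == "hydrolysis")
  }
  is_tt <- g$states$class == "closed_tt"
  st_buck <- g$states$buckled

  p0 <- .initial_distribution(g, init)
  set.seed(seed)
  cur <- sample.int(ns, n_dimers, replace = TRUE, prob = p0)
  tnow <- numeric(n_dimers)
  cnt <- numeric(n_dimers)
  first_b <- rep(NA_integer_, n_dimers)
  first_b[is_tt[cur]] <- st_buck[cur[is_tt[cur]]]

  ngrid <- length(t_grid)
  occ <- matrix(0, ngrid, ns, dimnames = list(NULL, g$states$key))
  pi_tr <- numeric(ngrid)
  occ[1, ] <- tabulate(cur, ns) / n_dimers

  for (gi in 2:ngrid) {
    tg <- t_grid[gi]
    repeat {
      act <- which(tnow < tg & tot[cur] > 0)
      if (!length(act)) break
      tjump <- tnow[act] + stats::rexp(length(act), tot[cur[act]])
      hold <- tjump > tg
      tnow[act[hold]] <- tg        # memoryless: safe to discard the residual
      j <- act[!hold]
      if (!length(j)) break
      tnow[j] <- tjump[!hold]
      rows <- cur[j]
      u <- stats::runif(length(j))
      slot <- rowSums(CPR[rows, , drop = FALSE] < u) + 1L
      idx <- cbind(rows, slot)
      nxt <- TRG[idx]
      cnt[j] <- cnt[j] + HYD[idx]
      newly <- is_tt[nxt] & is.na(first_b[j])
      if (any(newly)) first_b[j[newly]] <- st_buck[nxt[newly]]
      cur[j] <- nxt
    }
    tnow[tnow < tg] <- tg
    occ[gi, ] <- tabulate(cur, ns) / n_dimers
    pi_tr[gi] <- mean(cnt)
  }

  .new_cycle_sim(g, t_grid, occ, pi_tr, engine = "ssa",
                 n_dimers = as.integer(n_dimers), seed = as.integer(seed),
                 first_closure_buckled = first_b)
}

#' Buckled fraction of the labeled protomer, conditioned on a state class
#'
#' @param sim a `cycle_sim` from either engine.
#' @param condition_on the conditioning state class: all `"closed"` states,
#'   only the ATP/ATP `"closed_tt"` states, the hemi-hydrolyzed states
#'   (`"hemi"`, or specifically `"hemi_pre"`/`"hemi_post"`).
#' @param method `"occupancy"` averages the conditional buckled occupancy
#'   over the whole time grid; `"first_entry"` (SSA only, `closed_tt` only)
#'   uses the buckling assigned at each dimer's first closure.
#' @return list with `fraction`, the effective sample size `n` (dimers for
#'   `first_entry`; `NA` for occupancy weighting of a master run), and the
#'   conditioning used. `fraction` is `NA` when the conditioning class is
#'   never occupied.
#' @export
buckled_fraction <- function(sim,
                             condition_on = c("closed", "closed_tt", "hemi",
                                              "hemi_pre", "hemi_post"),
                             method = c("occupancy", "first_entry")) {
  stopifnot(inherits(sim, "cycle_sim"))
  condition_on <- match.arg(condition_on)
  method <- match.arg(method)
  lab <- which(sim$variant$labeled)
  if (length(lab) != 1L)
    stop("variant carries no conformational label", call. = FALSE)

  if (method == "first_entry") {
    if (sim$engine != "ssa" || condition_on != "closed_tt")
      stop("first_entry is defined for SSA runs conditioned on closed_tt",
           call. = FALSE)
    fb <- sim$first_closure_buckled
    n <- sum(!is.na(fb))
    if (n == 0L)
      return(list(fraction = NA_real_, n = 0L, condition_on = condition_on,
                  method = method))
    return(list(fraction = mean(fb[!is.na(fb)] == lab), n = n,
                condition_on = condition_on, method = method))
  }

  cls <- sim$states$class
  sel <- switch(condition_on,
                closed = sim$states$conf == "closed",
                closed_tt = cls == "closed_tt",
                hemi = cls %in% c("hemi_pre", "hemi_post"),
                hemi_pre = cls == "hemi_pre",
                hemi_post = cls == "hemi_post")
  den <- sum(sim$occupancy[, sel, drop = FALSE])
  if (den <= 1e-12) {
    message("conditioning class '", condition_on, "' is never occupied")
    return(list(fraction = NA_real_, n = NA_integer_,
                condition_on = condition_on, method = method))
  }
  num <- sum(sim$occupancy[, sel & sim$states$buckled == lab, drop = FALSE])
  list(fraction = num / den,
       n = if (!is.na(sim$n_dimers)) sim$n_dimers else NA_integer_,
       condition_on = condition_on, method = method)
}

.expected_total_hydrolysis <- function(graph, p0) {
  if (all(graph$hyd_out == 0)) return(0)
  tot <- -diag(graph$Q)
  tr <- tot > 1e-12
  if (!any(tr)) return(0)
  Qtt <- graph$Q[tr, tr, drop = FALSE]
  tau <- tryCatch(solve(t(-Qtt), p0[tr]), error = function(e) NULL)
  if (is.null(tau)) return(NA_real_)
  sum(tau * graph$hyd_out[tr])
}

#' Hydrolyzed fraction of initially bound ATP under single turnover
#'
#' Runs the cycle in single-turnover mode (no nucleotide rebinding from a
#' pool) and reports the fraction of the two initially bound ATPs hydrolyzed
#' over time, plus the exact asymptote computed from the absorbing-state
#' analysis of the graph. The wild type reaches 1; a heterodimer with one
#' hydrolysis-dead protomer and no reopening leak reaches exactly 0.5 (the
#' hemi-hydrolyzed closed state is absorbing); a reopening leak adds a slow
#' further phase as the remaining ATP re-equilibrates between the sites.
#'
#' @inheritParams simulate_master
#' @inheritParams simulate_ssa
#' @param engine `"master"` (default) or `"ssa"`.
#' @param t_max horizon; defaults to 30 over the slowest relevant rate.
#' @return list with `trace` (a [kinetic_trace()] of kind
#'   `"fraction_hydrolyzed"`), the exact `asymptote`, and the full `sim`.
#' @export
single_turnover_fraction <- function(rates, variant, t_max = NULL,
                                     t_grid = NULL,
                                     engine = c("master", "ssa"),
                                     n_dimers = 10000, seed = 1) {
  engine <- match.arg(engine)
  g <- enumerate_states(rates, variant, "single_turnover")
  if (is.null(t_grid)) {
    if (is.null(t_max)) {
      ks <- c(rates$k_close, rates$k_hyd_buckled)
      ks <- ks[ks > 0]
      if (!length(ks)) stop("no positive rates to set a horizon from",
                            call. = FALSE)
      t_max <- 30 / min(ks)
    }
    t_grid <- seq(0, t_max, length.out = 201L)
  }
  sim <- if (engine == "master")
    simulate_master(rates, variant, t_grid, mode = "single_turnover", graph = g)
  else
    simulate_ssa(rates, variant, n_dimers = n_dimers, seed = seed,
                 mode = "single_turnover", t_grid = t_grid, graph = g)
  asym <- .expected_total_hydrolysis(g, .initial_distribution(g, "default")) / 2
  tr <- kinetic_trace(sim$times, sim$observables$hydrolyzed_fraction,
                      time_unit = rates$unit, kind = "fraction_hydrolyzed",
                      label = "single turnover")
  list(trace = tr, asymptote = asym, sim = sim)
}

#' In-crystal hydrolysis timecourse
#'
#' The crystal lattice fixes the closed conformation, so only the two
#' hydrolysis rates act: the buckled protomer converts its ATP first (fast)
#' and the straight protomer slowly follows, giving the dominant-species
#' progression ATP/ATP -> ATP/ADP -> ADP/ADP, with the remaining ATP sitting
#' on the straight protomer throughout the intermediate.
#'
#' @param rates a [crystal_rates()] (or any [cycle_rates()]; only the
#'   hydrolysis rates act in this mode).
#' @param t_checkpoints times (in the rate unit) at which to report.
#' @param variant a [dimer_variant()]; wild type by default.
#' @return data frame with `time`, `P_TT`, `P_TD`, `P_DD`, the probability
#'   `P_T_on_straight` that the remaining ATP of a TD dimer sits on the
#'   straight protomer, and the dominant species at each checkpoint.
#' @export
crystal_mode_timecourse <- function(rates, t_checkpoints,
                                    variant = variant_wildtype()) {
  stopifnot(all(t_checkpoints >= 0))
  tck <- sort(unique(as.numeric(t_checkpoints)))
  grid <- sort(unique(c(0, tck)))
  if (length(grid) < 2L) grid <- c(0, max(tck, 1))
  sim <- simulate_master(rates, variant, grid, mode = "crystal")
  sdf <- sim$states
  at <- match(tck, sim$times)
  p_of <- function(classes) rowSums(sim$occupancy[at, sdf$class %in% classes,
                                                  drop = FALSE])
  p_tt <- p_of("closed_tt")
  p_pre <- p_of("hemi_pre")      # D on the buckled protomer, T on straight
  p_post <- p_of("hemi_post")    # T on the buckled protomer
  p_td <- p_pre + p_post
  p_dd <- p_of("closed_dd")
  out <- data.frame(time = tck, P_TT = p_tt, P_TD = p_td, P_DD = p_dd,
                    P_T_on_straight = ifelse(p_td > 1e-12, p_pre / p_td,
                                             NA_real_))
  out$dominant <- c("TT", "TD", "DD")[max.col(cbind(p_tt, p_td, p_dd))]
  out
}
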