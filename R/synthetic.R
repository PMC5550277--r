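# Seeded generators for every input the analysis modules consume.
#
# Defaults are the study's printed numbers so fixtures resemble the real
# experiments: closure 0.16/min (turnover regime) or 6.95/hr (Mg-free),
# per-site hydrolysis 0.5808/hr, spontaneous hydrolysis 0.00155/hr, 500 uM
# ATP, distance peaks at 22/41 A. Noise is Gaussian and homoscedastic,
# with standard deviation a fixed fraction (default 2%) of each trace's
# dynamic range. Identical seeds give bit-identical output and the caller's
# RNG state is never disturbed.

.noise_sd <- function(clean, frac) {
  rng <- diff(range(clean))
  frac * if (rng > 0) rng else max(abs(clean), 1)
}

#' Synthetic donor/acceptor FRET traces from the cycle model
#'
#' Runs the master-equation engine, maps the closed fraction `f(t)` to the
#' two channels as `donor = D0 (1 - eta f)`, `acceptor = A0 (1 + kappa f)`,
#' and adds Gaussian noise. Feeding the pair through [fret_ratio_trace()]
#' and [fit_exponential()] closes the round trip.
#'
#' @param seed integer seed.
#' @param variant a [dimer_variant()]; the hemi-dead heterodimer by default
#'   (the construct whose closed state accumulates).
#' @param rates a [cycle_rates()].
#' @param t_grid time grid in the rate unit.
#' @param D0,A0 initial channel intensities.
#' @param eta,kappa transfer contrasts (donor quench / acceptor gain at full
#'   closure).
#' @param noise Gaussian noise SD as a fraction of each channel's range.
#' @return list with `donor` and `acceptor` [kinetic_trace()]s and the
#'   echoed parameters in `$params`.
#' @export
gen_fret_traces <- function(seed, variant = variant_hemi_dead(),
                            rates = cycle_rates("mg"),
                            t_grid = seq(0, 40, by = 0.5),
                            D0 = 1000, A0 = 800, eta = 0.4, kappa = 0.4,
                            noise = 0.02) {
  sim <- simulate_master(rates, variant, t_grid)
  f <- sim$observables$fraction_closed
  donor_clean <- D0 * (1 - eta * f)
  acceptor_clean <- A0 * (1 + kappa * f)
  tr <- with_seed(seed, {
    d <- donor_clean + stats::rnorm(length(f), 0, .noise_sd(donor_clean, noise))
    a <- acceptor_clean + stats::rnorm(length(f),
                                       0, .noise_sd(acceptor_clean, noise))
    list(d = d, a = a)
  })
  list(donor = kinetic_trace(sim$times, tr$d, rates$unit, "rfu", "donor"),
       acceptor = kinetic_trace(sim$times, tr$a, rates$unit, "rfu",
                                "acceptor"),
       params = list(seed = seed, D0 = D0, A0 = A0, eta = eta, kappa = kappa,
                     noise = noise, rates = rates, variant = variant),
       fraction_closed = f)
}

#' Synthetic phosphate-release assay: sensor traces plus a standard curve
#'
#' Over the assay window only a small fraction of the 500 uM ATP pool is
#' consumed, so phosphate accumulates in the initial-rate regime:
#' `Pi(t) = (k_spont atp0 + 2 k_cat_site [dimer] efficiency) t`, capped at
#' `atp0` (all sites closed and loaded at saturating ATP; `efficiency`
#' exposes the not-fully-closed correction, default 1). Concentrations are
#' rendered as sensor fluorescence through the linear standard curve and
#' clipped at the detector-linearity cap. The inhibited scenario zeroes the
#' catalyzed term (the active-site inhibitor control).
#'
#' @param seed integer seed.
#' @param dimer_concs dimer concentrations in uM, one trace each.
#' @param k_cat_site catalyzed per-site hydrolysis rate (per hr).
#' @param k_spont spontaneous ATP hydrolysis rate (per hr).
#' @param atp0 initial ATP in uM.
#' @param t_grid time grid in hours.
#' @param cal_slope,cal_intercept,linear_cap standard-curve parameters
#'   (RFU per uM, RFU, RFU).
#' @param standards_pi phosphate standards in uM for the standard curve.
#' @param efficiency fraction of sites closed and loaded.
#' @param inhibited zero the catalyzed term in every trace.
#' @param noise Gaussian noise fraction.
#' @return list with `traces` (one RFU [kinetic_trace()] per concentration),
#'   `standards` (data frame `pi_uM`, `rfu`), and `$params`.
#' @export
gen_phosphate_release <- function(seed, dimer_concs = c(0, 0.25, 0.5, 1, 2),
                                  k_cat_site = 0.5808, k_spont = 0.00155,
                                  atp0 = 500,
                                  t_grid = seq(0, 3, by = 0.1),
                                  cal_slope = 2000, cal_intercept = 500,
                                  linear_cap = 20000,
                                  standards_pi = seq(0, 10, by = 1),
                                  efficiency = 1, inhibited = FALSE,
                                  noise = 0.02) {
  with_seed(seed, {
    traces <- lapply(dimer_concs, function(conc) {
      cat_rate <- if (inhibited) 0 else 2 * k_cat_site * conc * efficiency
      pi_uM <- pmin((k_spont * atp0 + cat_rate) * t_grid, atp0)
      rfu_clean <- pmin(cal_intercept + cal_slope * pi_uM, linear_cap)
      rfu <- rfu_clean + stats::rnorm(length(t_grid), 0,
                                      .noise_sd(rfu_clean, noise))
      kinetic_trace(t_grid, rfu, "hr", "rfu",
                    label = sprintf("%g uM dimer%s", conc,
                                    if (inhibited) " + inhibitor" else ""))
    })
    names(traces) <- sprintf("dimer_%g", dimer_concs)
    rfu_std_clean <- cal_intercept + cal_slope * standards_pi
    rfu_std <- rfu_std_clean + stats::rnorm(length(standards_pi), 0,
                                            noise * cal_slope)
    list(traces = traces,
         standards = data.frame(pi_uM = standards_pi, rfu = rfu_std),
         params = list(seed = seed, dimer_concs = dimer_concs,
                       k_cat_site = k_cat_site, k_spont = k_spont,
                       atp0 = atp0, cal_slope = cal_slope,
                       cal_intercept = cal_intercept, linear_cap = linear_cap,
                       efficiency = efficiency, inhibited = inhibited,
                       noise = noise))
  })
}

#' Synthetic single-turnover hydrolyzed-fraction time course
#'
#' The cycle model's single-turnover observable plus noise. With a
#' hemi-dead heterodimer and a reopening leak, the output shows the fast
#' 0->0.5 phase followed by the slow further phase, and an
#' exponential-plus-linear fit recovers both.
#'
#' @inheritParams gen_fret_traces
#' @return list with `trace` (kind `"fraction_hydrolyzed"`), the noise-free
#'   `clean` values, the exact `asymptote`, and `$params`.
#' @export
gen_single_turnover <- function(seed, variant = variant_hemi_dead(),
                                rates = cycle_rates("mg"),
                                t_grid = seq(0, 60, by = 0.5),
                                noise = 0.02) {
  st <- single_turnover_fraction(rates, variant, t_grid = t_grid)
  clean <- st$trace$values
  vals <- with_seed(seed,
                    clean + stats::rnorm(length(clean), 0,
                                         .noise_sd(clean, noise)))
  list(trace = kinetic_trace(st$trace$times, vals, rates$unit,
                             "fraction_hydrolyzed", "single turnover"),
       clean = clean, asymptote = st$asymptote,
       params = list(seed = seed, noise = noise, rates = rates,
                     variant = variant))
}

#' Synthetic mixing-ratio activity table
#'
#' Total activities from the binomial mixture model (default convention)
#' with replicate Gaussian noise, as produced by a dimer-exchange titration.
#'
#' @param seed integer seed.
#' @param v_wt,v_mut,v_het species activities; the default heterodimer is
#'   sub-additive.
#' @param f_grid wild-type subunit fractions.
#' @param n_rep replicates averaged per point.
#' @param noise replicate noise SD as a fraction of `v_wt`.
#' @return list with `table` (a [mix_table()]) and `$params`.
#' @export
gen_mixing_table <- function(seed, v_wt = 1, v_mut = 0, v_het = 0.2,
                             f_grid = seq(0, 1, by = 0.1), n_rep = 3,
                             noise = 0.02) {
  clean <- total_activity(f_grid, v_wt, v_mut, v_het)
  with_seed(seed, {
    reps <- vapply(clean, function(mu)
      stats::rnorm(n_rep, mu, noise * max(abs(v_wt), 1e-12)),
      numeric(n_rep))
    list(table = mix_table(f_grid, colMeans(reps), sd = apply(reps, 2, stats::sd)),
         clean = clean,
         params = list(seed = seed, v_wt = v_wt, v_mut = v_mut, v_het = v_het,
                       n_rep = n_rep, noise = noise))
  })
}

#' Synthetic two-Gaussian distance distribution
#'
#' A normalized Gaussian mixture on an r-grid with optional grid noise
#' (renormalized and floored at zero), emulating a processed DEER P(r).
#'
#' @param seed integer seed.
#' @param centers,widths,weights mixture parameters in A (weights
#'   renormalized to sum 1).
#' @param r_grid distance grid in A.
#' @param noise Gaussian grid noise as a fraction of the density maximum;
#'   0 gives the exact mixture.
#' @return a [distance_distribution()] with the parameters attached as
#'   attribute `"params"`.
#' @export
gen_pr <- function(seed, centers = c(22, 41), widths = c(3, 4),
                   weights = c(0.5, 0.5), r_grid = seq(10, 60, by = 0.25),
                   noise = 0.01) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(weights))
  weights <- weights / sum(weights)
  clean <- rowSums(vapply(seq_along(centers), function(i)
    weights[i] * stats::dnorm(r_grid, centers[i], widths[i]),
    numeric(length(r_grid))))
  p <- if (noise > 0)
    with_seed(seed, clean + stats::rnorm(length(r_grid), 0, noise * max(clean)))
  else clean
  out <- distance_distribution(r_grid, pmax(p, 0), normalize = TRUE)
  attr(out, "params") <- list(seed = seed, centers = centers, widths = widths,
                              weights = weights, noise = noise)
  out
}

#' Synthetic water trajectory with site-specific exchange kinetics
#'
#' Waters follow independent two-state telegraph (bound/unbound) processes
#' against their assigned pocket site. Bound waters sit within the cutoff
#' shell of the site center (radial jitter); unbound waters are placed
#' uniformly in the box, excluded from both cutoff shells. The stationary
#' bound probability is `k_on / (k_on + k_off)` and the mean dwell is
#' `1/k_off`, so the buckled site's defaults (lower `k_on`, higher `k_off`)
#' give it both fewer waters and shorter dwells than the straight site —
#' the ordering the pocket analysis is meant to recover.
#'
#' @param seed integer seed.
#' @param n_waters total water count, split evenly between the two site
#'   pools.
#' @param site_centers named list of 3-vectors (site label -> center, A).
#' @param k_on,k_off named per-site exchange rates (per ns).
#' @param frame_interval_ns frame spacing (3 ns, the analysis stride).
#' @param n_frames number of frames.
#' @param box cubic box edge length in A (placement volume; the trajectory
#'   itself is non-periodic).
#' @param cutoff shell radius the bound state respects.
#' @return a [trajectory_frames()]; generator parameters in attribute
#'   `"params"`.
#' @export
gen_trajectory <- function(seed, n_waters = 60,
                           site_centers = list(buckled = c(0, 0, 0),
                                               straight = c(25, 0, 0)),
                           k_on = c(buckled = 0.05, straight = 0.10),
                           k_off = c(buckled = 0.50, straight = 0.10),
                           frame_interval_ns = 3, n_frames = 200,
                           box = 60, cutoff = 5) {
  sites <- names(site_centers)
  stopifnot(length(sites) == 2L, all(sites %in% names(k_on)),
            all(sites %in% names(k_off)))
  ctrs <- do.call(rbind, site_centers)
  if (sqrt(sum((ctrs[1, ] - ctrs[2, ])^2)) <= 2 * cutoff)
    stop("site shells overlap: move the centers apart", call. = FALSE)

  # site atoms: central phosphorus-like atom plus 4 offsets, per site
  offs <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.2, 0, 0),
                c(0, 1.2, 0), c(0, 0, 1.2))
  site_xyz <- do.call(rbind, lapply(sites, function(s)
    sweep(offs, 2, site_centers[[s]], `+`)))
  n_site <- nrow(site_xyz)

  pool <- rep(sites, length.out = n_waters)
  dt <- frame_interval_ns

  with_seed(seed, {
    place_unbound <- function() {
      repeat {
        x <- stats::runif(3, -box / 2, box / 2) +
          colMeans(ctrs)  # box centered between the sites
        d <- sqrt(colSums((t(ctrs) - x)^2))
        # margin covers the site-atom offsets so unbound waters never count
        if (all(d > cutoff + 2)) return(x)
      }
    }
    place_bound <- function(center) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      radius <- min(abs(stats::rnorm(1, 0, 1.5)), cutoff - 1)
      center + u * radius
    }
    coords <- array(NA_real_, c(n_site + n_waters, 3, n_frames))
    for (f in seq_len(n_frames)) coords[seq_len(n_site), , f] <- site_xyz
    for (w in seq_len(n_waters)) {
      s <- pool[w]
      kon <- k_on[[s]]; koff <- k_off[[s]]
      ksum <- kon + koff
      p_eq <- if (ksum > 0) kon / ksum else 0
      # exact discrete-time transition probabilities of the 2-state CTMC
      decay <- exp(-ksum * dt)
      p_u2b <- p_eq * (1 - decay)
      p_b2b <- p_eq + (1 - p_eq) * decay
      bound <- stats::runif(1) < p_eq
      for (f in seq_len(n_frames)) {
        if (f > 1) {
          pb <- if (bound) p_b2b else p_u2b
          bound <- stats::runif(1) < pb
        }
        coords[n_site + w, , f] <- if (bound)
          place_bound(site_centers[[s]]) else place_unbound()
      }
    }
    atoms <- data.frame(
      id = c(sprintf("%s_%d", rep(sites, each = nrow(offs)),
                     rep(seq_len(nrow(offs)), 2)),
             sprintf("W%d", seq_len(n_waters))),
      role = c(rep("site_atom", n_site), rep("water_oxygen", n_waters)),
      site = c(rep(sites, each = nrow(offs)), rep(NA_character_, n_waters)),
      stringsAsFactors = FALSE)
    traj <- trajectory_frames(coords, atoms,
                              times = (seq_len(n_frames) - 1) * dt)
    attr(traj, "params") <- list(seed = seed, n_waters = n_waters,
                                 k_on = k_on, k_off = k_off,
                                 pool = pool, frame_interval_ns = dt,
                                 n_frames = n_frames, box = box,
                                 cutoff = cutoff)
    traj
  })
}
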