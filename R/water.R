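# Water occupancy and residence analysis around the two ATP pockets.
#
# Waters are identified by their oxygens only. A "site" is a set of atoms
# (the beta/gamma-phosphate phosphorus atoms and their bonded oxygens in
# practice, supplied through the atom-role table). A water is inside a site
# when its minimum distance to any site atom is strictly below the cutoff
# (the < 5 A convention; configurable to <=).

#' Trajectory frames with atom roles and frame times
#'
#' @param coords numeric array of dimension `(n_atoms, 3, n_frames)`, or a
#'   list of `n_atoms x 3` matrices, in Angstrom.
#' @param atoms data frame with one row per atom: `id` (unique), `role`
#'   (`"water_oxygen"`, `"site_atom"`, or `"other"`), `site` (site label for
#'   site atoms, `NA` otherwise).
#' @param times strictly increasing frame times in ns.
#' @param box optional orthorhombic box lengths, a length-3 vector or an
#'   `n_frames x 3` matrix, enabling minimum-image distances.
#' @return an object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(coords, atoms, times, box = NULL) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3,
                                            length(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]; n_frames <- dim(coords)[3]
  stopifnot(is.data.frame(atoms),
            all(c("id", "role", "site") %in% names(atoms)),
            nrow(atoms) == n_atoms)
  if (anyDuplicated(atoms$id)) stop("atom ids must be unique", call. = FALSE)
  if (!all(atoms$role %in% c("water_oxygen", "site_atom", "other")))
    stop("atom roles must be water_oxygen, site_atom or other", call. = FALSE)
  times <- as.numeric(times)
  stopifnot(length(times) == n_frames)
  if (n_frames >= 2L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  sites <- unique(atoms$site[atoms$role == "site_atom"])
  if (!length(sites)) stop("no site atoms declared", call. = FALSE)
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
    stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  }
  structure(list(coords = coords, atoms = atoms, times = times, box = box,
                 sites = sites, alignment = NULL),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms (%d water oxygens), %d frames over [%g, %g] ns\n",
              nrow(x$atoms), sum(x$atoms$role == "water_oxygen"),
              length(x$times), min(x$times), max(x$times)))
  cat("  sites:", paste(x$sites, collapse = ", "),
      if (!is.null(x$alignment)) "(aligned)" else "", "\n")
  invisible(x)
}

.site_idx <- function(traj, site) {
  idx <- which(traj$atoms$role == "site_atom" & traj$atoms$site == site)
  if (!length(idx)) stop("unknown site: ", site, call. = FALSE)
  idx
}

.water_idx <- function(traj) which(traj$atoms$role == "water_oxygen")

#' Optimal proper rotation between two point sets (Kabsch)
#'
#' Returns the rotation matrix `A` (det = +1, reflection excluded by sign
#' correction of the smallest singular vector) minimizing
#' `||P A - Q||` for centered coordinate rows `P` onto reference rows `Q`.
#'
#' @param P,Q `n x 3` matrices of corresponding points, already centered.
#' @return a 3x3 proper rotation matrix acting on coordinate rows.
#' @export
kabsch_rotation <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, all(dim(P) == dim(Q)),
            nrow(P) >= 3)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("degenerate point set: rotation undefined", call. = FALSE)
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body alignment of all frames on a reference selection
#'
#' Superimposes every frame onto the first by the optimal rotation +
#' translation (no scaling, no reflection) of the selection — in the pocket
#' analysis, the atoms of one ATP — and applies the transform to all atoms.
#' Counting within a cutoff is invariant under this; alignment matters only
#' for positional maps.
#'
#' @param traj a [trajectory_frames()].
#' @param selection atom indices, or a site label whose `site_atom`s are
#'   used.
#' @param reference_frame frame index defining the reference (default 1).
#' @return the aligned `trajectory_frames`, with `$alignment` holding the
#'   per-frame RMSD of the selection (in A) and the selection used.
#' @export
kabsch_align <- function(traj, selection, reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory_frames"))
  idx <- if (is.character(selection)) .site_idx(traj, selection)
         else as.integer(selection)
  if (length(idx) < 3L)
    stop("reference selection needs at least 3 atoms", call. = FALSE)
  ref <- traj$coords[idx, , reference_frame, drop = FALSE]
  dim(ref) <- c(length(idx), 3)
  refc <- colMeans(ref)
  ref0 <- sweep(ref, 2, refc)
  # collinearity check: the centered selection must span a plane
  if (svd(ref0)$d[2] < 1e-8)
    stop("reference selection is collinear/degenerate", call. = FALSE)
  n_frames <- dim(traj$coords)[3]
  out <- traj$coords
  rmsd <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    mob <- traj$coords[idx, , f, drop = FALSE]
    dim(mob) <- c(length(idx), 3)
    mc <- colMeans(mob)
    A <- kabsch_rotation(sweep(mob, 2, mc), ref0)
    frame <- traj$coords[, , f]
    out[, , f] <- sweep(sweep(frame, 2, mc) %*% A, 2, refc, `+`)
    moved <- sweep(mob, 2, mc) %*% A
    rmsd[f] <- sqrt(mean(rowSums((moved - ref0)^2)))
  }
  traj$coords <- out
  traj$alignment <- list(selection = idx, reference_frame = reference_frame,
                         rmsd = rmsd)
  if (!is.null(traj$box))
    traj$box <- NULL  # a rotated orthorhombic box is no longer axis-aligned
  traj
}

.min_dist_to_site <- function(wat, site, box = NULL) {
  # wat: nw x 3, site: ns x 3 -> per-water minimum distance
  nw <- nrow(wat); nsA <- nrow(site)
  if (is.null(box)) {
    d2 <- outer(rowSums(wat^2), rep(1, nsA)) +
      outer(rep(1, nw), rowSums(site^2)) - 2 * tcrossprod(wat, site)
    sqrt(pmax(apply(d2, 1, min), 0))
  } else {
    mind <- rep(Inf, nw)
    for (j in seq_len(nsA)) {
      dx <- sweep(wat, 2, site[j, ])
      dx <- dx - sweep(round(sweep(dx, 2, box, `/`)), 2, box, `*`)
      mind <- pmin(mind, sqrt(rowSums(dx^2)))
    }
    mind
  }
}

.cell_in_cutoff <- function(wat, site, cutoff) {
  # cell-list neighbor search, non-periodic; exact same answer as brute force
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  cw <- floor(wat / cutoff); cs <- floor(site / cutoff)
  site_cells <- split(seq_len(nrow(site)), key(cs))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  inside <- logical(nrow(wat))
  for (i in seq_len(nrow(wat))) {
    neigh <- sweep(offs, 2, as.numeric(cw[i, ]), `+`)
    cand <- unlist(site_cells[key(neigh)], use.names = FALSE)
    if (!length(cand)) next
    d2 <- rowSums(sweep(site[cand, , drop = FALSE], 2, wat[i, ])^2)
    inside[i] <- min(d2) < cutoff^2
  }
  inside
}

#' Per-frame water-in-site membership matrix
#'
#' @inheritParams count_waters_within
#' @return logical matrix, waters (rows, named by atom id) x frames.
#' @export
in_cutoff_matrix <- function(traj, site, cutoff = 5,
                             boundary = c("strict", "inclusive"),
                             method = c("brute", "cell")) {
  stopifnot(inherits(traj, "trajectory_frames"))
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  wi <- .water_idx(traj); si <- .site_idx(traj, site)
  n_frames <- dim(traj$coords)[3]
  M <- matrix(FALSE, length(wi), n_frames,
              dimnames = list(traj$atoms$id[wi], NULL))
  for (f in seq_len(n_frames)) {
    wat <- traj$coords[wi, , f, drop = FALSE]; dim(wat) <- c(length(wi), 3)
    sat <- traj$coords[si, , f, drop = FALSE]; dim(sat) <- c(length(si), 3)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    if (method == "cell" && is.null(box) && boundary == "strict") {
      M[, f] <- .cell_in_cutoff(wat, sat, cutoff)
    } else {
      d <- .min_dist_to_site(wat, sat, box)
      M[, f] <- if (boundary == "strict") d < cutoff else d <= cutoff
    }
  }
  M
}

#' Count waters within a cutoff of a site, per frame
#'
#' Counts distinct water oxygens whose minimum distance to any site atom is
#' below the cutoff (strictly below by default, the "< 5 A" convention).
#' When the trajectory carries an orthorhombic box, minimum-image distances
#' are used.
#'
#' @param traj a [trajectory_frames()].
#' @param site site label.
#' @param cutoff distance cutoff in A (default 5).
#' @param boundary `"strict"` (`<`, default) or `"inclusive"` (`<=`).
#' @param method `"brute"` all-pairs distances, or `"cell"` cell-list
#'   neighbor search (identical results; non-periodic, strict boundary).
#' @return integer vector of per-frame counts.
#' @export
count_waters_within <- function(traj, site, cutoff = 5,
                                boundary = c("strict", "inclusive"),
                                method = c("brute", "cell")) {
  colSums(in_cutoff_matrix(traj, site, cutoff, boundary, method))
}

#' Per-site water occupancy histogram
#'
#' Histograms the per-frame water counts of a site, the analysis behind
#' comparing the solvation of the buckled vs straight ATP pockets.
#'
#' @inheritParams count_waters_within
#' @return an object of class `occupancy_histogram`: `site`, `counts`
#'   (named table: water count -> number of frames), `n_frames`, `cutoff`,
#'   `mean`.
#' @export
occupancy_histogram <- function(traj, site, cutoff = 5,
                                boundary = c("strict", "inclusive")) {
  cc <- count_waters_within(traj, site, cutoff, boundary)
  structure(list(site = site,
                 counts = table(factor(cc, levels = 0:max(cc))),
                 n_frames = length(cc), cutoff = cutoff,
                 mean = mean(cc), per_frame = cc),
            class = "occupancy_histogram")
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("water occupancy at site '%s' (< %g A): mean %.2f over %d frames\n",
              x$site, x$cutoff, x$mean, x$n_frames))
  print(x$counts)
  invisible(x)
}

#' @export
plot.occupancy_histogram <- function(x, ...) {
  graphics::barplot(as.numeric(x$counts), names.arg = names(x$counts),
                    xlab = "waters within cutoff", ylab = "frames",
                    main = x$site, ...)
  invisible(x)
}

#' Compare mean water occupancy between two sites
#'
#' Difference of per-frame mean counts with a bootstrap confidence interval
#' obtained by resampling frames (jointly for both sites, preserving
#' frame-to-frame correlation).
#'
#' @inheritParams count_waters_within
#' @param site_a,site_b site labels; the difference reported is a - b.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return list with `mean_a`, `mean_b`, `difference`, `ci` and inputs.
#' @export
compare_occupancy <- function(traj, site_a, site_b, cutoff = 5,
                              n_boot = 1000, conf = 0.95, seed = 1) {
  ca <- count_waters_within(traj, site_a, cutoff)
  cb <- count_waters_within(traj, site_b, cutoff)
  nf <- length(ca)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nf, nf, replace = TRUE)
      mean(ca[idx]) - mean(cb[idx])
    }, 0)
  })
  alpha <- (1 - conf) / 2
  list(site_a = site_a, site_b = site_b,
       mean_a = mean(ca), mean_b = mean(cb),
       difference = mean(ca) - mean(cb),
       ci = unname(stats::quantile(diffs, c(alpha, 1 - alpha))),
       conf = conf, n_boot = n_boot)
}

.merge_gaps <- function(x, gap) {
  # close out-of-cutoff gaps of length <= gap that sit between in-runs
  if (gap <= 0 || !any(x)) return(x)
  r <- rle(x)
  nr <- length(r$lengths)
  for (i in seq_len(nr)) {
    if (!r$values[i] && r$lengths[i] <= gap && i > 1 && i < nr)
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

#' Per-water fractional residence and dwell times at a site
#'
#' For each water oxygen: the fraction of frames spent within the cutoff of
#' the site, the longest contiguous in-cutoff stretch in ns (a single
#' excursion breaks a dwell unless `gap_tolerance_frames` allows it), and
#' the number of distinct visits. Dwell durations count each in-cutoff frame
#' as one frame interval; with non-uniform frame spacing the actual
#' timestamps are used and a warning is emitted.
#'
#' @inheritParams count_waters_within
#' @param gap_tolerance_frames number of consecutive out-of-cutoff frames
#'   tolerated inside a dwell (default 0).
#' @param class_thresholds fractional-residence thresholds splitting the
#'   reporting classes short/medium/long.
#' @return an object of class `residence_profile`: a data frame with one row
#'   per water (`id`, `fractional_residence`, `longest_dwell_ns`,
#'   `n_visits`, `class`), plus attributes `site`, `cutoff`, `span_ns`.
#' @export
residence_profile <- function(traj, site, cutoff = 5,
                              gap_tolerance_frames = 0,
                              class_thresholds = c(short = 0.25, long = 0.75)) {
  stopifnot(inherits(traj, "trajectory_frames"))
  if (length(traj$times) < 2L)
    stop("residence analysis needs at least 2 frames", call. = FALSE)
  M <- in_cutoff_matrix(traj, site, cutoff)
  dts <- diff(traj$times)
  uniform <- diff(range(dts)) <= 1e-9 * mean(dts)
  if (!uniform)
    warning("non-uniform frame spacing: dwell times computed from timestamps",
            call. = FALSE)
  dur <- c(dts, dts[length(dts)])  # per-frame duration, last extends
  prof <- t(apply(M, 1, function(x) {
    x <- .merge_gaps(x, gap_tolerance_frames)
    fr <- mean(x)
    if (!any(x)) return(c(fr, 0, 0))
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dwells <- vapply(which(r$values),
                     function(i) sum(dur[starts[i]:ends[i]]), 0)
    c(fr, max(dwells), sum(r$values))
  }))
  cls <- cut(prof[, 1], c(-Inf, 0, class_thresholds[["short"]],
                          class_thresholds[["long"]], Inf),
             labels = c("none", "short", "medium", "long"))
  out <- data.frame(id = rownames(M),
                    fractional_residence = prof[, 1],
                    longest_dwell_ns = prof[, 2],
                    n_visits = as.integer(prof[, 3]),
                    class = as.character(cls),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "site") <- site
  attr(out, "cutoff") <- cutoff
  attr(out, "span_ns") <- sum(dur)
  class(out) <- c("residence_profile", "data.frame")
  out
}

#' Mean in-cutoff position of each qualifying water, with residence class
#'
#' The data behind the figure-style dot cloud: for every water that visits
#' the site, its mean position over in-cutoff frames (in the aligned frame)
#' and its residence class.
#'
#' @inheritParams residence_profile
#' @return data frame with `id`, `x`, `y`, `z`, `fractional_residence`,
#'   `class` (one row per water that ever enters the cutoff).
#' @export
positional_density <- function(traj, site, cutoff = 5,
                               class_thresholds = c(short = 0.25, long = 0.75)) {
  stopifnot(inherits(traj, "trajectory_frames"))
  if (is.null(traj$alignment))
    warning("trajectory is not aligned; positions are in raw coordinates",
            call. = FALSE)
  M <- in_cutoff_matrix(traj, site, cutoff)
  wi <- .water_idx(traj)
  keep <- which(rowSums(M) > 0)
  prof <- residence_profile(traj, site, cutoff,
                            class_thresholds = class_thresholds)
  pos <- t(vapply(keep, function(w) {
    fr <- which(M[w, ])
    xyz <- traj$coords[wi[w], , fr, drop = FALSE]
    dim(xyz) <- c(3, length(fr))
    rowMeans(xyz)
  }, numeric(3)))
  data.frame(id = rownames(M)[keep],
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             fractional_residence = prof$fractional_residence[keep],
             class = prof$class[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
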