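make_simple_traj <- function(water_xyz, n_frames = 4, times = NULL,
                             site_center = c(0, 0, 0)) {
  # fixed site (5 atoms) plus user-placed static waters
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  site <- sweep(offs, 2, site_center, `+`)
  xyz <- rbind(site, water_xyz)
  coords <- array(rep(xyz, n_frames), c(nrow(xyz), 3, n_frames))
  atoms <- data.frame(
    id = c(sprintf("S%d", 1:5), sprintf("W%d", seq_len(nrow(water_xyz)))),
    role = c(rep("site_atom", 5), rep("water_oxygen", nrow(water_xyz))),
    site = c(rep("pocket", 5), rep(NA, nrow(water_xyz))),
    stringsAsFactors = FALSE)
  trajectory_frames(coords, atoms, times %||% (seq_len(n_frames) - 1) * 3)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Kabsch rotation is proper and inverts constructed transforms", {
  set.seed(8)
  for (i in 1:20) {
    P <- matrix(rnorm(30), 10, 3)
    A <- kabsch_rotation(P, P)
    expect_equal(det(A), 1, tolerance = 1e-9)
    expect_equal(A, diag(3), tolerance = 1e-7)
    # arbitrary proper rotation, recovered exactly
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    Arec <- kabsch_rotation(P %*% R, P)
    expect_equal(det(Arec), 1, tolerance = 1e-9)
    expect_equal(P %*% R %*% Arec, P, tolerance = 1e-9)
  }
})

test_that("frame alignment undoes rotation + translation of whole frames", {
  tr <- make_simple_traj(rbind(c(3, 0, 0), c(0, 4, 0)), n_frames = 3)
  # rotate frame 2 by 90 degrees about z and translate
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr$coords[, , 2] <- sweep(tr$coords[, , 2] %*% R, 2, c(5, -2, 1), `+`)
  al <- kabsch_align(tr, "pocket")
  expect_lt(max(al$alignment$rmsd), 1e-9)
  expect_equal(al$coords[, , 2], al$coords[, , 1], tolerance = 1e-9)
  # degenerate (collinear) selections are rejected
  bad <- make_simple_traj(rbind(c(3, 0, 0)))
  bad$atoms$site[4:5] <- NA; bad$atoms$role[4:5] <- "other"
  expect_error(kabsch_align(bad, "pocket"), "collinear|degenerate")
})

test_that("alignment RMSD under selection noise matches the Monte-Carlo level", {
  set.seed(21)
  sigma <- 0.1
  offs <- matrix(rnorm(60), 20, 3) * 3
  rms <- replicate(60, {
    noisy <- offs + matrix(rnorm(60, 0, sigma), 20, 3)
    A <- kabsch_rotation(scale(noisy, scale = FALSE),
                         scale(offs, scale = FALSE))
    sqrt(mean(rowSums((scale(noisy, scale = FALSE) %*% A -
                         scale(offs, scale = FALSE))^2)))
  })
  # expected RMSD is sigma * sqrt(3) per point, reduced by the 6 fitted
  # rigid-body degrees of freedom; within 20%
  expected <- sigma * sqrt(3 * (3 * 20 - 6) / (3 * 20))
  expect_lt(abs(mean(rms) - expected) / expected, 0.2)
})

test_that("water counting uses a strict boundary by default", {
  tr <- make_simple_traj(rbind(c(5.99, 0, 0),   # 4.99 from the +x site atom
                               c(6.00, 0, 0),   # exactly 5.00
                               c(30, 30, 30)))
  counts <- count_waters_within(tr, "pocket", cutoff = 5)
  expect_equal(unname(counts), rep(1L, 4))
  counts_inc <- count_waters_within(tr, "pocket", 5, boundary = "inclusive")
  expect_equal(unname(counts_inc), rep(2L, 4))
  # no waters at all
  empty <- make_simple_traj(matrix(numeric(0), 0, 3))
  expect_equal(unname(count_waters_within(empty, "pocket")), rep(0L, 4))
})

test_that("counting is invariant under a joint rigid transform", {
  traj <- gen_trajectory(seed = 2, n_waters = 30, n_frames = 20)
  base <- count_waters_within(traj, "straight")
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- traj
  for (f in seq_along(traj$times))
    moved$coords[, , f] <- sweep(traj$coords[, , f] %*% R, 2, c(7, -3, 2), `+`)
  expect_identical(count_waters_within(moved, "straight"), base)
})

test_that("cell-list search equals brute force exactly", {
  set.seed(5)
  for (i in 1:25) {
    nw <- sample(5:40, 1)
    wat <- matrix(runif(nw * 3, -15, 15), nw, 3)
    tr <- make_simple_traj(wat, n_frames = 2)
    b <- in_cutoff_matrix(tr, "pocket", method = "brute")
    cl <- in_cutoff_matrix(tr, "pocket", method = "cell")
    expect_identical(b, cl)
  }
})

test_that("occupancy histograms conserve frames and recover generator means", {
  tr <- make_simple_traj(rbind(c(1, 1, 0), c(2, 0, 0), c(0, 0, 2),
                               c(40, 0, 0)))
  h <- occupancy_histogram(tr, "pocket")
  expect_equal(sum(h$counts), h$n_frames)
  expect_equal(unname(h$counts[["3"]]), 4L)
  expect_equal(h$mean, 3)

  traj <- gen_trajectory(seed = 13, n_waters = 60, n_frames = 150)
  cmp <- compare_occupancy(traj, "buckled", "straight", seed = 1)
  p <- attr(traj, "params")
  true_diff <- 30 * (0.05 / 0.55) - 30 * (0.10 / 0.20)
  expect_lt(cmp$difference, 0)
  expect_gt(true_diff, cmp$ci[1] - 1)
  expect_lt(true_diff, cmp$ci[2] + 1)
})

test_that("per-water and per-frame counts obey the double-counting identity", {
  traj <- gen_trajectory(seed = 17, n_waters = 40, n_frames = 60)
  M <- in_cutoff_matrix(traj, "buckled")
  expect_equal(sum(rowSums(M)), sum(count_waters_within(traj, "buckled")))
})

test_that("residence profiles measure fractions, dwells and visits", {
  # one water always inside, one alternating every frame
  n_frames <- 8
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  coords <- array(NA_real_, c(7, 3, n_frames))
  for (f in 1:n_frames) {
    coords[1:5, , f] <- offs
    coords[6, , f] <- c(2, 0, 0)
    coords[7, , f] <- if (f %% 2 == 1) c(0, 2, 0) else c(30, 0, 0)
  }
  atoms <- data.frame(id = c(paste0("S", 1:5), "Win", "Walt"),
                      role = c(rep("site_atom", 5), "water_oxygen",
                               "water_oxygen"),
                      site = c(rep("pocket", 5), NA, NA))
  tr <- trajectory_frames(coords, atoms, (0:(n_frames - 1)) * 3)
  rp <- residence_profile(tr, "pocket")
  win <- rp[rp$id == "Win", ]
  expect_equal(win$fractional_residence, 1)
  expect_equal(win$longest_dwell_ns, attr(rp, "span_ns"))
  expect_equal(win$n_visits, 1L)
  walt <- rp[rp$id == "Walt", ]
  expect_equal(walt$fractional_residence, 0.5)
  expect_equal(walt$longest_dwell_ns, 3)  # one frame interval
  expect_equal(walt$n_visits, 4L)
  # a gap tolerance of 1 merges the alternating runs into one visit
  rp1 <- residence_profile(tr, "pocket", gap_tolerance_frames = 1)
  expect_equal(rp1[rp1$id == "Walt", "n_visits"], 1L)
  # non-uniform spacing warns and uses timestamps
  tr2 <- tr; tr2$times <- c(0, 3, 6, 9, 12, 20, 23, 26)
  expect_warning(residence_profile(tr2, "pocket"), "non-uniform")
})

test_that("telegraph-generator occupancy matches the stationary closed form", {
  traj <- gen_trajectory(seed = 31, n_waters = 200, n_frames = 150,
                         k_on = c(buckled = 0.05, straight = 0.10),
                         k_off = c(buckled = 0.50, straight = 0.10))
  rp <- residence_profile(traj, "straight")
  p <- attr(traj, "params")
  pool_straight <- p$pool == "straight"
  frac <- mean(rp$fractional_residence[rp$id %in%
                                         sprintf("W%d", which(pool_straight))])
  p_eq <- 0.10 / (0.10 + 0.10)
  # frames are 3 ns apart but correlated; allow 3 SE of the water-level mean
  se <- stats::sd(rp$fractional_residence[rp$id %in%
                                            sprintf("W%d", which(pool_straight))]) /
    sqrt(sum(pool_straight))
  expect_lt(abs(frac - p_eq), 3 * se)
  # ordering: buckled pocket drier with shorter dwells
  rpb <- residence_profile(traj, "buckled")
  expect_lt(mean(count_waters_within(traj, "buckled")),
            mean(count_waters_within(traj, "straight")))
  expect_lt(mean(rpb$longest_dwell_ns[rpb$fractional_residence > 0]),
            mean(rp$longest_dwell_ns[rp$fractional_residence > 0]))
})

test_that("positional density reports mean in-cutoff positions and classes", {
  tr <- make_simple_traj(rbind(c(2, 1, 0), c(40, 0, 0)))
  pd <- suppressWarnings(positional_density(tr, "pocket"))
  expect_equal(nrow(pd), 1L)
  expect_equal(unlist(pd[1, c("x", "y", "z")]),
               c(x = 2, y = 1, z = 0), tolerance = 1e-12)
  expect_identical(pd$class, "long")
  # generator: density centroid near the site center
  traj <- gen_trajectory(seed = 41, n_waters = 80, n_frames = 80)
  pdg <- suppressWarnings(positional_density(traj, "straight"))
  heavy <- pdg[pdg$fractional_residence > 0.2, ]
  expect_lt(sqrt(sum((colMeans(heavy[, c("x", "y", "z")]) - c(25, 0, 0))^2)),
            1.5)
})

test_that("PDB and XYZ round trips preserve coordinates, roles and times", {
  traj <- gen_trajectory(seed = 3, n_waters = 12, n_frames = 5)
  fp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, fp)
  tr2 <- read_trajectory_pdb(fp, site_chains = c(buckled = "A",
                                                 straight = "B"))
  expect_equal(tr2$coords, traj$coords, tolerance = 1e-3)
  expect_identical(tr2$atoms$role, traj$atoms$role)
  expect_identical(tr2$atoms$site, traj$atoms$site)
  fx <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, fx)
  tr3 <- read_trajectory_xyz(fx)
  expect_equal(tr3$coords, traj$coords, tolerance = 1e-5)
  expect_identical(tr3$times, traj$times)
  expect_identical(tr3$atoms$role, traj$atoms$role)
  unlink(c(fp, fx))
})
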