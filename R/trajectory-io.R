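# Plain-text trajectory formats: multi-model PDB (MODEL/ENDMDL) and XYZ with
# frame times on the comment line. bio3d parses the PDB side; the multi-model
# writer and the XYZ pair are implemented here.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so
#' seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.default_site_chains <- function(sites) {
  stats::setNames(LETTERS[seq_along(sites)], sites)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame. Water oxygens are written as `O` atoms
#' of `HOH` residues on chain `W`; site atoms as `P`-named atoms of `STE`
#' residues, one chain per site (in the order of `traj$sites`, chains A, B,
#' ...); any other atoms as `C` atoms of `OTH` residues on chain `X`.
#'
#' @param traj a [trajectory_frames()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_trajectory_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory_frames"))
  chains <- .default_site_chains(traj$sites)
  at <- traj$atoms
  name <- ifelse(at$role == "water_oxygen", "O",
                 ifelse(at$role == "site_atom", "P", "C"))
  resn <- ifelse(at$role == "water_oxygen", "HOH",
                 ifelse(at$role == "site_atom", "STE", "OTH"))
  chain <- ifelse(at$role == "water_oxygen", "W",
                  ifelse(at$role == "site_atom", chains[at$site], "X"))
  elem <- ifelse(at$role == "site_atom", "P",
                 ifelse(at$role == "water_oxygen", "O", "C"))
  n <- nrow(at)
  resseq <- seq_len(n) %% 10000L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 FRAME INTERVAL NS %g",
                     if (length(traj$times) > 1) diff(traj$times)[1] else 0),
             con)
  for (f in seq_along(traj$times)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f]
    writeLines(sprintf(
      "ATOM  %5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n) %% 100000L, name, "", resn, chain, resseq, "",
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL frames via bio3d. Water oxygens are selected by
#' residue name and an `O*` atom name; site atoms by chain, through the
#' `site_chains` map.
#'
#' @param file path to a multi-model PDB.
#' @param site_chains named character vector mapping site labels to chain
#'   IDs, e.g. `c(buckled = "A", straight = "B")`.
#' @param water_resnames residue names treated as water.
#' @param frame_times explicit frame times in ns, or `NULL` to use
#'   `frame_interval_ns` (PDB has no time field).
#' @param frame_interval_ns uniform frame spacing when `frame_times` is
#'   absent; 3 ns mirrors the generator default.
#' @return a [trajectory_frames()].
#' @export
read_trajectory_pdb <- function(file,
                                site_chains = c(buckled = "A", straight = "B"),
                                water_resnames = c("HOH", "WAT", "TIP", "TIP3",
                                                   "SPC"),
                                frame_times = NULL, frame_interval_ns = 3) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n <- nrow(at)
  xyz <- pdb$xyz              # n_frames x 3n
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  is_water <- at$resid %in% water_resnames & grepl("^O", at$elety)
  site <- rep(NA_character_, n)
  for (lab in names(site_chains))
    site[!is_water & at$chain %in% site_chains[[lab]]] <- lab
  role <- ifelse(is_water, "water_oxygen",
                 ifelse(!is.na(site), "site_atom", "other"))
  atoms <- data.frame(id = paste0(at$elety, "_", seq_len(n), "_", at$chain),
                      role = role, site = site, stringsAsFactors = FALSE)
  if (is.null(frame_times))
    frame_times <- (seq_len(n_frames) - 1) * frame_interval_ns
  trajectory_frames(coords, atoms, frame_times)
}

#' Write and read XYZ trajectories with frame times
#'
#' The XYZ block format: an atom-count line, a comment line carrying
#' `t= <ns>`, then one `<name> x y z` line per atom. Water oxygens are
#' written with name `OW`; site atoms with the per-site names of
#' `site_names`; others as `X`. Reading maps the names back to roles.
#'
#' @param traj a [trajectory_frames()].
#' @param file path.
#' @param site_names named character vector mapping site labels to atom
#'   names.
#' @return `write_trajectory_xyz()` invisibly returns `file`;
#'   `read_trajectory_xyz()` returns a [trajectory_frames()].
#' @export
write_trajectory_xyz <- function(traj, file,
                                 site_names = c(buckled = "SA",
                                                straight = "SB")) {
  stopifnot(inherits(traj, "trajectory_frames"))
  if (!all(traj$sites %in% names(site_names)))
    site_names <- stats::setNames(paste0("S", seq_along(traj$sites)),
                                  traj$sites)
  at <- traj$atoms
  nm <- ifelse(at$role == "water_oxygen", "OW",
               ifelse(at$role == "site_atom", site_names[at$site], "X"))
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(at)
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6f ns", traj$times[f]), con)
    xyz <- traj$coords[, , f]
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       nm, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_trajectory_xyz
#' @param water_names atom names treated as water oxygens on read.
#' @export
read_trajectory_xyz <- function(file, water_names = "OW",
                                site_names = c(buckled = "SA",
                                               straight = "SB")) {
  lines <- readLines(file)
  i <- 1L
  frames <- list()
  times <- numeric()
  names_ref <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i,
                       call. = FALSE)
    tm <- regmatches(lines[i + 1L],
                     regexec("t=\\s*([0-9.eE+-]+)", lines[i + 1L]))[[1]]
    times[length(times) + 1L] <- if (length(tm) >= 2) as.numeric(tm[2])
                                 else length(times) * 3
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    nm <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(names_ref)) names_ref <- nm
    else if (!identical(nm, names_ref))
      stop("atom table changes between XYZ frames", call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  coords <- array(unlist(frames), c(length(names_ref), 3, length(frames)))
  site <- rep(NA_character_, length(names_ref))
  for (lab in names(site_names)) site[names_ref == site_names[[lab]]] <- lab
  role <- ifelse(names_ref %in% water_names, "water_oxygen",
                 ifelse(!is.na(site), "site_atom", "other"))
  atoms <- data.frame(id = paste0(names_ref, "_", seq_along(names_ref)),
                      role = role, site = site, stringsAsFactors = FALSE)
  trajectory_frames(coords, atoms, times)
}
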