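#' Simulate closest-approach distance series from a two-state binding model
#'
#' Emulates the reduced output of a box simulation of one nucleotide with
#' several amino-acid copies: per-frame closest-approach distances for a
#' set of independent parallel runs. Frames alternate between a bound and
#' a free state following a two-state Markov chain whose stationary bound
#' probability equals \code{occupancy}; dwell lengths are geometric.
#' Bound frames draw distances from a truncated-Gaussian mixture over the
#' three experimentally motivated binding modes near 1.9, 2.5 and 4.0
#' Angstrom; free frames draw from a Gaussian centred at 5.5 Angstrom
#' left-truncated at the binding threshold, reflecting the typical
#' distance of the closest unbound amino acid. Distances are emitted
#' directly (not derived from coordinates) so the planted occupancy is
#' exact ground truth; use [gen_box_trajectory()] to exercise geometry.
#'
#' @param occupancy Target stationary fraction of bound frames, in [0, 1].
#' @param n_runs Number of independent parallel runs (default 100).
#' @param n_frames Frames per run (default 10000).
#' @param seed Integer seed; identical seeds give identical output. Each
#'   run uses a distinct sub-seed so runs are independent.
#' @param mean_dwell_bound Mean bound dwell in frames (>= 1).
#' @param bound_modes,bound_sds,bound_weights Mixture describing the bound
#'   distance distribution (Angstrom).
#' @param free_mean,free_sd Free-state distance distribution (Angstrom).
#' @param threshold Binding threshold separating the two states (default 5
#'   Angstrom); bound samples lie strictly below it, free samples at or
#'   above it.
#' @return A data frame of class \code{"distance_series"} with columns
#'   \code{run_id}, \code{frame}, \code{distance} (Angstrom).
#' @export
gen_distance_series <- function(occupancy, n_runs = 100L, n_frames = 10000L,
                                seed = 1L, mean_dwell_bound = 20,
                                bound_modes = c(1.9, 2.5, 4.0),
                                bound_sds = c(0.15, 0.2, 0.3),
                                bound_weights = c(0.3, 0.4, 0.3),
                                free_mean = 5.5, free_sd = 1.0,
                                threshold = 5) {
  assert_scalar_num(occupancy, "occupancy", 0, 1)
  assert_scalar_num(mean_dwell_bound, "mean_dwell_bound", 1)
  if (occupancy > 0 && occupancy < 1) {
    dwell_free <- mean_dwell_bound * (1 - occupancy) / occupancy
    if (dwell_free < 1)
      stop("implied free dwell < 1 frame; lower `occupancy` or raise ",
           "`mean_dwell_bound`", call. = FALSE)
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    with_seed(sub_seed(seed, r), {
      bound <- sim_two_state(n_frames, occupancy, mean_dwell_bound)
      d <- numeric(n_frames)
      nb <- sum(bound)
      if (nb > 0)
        d[bound] <- sample_bound_distances(nb, bound_modes, bound_sds,
                                           bound_weights, threshold)
      if (nb < n_frames)
        d[!bound] <- sample_free_distances(n_frames - nb, free_mean,
                                           free_sd, threshold)
      data.frame(run_id = r, frame = seq_len(n_frames), distance = d)
    })
  })
  out <- do.call(rbind, runs)
  class(out) <- c("distance_series", "data.frame")
  out
}

# Alternating geometric dwells; stationary bound probability = p_bound
sim_two_state <- function(n_frames, p_bound, dwell_bound) {
  if (p_bound <= 0) return(rep(FALSE, n_frames))
  if (p_bound >= 1) return(rep(TRUE, n_frames))
  dwell_free <- dwell_bound * (1 - p_bound) / p_bound
  state <- runif(1) < p_bound
  states <- logical(0)
  lens <- integer(0)
  total <- 0L
  cur <- state
  while (total < n_frames) {
    n_need <- max(16L, ceiling(2 * (n_frames - total) /
                                 (dwell_bound + dwell_free)) + 8L)
    # dwell ~ 1 + Geom(1/mean) so the mean dwell is the requested one
    db <- rgeom(n_need, min(1, 1 / dwell_bound)) + 1L
    df <- rgeom(n_need, min(1, 1 / dwell_free)) + 1L
    pair <- if (cur) rbind(db, df) else rbind(df, db)
    newlens <- as.integer(pair)
    newstates <- rep(c(cur, !cur), n_need)
    lens <- c(lens, newlens)
    states <- c(states, newstates)
    total <- total + sum(newlens)
    # after an even number of dwells the next state is again `cur`
  }
  rep(states, lens)[seq_len(n_frames)]
}

sample_bound_distances <- function(n, modes, sds, weights, threshold) {
  comp <- sample.int(length(modes), n, replace = TRUE, prob = weights)
  d <- rnorm(n, modes[comp], sds[comp])
  bad <- d <= 0 | d >= threshold
  while (any(bad)) {
    nb <- sum(bad)
    comp <- sample.int(length(modes), nb, replace = TRUE, prob = weights)
    d[bad] <- rnorm(nb, modes[comp], sds[comp])
    bad <- d <= 0 | d >= threshold
  }
  d
}

sample_free_distances <- function(n, mean, sd, threshold) {
  d <- rnorm(n, mean, sd)
  bad <- d < threshold
  while (any(bad)) {
    d[bad] <- rnorm(sum(bad), mean, sd)
    bad <- d < threshold
  }
  d
}

#' Simulate a rigid-molecule random-walk trajectory in a periodic box
#'
#' Geometry fixture for the minimum-image distance and Monte Carlo volume
#' code: rigid point-cluster molecules (one nucleotide, \code{n_copies}
#' amino-acid copies) perform random walks in a periodic cube. An optional
#' square-well attraction between the nucleotide and each amino-acid copy
#' is applied by Metropolis acceptance of amino-acid moves, raising the
#' time spent within the well; with \code{attraction = 0} the stationary
#' distribution is uniform (the geometric null).
#'
#' @param box_edge Cube edge in Angstrom (default 40).
#' @param n_copies Number of amino-acid copies (default 10).
#' @param n_frames Number of stored frames.
#' @param atoms_nucleotide,atoms_amino Atoms per molecule.
#' @param radius_nucleotide,radius_amino Radius (Angstrom) of the rigid
#'   atom cluster around each molecule's centre; 0 gives point molecules.
#' @param step_sd Random-walk step standard deviation per axis (Angstrom).
#' @param attraction Square-well depth in kT units (0 = no attraction).
#' @param well Well width: the closest-approach distance (Angstrom) below
#'   which the attraction applies (default 5).
#' @param seed Integer seed.
#' @return List of class \code{"box_trajectory"}: \code{coords} (array
#'   frames x atoms x 3, all in [0, box_edge)), \code{atoms} (data frame
#'   with \code{molecule}, \code{group}, \code{atom}), \code{box_edge}.
#' @export
gen_box_trajectory <- function(box_edge = 40, n_copies = 10L,
                               n_frames = 100L, atoms_nucleotide = 4L,
                               atoms_amino = 3L, radius_nucleotide = 2,
                               radius_amino = 1.5, step_sd = 1.0,
                               attraction = 0, well = 5, seed = 1L) {
  assert_scalar_num(box_edge, "box_edge", lower = 1e-9)
  if (n_copies < 1) stop("`n_copies` must be >= 1", call. = FALSE)
  n_mol <- n_copies + 1L
  with_seed(seed, {
    offsets <- lapply(seq_len(n_mol), function(m) {
      na <- if (m == 1L) atoms_nucleotide else atoms_amino
      r <- if (m == 1L) radius_nucleotide else radius_amino
      off <- matrix(rnorm(na * 3), ncol = 3)
      nrm <- sqrt(rowSums(off^2))
      nrm[nrm == 0] <- 1
      off * (r * runif(na)^(1 / 3) / nrm)
    })
    centers <- matrix(runif(n_mol * 3, 0, box_edge), ncol = 3)
    n_atoms <- sum(vapply(offsets, nrow, 1L))
    coords <- array(NA_real_, c(n_frames, n_atoms, 3))
    atom_tab <- data.frame(
      molecule = rep(seq_len(n_mol), vapply(offsets, nrow, 1L)),
      group = rep(c("nucleotide", rep("amino_acid", n_copies)),
                  vapply(offsets, nrow, 1L)))
    atom_tab$atom <- seq_len(n_atoms)
    place <- function(centers) {
      do.call(rbind, lapply(seq_len(n_mol), function(m)
        sweep(offsets[[m]], 2, centers[m, ], `+`) %% box_edge))
    }
    nt_atoms <- function(centers)
      (sweep(offsets[[1]], 2, centers[1, ], `+`)) %% box_edge
    closest <- function(m, centers, nt) {
      aa <- sweep(offsets[[m]], 2, centers[m, ], `+`) %% box_edge
      min_image_set_distance(nt, aa, box_edge)
    }
    for (f in seq_len(n_frames)) {
      # nucleotide moves freely
      centers[1, ] <- (centers[1, ] + rnorm(3, 0, step_sd)) %% box_edge
      nt <- nt_atoms(centers)
      for (m in 2:n_mol) {
        prop <- (centers[m, ] + rnorm(3, 0, step_sd)) %% box_edge
        if (attraction > 0) {
          e_old <- -attraction * (closest(m, centers, nt) < well)
          cand <- centers
          cand[m, ] <- prop
          e_new <- -attraction * (closest(m, cand, nt) < well)
          if (runif(1) < exp(e_old - e_new)) centers[m, ] <- prop
        } else {
          centers[m, ] <- prop
        }
      }
      coords[f, , ] <- place(centers)
    }
    structure(list(coords = coords, atoms = atom_tab,
                   box_edge = box_edge),
              class = "box_trajectory")
  })
}

#' Simulate a noisy chemical-shift titration curve
#'
#' Generates observed shift changes for a ligand (amino acid) titration
#' against a fixed observed species (nucleotide) concentration, following
#' the one-site fast-exchange binding isotherm ([binding_isotherm()]) with
#' additive Gaussian noise.
#'
#' @param KD Dissociation constant (mM), >= 0.
#' @param dmax Maximum shift change at saturation (ppm), >= 0.
#' @param P_total Observed species concentration (mM), default 0.1.
#' @param L_totals Ligand concentrations (mM), all > 0; default a
#'   log-spaced grid over 0.1-100 mM as used experimentally.
#' @param noise_sd Gaussian noise standard deviation (ppm), >= 0.
#' @param seed Integer seed.
#' @return Data frame of class \code{"titration_curve"} with columns
#'   \code{L_total} (mM) and \code{shift} (ppm); \code{P_total} and the
#'   ground-truth parameters are stored as attributes.
#' @export
gen_titration <- function(KD, dmax, P_total = 0.1,
                          L_totals = 10^seq(-1, 2, length.out = 9),
                          noise_sd = 0, seed = 1L) {
  assert_scalar_num(KD, "KD", 0)
  assert_scalar_num(dmax, "dmax", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  if (any(L_totals <= 0)) stop("`L_totals` must be > 0", call. = FALSE)
  mu <- binding_isotherm(P_total, L_totals, KD, dmax)
  obs <- with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  out <- data.frame(L_total = L_totals, shift = obs)
  attr(out, "P_total") <- P_total
  attr(out, "truth") <- c(KD = KD, dmax = dmax, noise_sd = noise_sd)
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Write / read a distance series as tabular text
#'
#' @param series A \code{distance_series} data frame.
#' @param path Output/input file path (tab-separated, with header
#'   \code{run_id}, \code{frame}, \code{distance_A}).
#' @return \code{read_distance_series} returns a \code{distance_series}
#'   data frame.
#' @export
write_distance_series <- function(series, path) {
  out <- data.frame(run_id = series$run_id, frame = series$frame,
                    distance_A = series$distance)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_series
#' @export
read_distance_series <- function(path) {
  if (!file.exists(path))
    stop("distance series file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = "\t")
  out <- data.frame(run_id = tab$run_id, frame = tab$frame,
                    distance = tab$distance_A)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Write / read a box trajectory as multi-frame XYZ plus a group sidecar
#'
#' The coordinate file is standard extended XYZ (atom count, comment line
#' with the box edge, then one \code{label x y z} row per atom); the
#' sidecar is a tab-separated table mapping atom index to molecule and
#' group.
#'
#' @param traj A \code{box_trajectory}.
#' @param xyz_path,groups_path File paths.
#' @return \code{read_box_trajectory} returns a \code{box_trajectory}.
#' @export
write_box_trajectory <- function(traj, xyz_path, groups_path) {
  n_atoms <- dim(traj$coords)[2]
  lab <- ifelse(traj$atoms$group == "nucleotide", "N", "C")
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(c(as.character(n_atoms),
                 sprintf("box_edge=%.6f frame=%d", traj$box_edge, f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  write.table(traj$atoms, groups_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(xyz_path)
}

#' @rdname write_box_trajectory
#' @export
read_box_trajectory <- function(xyz_path, groups_path) {
  for (p in c(xyz_path, groups_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  lines <- readLines(xyz_path)
  n_atoms <- as.integer(lines[1])
  block <- n_atoms + 2L
  n_frames <- length(lines) %/% block
  box_edge <- as.numeric(sub(".*box_edge=([0-9.]+).*", "\\1", lines[2]))
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    rows <- lines[((f - 1) * block + 3):((f - 1) * block + 2 + n_atoms)]
    xyz <- do.call(rbind, lapply(strsplit(rows, "\\s+"), function(x)
      as.numeric(x[2:4])))
    coords[f, , ] <- xyz
  }
  atoms <- read.table(groups_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  structure(list(coords = coords, atoms = atoms, box_edge = box_edge),
            class = "box_trajectory")
}
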