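#' Monte Carlo molecular volume fraction
#'
#' Estimates the fraction of the periodic box lying within a distance
#' threshold of a molecule: at each sampled frame, uniform random points
#' are drawn in the box and the fraction within the threshold
#' (minimum-image) of any selected atom is computed. Molecular
#' flexibility is captured by repeating over randomly chosen frames and
#' reporting the mean and 95% range of the per-frame fractions.
#'
#' @param traj A \code{box_trajectory}, or a numeric matrix (atoms x 3)
#'   for a single static conformation.
#' @param group Which molecule group to measure (\code{"nucleotide"} or
#'   \code{"amino_acid"}); ignored when \code{traj} is a bare matrix.
#' @param box_edge Required when \code{traj} is a matrix; otherwise taken
#'   from the trajectory.
#' @param threshold Distance threshold (Angstrom, default 5).
#' @param n_points Random points per frame (default 100000).
#' @param n_frames Frames to sample (default 150). If this exceeds the
#'   frames available, frames are sampled with replacement with a
#'   warning.
#' @param seed Integer seed.
#' @param atom_subset Optional atom indices (rows of \code{traj$atoms})
#'   restricting the molecule, e.g. to ring nitrogens.
#' @return List of class \code{"volume_fraction"}: \code{mean_fraction},
#'   \code{range95}, \code{per_frame}, and the settings used.
#' @export
volume_fraction <- function(traj, group = "nucleotide", box_edge = NULL,
                            threshold = 5, n_points = 1e5, n_frames = 150,
                            seed = 1L, atom_subset = NULL) {
  assert_scalar_num(threshold, "threshold", lower = 1e-12)
  if (is.matrix(traj)) {
    if (is.null(box_edge))
      stop("`box_edge` is required with a coordinate matrix", call. = FALSE)
    coords <- array(traj, c(1, nrow(traj), 3))
    idx <- seq_len(nrow(traj))
    avail <- 1L
  } else {
    stopifnot(inherits(traj, "box_trajectory"))
    box_edge <- traj$box_edge
    idx <- which(traj$atoms$group == group)
    if (!is.null(atom_subset)) idx <- intersect(idx, atom_subset)
    if (!length(idx))
      stop("no atoms in group `", group, "` after applying atom subset",
           call. = FALSE)
    coords <- traj$coords
    avail <- dim(coords)[1]
  }
  with_seed(seed, {
    if (n_frames > avail) {
      if (avail > 1)   # replicating a single static conformation is exact
        warning("requested ", n_frames, " frames but only ", avail,
                " available; sampling with replacement")
      frames <- sample.int(avail, n_frames, replace = TRUE)
    } else {
      frames <- sample.int(avail, n_frames)
    }
    # one point cloud shared across frames: the 95% range over frames
    # then reflects molecular flexibility, not point-sampling noise
    pts <- matrix(runif(n_points * 3, 0, box_edge), ncol = 3)
    per_frame <- vapply(frames, function(f) {
      atoms <- coords[f, idx, , drop = FALSE]
      dim(atoms) <- c(length(idx), 3)
      within <- rep(FALSE, n_points)
      th2 <- threshold^2
      for (a in seq_len(nrow(atoms))) {
        d <- sweep(pts, 2, atoms[a, ], `-`)
        d <- d - box_edge * round(d / box_edge)
        within <- within | (rowSums(d * d) < th2)
      }
      mean(within)
    }, 0)
    structure(list(mean_fraction = mean(per_frame),
                   range95 = unname(quantile(per_frame, c(0.025, 0.975))),
                   per_frame = per_frame, threshold = threshold,
                   n_points = n_points, n_frames = n_frames,
                   box_edge = box_edge, seed = seed),
              class = "volume_fraction")
  })
}

#' @export
print.volume_fraction <- function(x, ...) {
  cat(sprintf(
    "volume fraction: %.5f [95%% range %.5f-%.5f] (%g pts x %d frames, < %g A)\n",
    x$mean_fraction, x$range95[1], x$range95[2], x$n_points, x$n_frames,
    x$threshold))
  invisible(x)
}

#' Volume-adjust a binding measure
#'
#' Larger molecules spend more time within any distance threshold of each
#' other purely by size: the expected time-within-threshold under the
#' geometric null grows with the molecular volume fraction. This is
#' removed by dividing the raw binding fraction by a volume divisor.
#' The default divisor is the product of the amino-acid and nucleotide
#' mean volume fractions; \code{"sum"} and \code{"aa_only"} are available
#' since the published procedure is ambiguous about whether one combined
#' volume or both were used. Adjusted values are only comparable across
#' systems computed under the same mode.
#'
#' @param measure A \code{binding_measure}.
#' @param v_aa,v_nt \code{volume_fraction} objects (or bare positive
#'   numbers) for the amino acid and nucleotide.
#' @param mode Divisor mode: \code{"product"} (default), \code{"sum"} or
#'   \code{"aa_only"}.
#' @return The measure with elements \code{adjusted} (value),
#'   \code{adjusted_ci95} and \code{divisor_mode} added.
#' @examples
#' m <- structure(list(raw_fraction = 0.2, ci95 = c(NA, NA)),
#'                class = "binding_measure")
#' adjust_binding(m, 0.05, 0.04)$adjusted  # 100
#' @export
adjust_binding <- function(measure, v_aa, v_nt,
                           mode = c("product", "sum", "aa_only")) {
  mode <- match.arg(mode)
  vf <- function(v) if (inherits(v, "volume_fraction")) v$mean_fraction
    else as.numeric(v)
  a <- vf(v_aa)
  b <- vf(v_nt)
  if (!is.finite(a) || a <= 0 || (mode != "aa_only" && (!is.finite(b) || b <= 0)))
    stop("volume fractions must be positive", call. = FALSE)
  div <- switch(mode, product = a * b, sum = a + b, aa_only = a)
  measure$adjusted <- measure$raw_fraction / div
  measure$adjusted_ci95 <- measure$ci95 / div
  measure$divisor_mode <- mode
  measure$divisor <- div
  measure
}
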