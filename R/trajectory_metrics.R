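#' Minimum-image displacement and set distances in an orthorhombic box
#'
#' \code{min_image_set_distance} returns the minimum over all atom pairs
#' of the minimum-image Euclidean distance between two coordinate sets in
#' a periodic cube. Triclinic boxes are out of scope.
#'
#' @param A,B Numeric matrices (atoms x 3).
#' @param box_edge Cube edge (Angstrom).
#' @return A single distance (Angstrom).
#' @keywords internal
min_image_set_distance <- function(A, B, box_edge) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sweep(B, 2, A[i, ], `-`)
    d <- d - box_edge * round(d / box_edge)
    best <- min(best, min(rowSums(d * d)))
  }
  sqrt(best)
}

#' Reduce a box trajectory to a closest-approach distance series
#'
#' For each frame, computes the minimum over amino-acid copies of the
#' minimum-image distance between any selected nucleotide atom and any
#' amino-acid atom: the "closest atom of the closest copy" statistic used
#' as the binding proxy. A restriction of the nucleotide to a subset of
#' its atoms (e.g. ring nitrogens) is supported via \code{atom_subset}.
#'
#' @param traj A \code{box_trajectory} (see [gen_box_trajectory()]).
#' @param atom_subset Optional integer vector of atom indices (rows of
#'   \code{traj$atoms}) restricting the nucleotide side of the distance;
#'   \code{NULL} uses all nucleotide atoms.
#' @param run_id Run identifier stored in the output (default 1).
#' @return A \code{distance_series} data frame (one run).
#' @export
min_distance_series <- function(traj, atom_subset = NULL, run_id = 1L) {
  stopifnot(inherits(traj, "box_trajectory"))
  nt_idx <- which(traj$atoms$group == "nucleotide")
  if (!is.null(atom_subset)) nt_idx <- intersect(nt_idx, atom_subset)
  if (!length(nt_idx))
    stop("no nucleotide atoms left after applying atom subset [",
         paste(atom_subset, collapse = ", "), "]", call. = FALSE)
  copies <- split(which(traj$atoms$group == "amino_acid"),
                  traj$atoms$molecule[traj$atoms$group == "amino_acid"])
  if (!length(copies))
    stop("trajectory contains no amino-acid group", call. = FALSE)
  n_frames <- dim(traj$coords)[1]
  d <- vapply(seq_len(n_frames), function(f) {
    nt <- traj$coords[f, nt_idx, , drop = FALSE]
    dim(nt) <- c(length(nt_idx), 3)
    min(vapply(copies, function(idx) {
      aa <- traj$coords[f, idx, , drop = FALSE]
      dim(aa) <- c(length(idx), 3)
      min_image_set_distance(nt, aa, traj$box_edge)
    }, 0))
  }, 0)
  out <- data.frame(run_id = run_id, frame = seq_len(n_frames),
                    distance = d)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Fraction of frames within the binding threshold
#'
#' Pools all frames across runs and returns the fraction with
#' closest-approach distance strictly below the threshold. Runs
#' contribute frames (not equal weights), so the pooled estimate is the
#' frame-weighted mean of per-run fractions.
#'
#' @param series A \code{distance_series} data frame (>= 1 run).
#' @param threshold Binding threshold in Angstrom (default 5), > 0 unless
#'   exactly 0 (which trivially yields 0).
#' @return List of class \code{"binding_measure"}: \code{raw_fraction},
#'   \code{threshold}, \code{n_runs}, \code{n_frames}, and \code{ci95}
#'   (NA until filled by [bootstrap_ci()]).
#' @export
binding_fraction <- function(series, threshold = 5) {
  if (is.null(series) || !nrow(series))
    stop("empty distance series", call. = FALSE)
  assert_scalar_num(threshold, "threshold", 0)
  structure(list(raw_fraction = mean(series$distance < threshold),
                 threshold = threshold,
                 n_runs = length(unique(series$run_id)),
                 n_frames = nrow(series),
                 ci95 = c(NA_real_, NA_real_), n_boot = NA_integer_),
            class = "binding_measure")
}

#' @export
print.binding_measure <- function(x, ...) {
  cat(sprintf("binding occupancy: %.4f (< %g A, %d runs, %d frames)\n",
              x$raw_fraction, x$threshold, x$n_runs, x$n_frames))
  if (!anyNA(x$ci95))
    cat(sprintf("  bootstrap 95%% interval: [%.4f, %.4f] (%d resamples)\n",
                x$ci95[1], x$ci95[2], x$n_boot))
  invisible(x)
}

#' Bootstrap interval for the pooled binding fraction
#'
#' Treats the parallel runs as individual experiments: resamples runs
#' with replacement \code{n_boot} times, recomputes the pooled fraction
#' in each pseudo-replicate, and returns the 2.5th-97.5th percentile
#' range.
#'
#' @param series A \code{distance_series} with >= 2 runs.
#' @param threshold Binding threshold (Angstrom).
#' @param n_boot Number of bootstrap resamples (default 100000).
#' @param seed Integer seed.
#' @return The corresponding \code{binding_measure} with \code{ci95}
#'   filled in.
#' @export
bootstrap_ci <- function(series, threshold = 5, n_boot = 1e5, seed = 1L) {
  runs <- unique(series$run_id)
  if (length(runs) < 2)
    stop("bootstrap over runs needs >= 2 runs (no between-run variance ",
         "with a single run)", call. = FALSE)
  below <- tapply(series$distance < threshold, series$run_id, sum)
  sizes <- tapply(series$run_id, series$run_id, length)
  k <- as.numeric(below)
  n <- as.numeric(sizes)
  R <- length(k)
  fracs <- with_seed(seed, {
    out <- numeric(n_boot)
    chunk <- max(1L, min(n_boot, floor(2e6 / R)))
    done <- 0L
    while (done < n_boot) {
      m <- min(chunk, n_boot - done)
      idx <- matrix(sample.int(R, m * R, replace = TRUE), nrow = R)
      out[done + seq_len(m)] <- colSums(matrix(k[idx], nrow = R)) /
        colSums(matrix(n[idx], nrow = R))
      done <- done + m
    }
    out
  })
  bm <- binding_fraction(series, threshold)
  bm$ci95 <- unname(quantile(fracs, c(0.025, 0.975)))
  bm$n_boot <- as.integer(n_boot)
  bm
}

#' Proximity histogram of a distance series
#'
#' Normalised frequency of closest-approach distances per bin, optionally
#' divided by a volume divisor from the Monte Carlo volume stage so that
#' distributions are comparable across molecules of different size.
#'
#' @param series A \code{distance_series}.
#' @param bin_width Bin width in Angstrom (> 0).
#' @param max_distance Upper edge of the last bin; defaults to the data
#'   maximum rounded up to a whole bin.
#' @param volume_adjust Optional positive divisor (scalar, or one value
#'   per bin) applied to the normalised frequencies.
#' @return Data frame with columns \code{lower}, \code{upper}, \code{prob}
#'   (sums to 1) and \code{adjusted}.
#' @export
proximity_histogram <- function(series, bin_width = 0.25,
                                max_distance = NULL, volume_adjust = NULL) {
  assert_scalar_num(bin_width, "bin_width", lower = 1e-12)
  max_distance <- max_distance %||%
    (bin_width * ceiling(max(series$distance) / bin_width))
  breaks <- seq(0, max_distance, by = bin_width)
  if (max(breaks) < max_distance) breaks <- c(breaks, max_distance)
  cnt <- tabulate(findInterval(series$distance, breaks,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  prob <- cnt / sum(cnt)
  adj <- prob
  if (!is.null(volume_adjust)) {
    if (any(volume_adjust <= 0))
      stop("`volume_adjust` must be positive", call. = FALSE)
    adj <- prob / volume_adjust
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             prob = prob, adjusted = adj)
}
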