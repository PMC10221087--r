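#' Within-row ranks of a preference matrix
#'
#' Ranks each amino acid's adjusted binding values across nucleotides,
#' with rank 1 the strongest binder. Exact ties receive average ranks, so
#' a row has a strict "first choice" only when a unique entry holds
#' rank 1.
#'
#' @param matrix Numeric matrix: rows = amino acids (rownames required),
#'   columns = nucleotides or dinucleotides. No missing entries allowed.
#' @return Matrix of the same shape containing within-row ranks.
#' @examples
#' m <- rbind(F = c(A = 0.9, C = 0.1, G = 0.1, U = 0.1))
#' rank_rows(m)  # 1, 3, 3, 3
#' @export
rank_rows <- function(matrix) {
  if (anyNA(matrix)) {
    gaps <- which(is.na(matrix), arr.ind = TRUE)
    stop("missing entries at: ",
         paste(sprintf("[%s, %s]",
                       rownames(matrix)[gaps[, 1]] %||% gaps[, 1],
                       colnames(matrix)[gaps[, 2]] %||% gaps[, 2]),
               collapse = ", "), call. = FALSE)
  }
  t(apply(matrix, 1, function(r) rank(-r, ties.method = "average")))
}

#' Exact binomial tail probability for preference counts
#'
#' Tests an observed count of amino acids showing some cognate preference
#' against the null of uniform random preferences. The parameterization
#' (k, n, p, tail) is explicit: enrichment of cognate-first counts uses
#' the upper tail with p = 1/4; depletion (cognate-last) the lower tail;
#' the "best with at least one cognate" test an upper tail at its own p.
#'
#' @param k Observed count, 0 <= k <= n.
#' @param n Number of trials.
#' @param p Null success probability, in (0, 1).
#' @param tail \code{"upper"} for P(X >= k), \code{"lower"} for
#'   P(X <= k).
#' @return The exact tail probability.
#' @examples
#' binomial_preference_test(10, 20, 0.25, "upper")  # 0.0139
#' @export
binomial_preference_test <- function(k, n, p, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!is.numeric(k) || !is.numeric(n) || k != round(k) || n != round(n) ||
      k < 0 || n < 1 || k > n)
    stop("need integer counts with 0 <= k <= n", call. = FALSE)
  assert_scalar_num(p, "p", 0, 1)
  if (p <= 0 || p >= 1) stop("`p` must be in (0, 1)", call. = FALSE)
  if (tail == "upper") pbinom(k - 1, n, p, lower.tail = FALSE)
  else pbinom(k, n, p)
}

# Best (lowest) rank among an allocation's cognate columns; average-rank
# ties mean rank 1 exists only for a strict maximum.
cognate_rank <- function(rank_row, bases) {
  hit <- intersect(bases, names(rank_row))
  if (!length(hit))
    stop("cognate base(s) ", paste(bases, collapse = ","),
         " absent from matrix columns", call. = FALSE)
  min(rank_row[hit])
}

#' First-choice summary against cognate allocations
#'
#' For each allocation, determines whether the amino acid's strict best
#' (and strict worst) binder lies in its cognate base set, and counts,
#' per amino acid, whether the strict best binder is cognate under any of
#' that amino acid's allocations (the union of the supplied cognate
#' sets; pass allocations row-bound across several position schemes to
#' reproduce the "at least one codonic or anticodonic cognate" count).
#'
#' @param rank_matrix From [rank_rows()]; rownames are amino acids.
#' @param allocations From [expand_assignments()] (possibly row-bound
#'   across position schemes).
#' @return List: \code{per_allocation} data frame with logical
#'   \code{cognate_first} / \code{cognate_last}; counts
#'   \code{n_cognate_first}, \code{n_cognate_last},
#'   \code{n_best_any_cognate} (per amino acid), \code{n_allocations},
#'   \code{n_amino_acids}.
#' @export
first_choice_summary <- function(rank_matrix, allocations) {
  nb <- ncol(rank_matrix)
  per <- allocations[, c("amino_acid", "prefix", "position")]
  per$cognate_first <- per$cognate_last <- NA
  for (i in seq_len(nrow(allocations))) {
    row <- rank_matrix[allocations$amino_acid[i], ]
    bases <- allocations$cognate[[i]]
    best <- names(row)[row == 1]      # empty when tied at the top
    worst <- names(row)[row == nb]
    per$cognate_first[i] <- length(best) == 1 && best %in% bases
    per$cognate_last[i] <- length(worst) == 1 && worst %in% bases
  }
  union_by_aa <- lapply(split(allocations$cognate, allocations$amino_acid),
                        function(x) unique(unlist(x)))
  any_best <- vapply(names(union_by_aa), function(aa) {
    row <- rank_matrix[aa, ]
    best <- names(row)[row == 1]
    length(best) == 1 && best %in% union_by_aa[[aa]]
  }, TRUE)
  list(per_allocation = per,
       n_cognate_first = sum(per$cognate_first),
       n_cognate_last = sum(per$cognate_last),
       n_best_any_cognate = sum(any_best),
       n_allocations = nrow(allocations),
       n_amino_acids = length(union_by_aa))
}

#' Sum-of-ranks score for cognate allocations
#'
#' Sums, over allocations, the rank of the cognate base (the best rank
#' when an allocation's cognate set holds several bases). With 20 amino
#' acids and four nucleotides the best case is 1 x 20 = 20 and the worst
#' 4 x 20 = 80; hexacodonic expansion to 23 allocations raises the
#' minimum to 23. Lower scores mean stronger collective cognate
#' preference.
#'
#' @inheritParams first_choice_summary
#' @return The observed sum (numeric; ties can make it non-integer).
#' @export
rank_sum_score <- function(rank_matrix, allocations) {
  sum(vapply(seq_len(nrow(allocations)), function(i)
    cognate_rank(rank_matrix[allocations$amino_acid[i], ],
                 allocations$cognate[[i]]), 0))
}

#' Randomization null for the sum-of-ranks score
#'
#' Generates the null distribution of the score by assigning each
#' allocation an independent uniform rank from 1..n_columns and summing,
#' repeated \code{n_randomizations} times. With
#' \code{dinucleotide_constraint = TRUE}, an amino acid's multiple
#' cognate dinucleotide allocations are never assigned identical ranks
#' within one draw (sampled without replacement within the amino acid).
#'
#' @param observed The observed sum from [rank_sum_score()].
#' @param allocations The allocation table (used for the count and, with
#'   the constraint, for grouping by amino acid).
#' @param n_columns Number of rankable columns (4 for mononucleotides).
#' @param n_randomizations Number of null draws (default 200000).
#' @param seed Integer seed.
#' @param dinucleotide_constraint Logical; warn-and-ignore when requested
#'   with \code{n_columns = 4} (mononucleotide scheme).
#' @return List of class \code{"rank_score"}: \code{observed},
#'   \code{null_sums}, \code{null_mean}, \code{frac_stronger} (fraction
#'   of null sums strictly greater than observed, i.e. the fraction of
#'   randomised pairings the observed preference beats), \code{p_le}
#'   (fraction of null sums <= observed, the enrichment p-value),
#'   \code{frac_ge} (fraction >= observed), plus settings.
#' @export
randomization_null <- function(observed, allocations, n_columns = 4,
                               n_randomizations = 2e5, seed = 1L,
                               dinucleotide_constraint = FALSE) {
  if (n_randomizations < 1)
    stop("`n_randomizations` must be >= 1", call. = FALSE)
  n_alloc <- nrow(allocations)
  if (dinucleotide_constraint && n_columns == 4) {
    warning("dinucleotide constraint ignored for the mononucleotide scheme")
    dinucleotide_constraint <- FALSE
  }
  sums <- with_seed(seed, {
    draws <- matrix(sample.int(n_columns, n_alloc * n_randomizations,
                               replace = TRUE), nrow = n_alloc)
    if (dinucleotide_constraint) {
      groups <- split(seq_len(n_alloc), allocations$amino_acid)
      for (g in groups[lengths(groups) > 1]) {
        if (length(g) == 2) {
          # uniform pair without replacement: shift the second draw past
          # the first
          r2 <- sample.int(n_columns - 1, n_randomizations, replace = TRUE)
          draws[g[2], ] <- r2 + (r2 >= draws[g[1], ])
        } else {
          for (j in seq_len(n_randomizations))
            draws[g, j] <- sample.int(n_columns, length(g))
        }
      }
    }
    colSums(draws)
  })
  structure(list(observed = observed, null_sums = sums,
                 null_mean = mean(sums),
                 frac_stronger = mean(sums > observed),
                 p_le = mean(sums <= observed),
                 frac_ge = mean(sums >= observed),
                 n_allocations = n_alloc, n_columns = n_columns,
                 n_randomizations = n_randomizations, seed = seed,
                 dinucleotide_constraint = dinucleotide_constraint),
            class = "rank_score")
}

#' @export
print.rank_score <- function(x, ...) {
  cat(sprintf(
    "sum-of-ranks %.1f over %d allocations (null mean %.1f, %g draws)\n",
    x$observed, x$n_allocations, x$null_mean, x$n_randomizations))
  cat(sprintf("  stronger than %.1f%% of randomised assignments (p = %.4g)\n",
              100 * x$frac_stronger, x$p_le))
  invisible(x)
}

#' Compare binding between the two orientations of a dinucleotide
#'
#' Directionality test: the difference in binding fraction between the
#' XY and YX orientations of a dinucleotide with the same amino acid,
#' with a bootstrap interval obtained by resampling runs independently
#' within each orientation. Pairs whose interval excludes 0 are flagged.
#'
#' @param series_xy,series_yx \code{distance_series} for the two
#'   orientations (each >= 2 runs).
#' @param threshold Binding threshold (Angstrom).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List: \code{difference} (XY minus YX pooled fractions),
#'   \code{ci95}, \code{excludes_zero}, per-orientation fractions.
#' @export
directionality_compare <- function(series_xy, series_yx, threshold = 5,
                                   n_boot = 1e4, seed = 1L) {
  if (is.null(series_xy) || is.null(series_yx) ||
      !nrow(series_xy) || !nrow(series_yx))
    stop("both orientations must be supplied", call. = FALSE)
  stat <- function(s) {
    k <- as.numeric(tapply(s$distance < threshold, s$run_id, sum))
    n <- as.numeric(tapply(s$run_id, s$run_id, length))
    list(k = k, n = n, frac = sum(k) / sum(n))
  }
  a <- stat(series_xy)
  b <- stat(series_yx)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(length(a$k), replace = TRUE)
      ib <- sample.int(length(b$k), replace = TRUE)
      sum(a$k[ia]) / sum(a$n[ia]) - sum(b$k[ib]) / sum(b$n[ib])
    }, 0)
  })
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  list(difference = a$frac - b$frac, ci95 = ci,
       excludes_zero = ci[1] > 0 || ci[2] < 0,
       fraction_xy = a$frac, fraction_yx = b$frac)
}
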