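#' Construct a hydrophobicity scale object
#'
#' @param values Named numeric vector, one value per amino acid (1-letter
#'   codes).
#' @param name Scale label.
#' @param higher_is_hydrophobic Orientation flag: \code{TRUE} when larger
#'   values mean more hydrophobic (e.g. Kyte-Doolittle), \code{FALSE}
#'   for hydrophilicity scales (e.g. Hopp-Woods).
#' @return List of class \code{"hydro_scale"}.
#' @export
hydrophobicity_scale <- function(values, name,
                                 higher_is_hydrophobic = TRUE) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(list(name = name, values = values,
                 higher_is_hydrophobic = isTRUE(higher_is_hydrophobic)),
            class = "hydro_scale")
}

#' Built-in hydrophobicity scales
#'
#' A small set of widely used published scales shipped as fixtures
#' (Kyte-Doolittle, Hopp-Woods, Eisenberg consensus, Janin). The exact
#' 43-scale compilation used for the published composite is external
#' data; supply it via [read_hydrophobicity_scale()] to reproduce that
#' composite exactly.
#'
#' @return Named list of \code{hydro_scale} objects.
#' @export
builtin_hydrophobicity_scales <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  hw <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2,
          E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
          M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4,
          Y = -2.3, V = -1.5)
  ei <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
          E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
          M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
          Y = 0.26, V = 1.08)
  ja <- c(A = 0.3, R = -1.4, N = -0.5, D = -0.6, C = 0.9, Q = -0.7,
          E = -0.7, G = 0.3, H = -0.1, I = 0.7, L = 0.5, K = -1.8,
          M = 0.4, F = 0.5, P = -0.3, S = -0.1, T = -0.2, W = 0.3,
          Y = -0.4, V = 0.6)
  list(kyte_doolittle = hydrophobicity_scale(kd, "Kyte-Doolittle", TRUE),
       hopp_woods = hydrophobicity_scale(hw, "Hopp-Woods", FALSE),
       eisenberg = hydrophobicity_scale(ei, "Eisenberg consensus", TRUE),
       janin = hydrophobicity_scale(ja, "Janin", TRUE))
}

#' Read a hydrophobicity scale from tabular text
#'
#' @param path File with columns \code{amino_acid} (1-letter code) and
#'   \code{value}.
#' @param name Scale label (defaults to the file name).
#' @param higher_is_hydrophobic Orientation flag.
#' @return A \code{hydro_scale}.
#' @export
read_hydrophobicity_scale <- function(path, name = basename(path),
                                      higher_is_hydrophobic = TRUE) {
  if (!file.exists(path))
    stop("scale file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "value") %in% names(tab)))
    stop("scale table must have columns `amino_acid` and `value`",
         call. = FALSE)
  v <- tab$value
  names(v) <- tab$amino_acid
  hydrophobicity_scale(v, name, higher_is_hydrophobic)
}

#' Composite hydrophobicity rank across scales
#'
#' Within each scale, amino acids are ranked with 1 = most hydrophobic
#' (respecting each scale's orientation flag; ties averaged); the
#' composite is the mean rank across scales. Invariant to monotone
#' transformations of any scale's values.
#'
#' @param scales List of \code{hydro_scale} objects covering a common
#'   residue set.
#' @return Named numeric vector of mean ranks (1 = most hydrophobic),
#'   sorted by rank.
#' @export
composite_rank <- function(scales) {
  if (!length(scales)) stop("need at least one scale", call. = FALSE)
  residues <- sort(unique(unlist(lapply(scales, function(s)
    names(s$values)))))
  ranks <- vapply(scales, function(s) {
    miss <- setdiff(residues, names(s$values))
    if (length(miss))
      stop("scale `", s$name, "` is missing residue(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    v <- s$values[residues]
    if (s$higher_is_hydrophobic) rank(-v, ties.method = "average")
    else rank(v, ties.method = "average")
  }, numeric(length(residues)))
  out <- rowMeans(ranks)
  names(out) <- residues
  sort(out)
}

#' Regress adjusted binding on volume and hydrophobicity covariates
#'
#' Ordinary least-squares fit of per-amino-acid binding against
#' covariates such as amino-acid volume fraction, nucleotide volume
#' fraction, and (composite) hydrophobicity, reporting the slope,
#' standard error and p-value per covariate. Run once per nucleotide and
#' charge state to reproduce the per-system regressions; loop over
#' single scales for per-scale comparisons.
#'
#' @param binding Named numeric vector (amino acid -> adjusted binding).
#' @param covariates Data frame of covariates with rownames (or a column
#'   \code{amino_acid}) matching \code{binding}'s names.
#' @return List: \code{coefficients} data frame (estimate, std.error,
#'   p.value per term), \code{r_squared}, \code{fit} (the \code{lm}
#'   object).
#' @export
regress_binding <- function(binding, covariates) {
  if (!is.null(covariates$amino_acid)) {
    rownames(covariates) <- covariates$amino_acid
    covariates$amino_acid <- NULL
  }
  aa <- names(binding)
  if (is.null(aa) || !all(aa %in% rownames(covariates)))
    stop("`binding` names must match covariate rows", call. = FALSE)
  df <- cbind(binding = unname(binding), covariates[aa, , drop = FALSE])
  if (nrow(df) < ncol(covariates) + 2)
    stop("need at least ", ncol(covariates) + 2, " observations for ",
         ncol(covariates), " covariates", call. = FALSE)
  X <- stats::model.matrix(binding ~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    kap <- kappa(X)
    stop("collinear covariates (design rank ", qrX$rank, " < ", ncol(X),
         ", condition number ", format(kap, digits = 3), ")",
         call. = FALSE)
  }
  fit <- lm(binding ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1],
                                 std.error = sm[, 2],
                                 p.value = sm[, 4],
                                 row.names = NULL),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}
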