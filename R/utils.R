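#' @importFrom stats rnorm runif rgeom quantile pbinom coef lm qnorm sd
#' @importFrom utils read.table write.table packageVersion
NULL

# RNA alphabet used throughout; order fixed so rank matrices are reproducible
RNA_BASES <- c("A", "C", "G", "U")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state. All exported stochastic functions
# route through this so a seed argument never clobbers the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed per worker/run, kept well inside 32-bit range
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483587)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
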