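# Independent oracles shared across tests. These deliberately avoid the
# package's own code paths.

# Minimum-image distance by exhaustive search over all 27 periodic images
brute_min_image_dist <- function(A, B, box) {
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * box
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    for (s in seq_len(nrow(shifts))) {
      d <- A[i, ] - (B[j, ] + shifts[s, ])
      best <- min(best, sqrt(sum(d^2)))
    }
  best
}

# Bound-state complex concentration from the quadratic, solved with
# polyroot (independent of the closed form in the package)
oracle_bound_fraction <- function(P, L, KD) {
  roots <- Re(polyroot(c(P * L, -(KD + P + L), 1)))
  complex <- min(roots[roots >= 0])
  complex / P
}

# Standard error of the pooled occupancy estimate from a stationary
# two-state chain with geometric dwells
two_state_se <- function(p, dwell_bound, n_total) {
  dwell_free <- dwell_bound * (1 - p) / p
  lambda <- 1 - 1 / dwell_bound - 1 / dwell_free
  sqrt(p * (1 - p) * (1 + lambda) / (1 - lambda) / n_total)
}

# Brute-force upper/lower binomial tails by enumerating all 4^n outcomes
# (success = 1 of the 4 equally likely symbols)
brute_binom_tail <- function(k, n, tail) {
  grid <- as.matrix(expand.grid(rep(list(1:4), n)))
  hits <- rowSums(grid == 1)
  if (tail == "upper") mean(hits >= k) else mean(hits <= k)
}

# A tiny complete preference matrix with known structure: each amino
# acid's strict best binder is the base named in `best` (named vector)
toy_matrix <- function(best, columns = c("A", "C", "G", "U"),
                       seed = 1) {
  set.seed(seed)
  m <- matrix(runif(length(best) * length(columns), 0, 0.5),
              length(best), length(columns),
              dimnames = list(names(best), columns))
  for (aa in names(best)) m[aa, best[aa]] <- 1
  m
}
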