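test_that("distance series generator hits the planted occupancy", {
  # zero occupancy: every frame at or beyond the threshold
  s0 <- gen_distance_series(0, n_runs = 3, n_frames = 500, seed = 1)
  expect_true(all(s0$distance >= 5))
  s1 <- gen_distance_series(1, n_runs = 2, n_frames = 500, seed = 1)
  expect_true(all(s1$distance < 5))
  # stationary occupancy within 3 chain-aware standard errors
  s <- gen_distance_series(0.3, n_runs = 20, n_frames = 5000, seed = 7)
  se <- two_state_se(0.3, 20, nrow(s))
  expect_lt(abs(mean(s$distance < 5) - 0.3), 3 * se)
})

test_that("generators are pure functions of their seed", {
  a <- gen_distance_series(0.4, n_runs = 3, n_frames = 200, seed = 11)
  b <- gen_distance_series(0.4, n_runs = 3, n_frames = 200, seed = 11)
  expect_identical(a, b)
  c <- gen_distance_series(0.4, n_runs = 3, n_frames = 200, seed = 12)
  expect_false(identical(a$distance, c$distance))
  t1 <- gen_box_trajectory(n_frames = 4, seed = 3)
  t2 <- gen_box_trajectory(n_frames = 4, seed = 3)
  expect_identical(t1$coords, t2$coords)
  g1 <- gen_titration(2, 0.1, noise_sd = 0.01, seed = 5)
  g2 <- gen_titration(2, 0.1, noise_sd = 0.01, seed = 5)
  expect_identical(g1$shift, g2$shift)
  # a seed argument must not disturb the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(gen_distance_series(0.2, 2, 50, seed = 1))
  expect_identical(runif(1), x)
})

test_that("bound and free distance modes respect the threshold", {
  s <- gen_distance_series(0.5, n_runs = 5, n_frames = 2000, seed = 2)
  below <- s$distance[s$distance < 5]
  above <- s$distance[s$distance >= 5]
  expect_true(all(below > 0))
  # the three bound modes should all be populated
  expect_gt(sum(below < 2.2), 0)
  expect_gt(sum(below > 2.2 & below < 3.2), 0)
  expect_gt(sum(below > 3.5), 0)
  # free mode: N(5.5, 1) left-truncated at 5 has mean
  # 5.5 + dnorm(-0.5) / pnorm(0.5) = 6.009
  mu_trunc <- 5.5 + dnorm(-0.5) / pnorm(0.5)
  expect_lt(abs(mean(above) - mu_trunc), 0.1)
  expect_error(gen_distance_series(1.2), "occupancy")
})

test_that("box trajectory respects periodic geometry", {
  expect_error(gen_box_trajectory(box_edge = -1), "box_edge")
  tr <- gen_box_trajectory(n_frames = 10, seed = 4)
  expect_true(all(tr$coords >= 0 & tr$coords < tr$box_edge))
  # single-atom molecules, one frame: closest approach equals the
  # minimum-image Euclidean distance; periodic wrap example sqrt(12)
  d <- min_image_set_distance(matrix(c(1, 1, 1), 1),
                              matrix(c(39, 39, 39), 1), 40)
  expect_equal(d, sqrt(12))
})

test_that("null box occupancy matches brute-force random placement", {
  # fast mixing (large steps) so frames are nearly independent draws
  tr <- gen_box_trajectory(n_copies = 5, n_frames = 1500,
                           atoms_nucleotide = 3, atoms_amino = 2,
                           radius_nucleotide = 1.5, radius_amino = 1,
                           step_sd = 25, attraction = 0, seed = 8)
  ds <- min_distance_series(tr)
  frac <- mean(ds$distance < 5)
  # oracle: uniform random placement of the same rigid clusters
  set.seed(80)
  n_draws <- 3e4
  draw_cluster <- function(n, r) {
    off <- matrix(rnorm(n * 3), ncol = 3)
    off <- off / sqrt(rowSums(off^2)) * (r * runif(n)^(1 / 3))
    sweep(off, 2, runif(3, 0, 40), `+`) %% 40
  }
  hits <- vapply(seq_len(n_draws), function(i) {
    nt <- draw_cluster(3, 1.5)
    any(vapply(1:5, function(m)
      min_image_set_distance(nt, draw_cluster(2, 1), 40) < 5, TRUE))
  }, TRUE)
  p0 <- mean(hits)
  # random-walk frames are correlated; allow a generous band around the
  # geometric null
  expect_lt(abs(frac - p0), 0.05)
})

test_that("attraction raises time within the well above the null", {
  base <- gen_box_trajectory(n_copies = 4, n_frames = 800, step_sd = 8,
                             attraction = 0, seed = 21)
  att <- gen_box_trajectory(n_copies = 4, n_frames = 800, step_sd = 8,
                            attraction = 3, seed = 21)
  f0 <- mean(min_distance_series(base)$distance < 5)
  f1 <- mean(min_distance_series(att)$distance < 5)
  expect_gt(f1, f0)
})

test_that("titration generator follows the exact isotherm", {
  # no ligand, no complex
  g <- gen_titration(5, 0.2, L_totals = c(1e-9, 1, 10), noise_sd = 0)
  expect_lt(g$shift[1], 1e-6)
  # KD = 0 with excess ligand saturates at dmax
  g2 <- gen_titration(0, 0.2, L_totals = c(1, 10), noise_sd = 0)
  expect_equal(g2$shift, c(0.2, 0.2))
  # oracle: exact quadratic for the complex concentration
  g3 <- gen_titration(5, 1, P_total = 0.1, L_totals = 10, noise_sd = 0)
  expect_equal(g3$shift, oracle_bound_fraction(0.1, 10, 5),
               tolerance = 1e-10)
  expect_equal(round(g3$shift, 3), 0.665)
  expect_error(gen_titration(5, 1, noise_sd = -1), "noise_sd")
})

test_that("distance series and trajectories round-trip through text", {
  s <- gen_distance_series(0.3, n_runs = 2, n_frames = 50, seed = 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_distance_series(s, p)
  back <- read_distance_series(p)
  expect_equal(back$distance, s$distance, tolerance = 1e-12)
  expect_equal(back$run_id, s$run_id)
  tr <- gen_box_trajectory(n_frames = 3, n_copies = 2, seed = 9)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  grp <- withr::local_tempfile(fileext = ".tsv")
  write_box_trajectory(tr, xyz, grp)
  tb <- read_box_trajectory(xyz, grp)
  expect_equal(tb$box_edge, tr$box_edge)
  expect_equal(tb$coords, tr$coords, tolerance = 1e-5)
  expect_equal(tb$atoms$group, tr$atoms$group)
})
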