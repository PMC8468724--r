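# MD post-analysis: energy drift, RMSF, distances, hydrogen bonds.

toy_hbond_traj <- function(coords_list) {
  # 1 protein donor-H pair + 1 ligand acceptor, coordinates per frame as
  # list of 3x3 matrices (rows: donor, hydrogen, acceptor)
  atoms <- data.frame(
    atom_id = 1:3, residue_id = c(1, 1, 99),
    residue_name = c("SER", "SER", "LIG"), chain = c("A", "A", "X"),
    element = c("O", "H", "O"),
    role = c("donor", "hydrogen", "acceptor"),
    ligand = c(FALSE, FALSE, TRUE), bonded_to = c(NA, 1, NA))
  co <- array(0, dim = c(length(coords_list), 3, 3))
  for (f in seq_along(coords_list)) co[f, , ] <- coords_list[[f]]
  trajectory(seq(0, by = 10, length.out = length(coords_list)), co, atoms)
}

test_that("a drift-free energy series passes the 1% tolerance", {
  set.seed(1)
  tms <- seq(0, 990, by = 10)
  e <- rnorm(100, 1000, 0.5)
  d <- energy_drift(e, tms)
  expect_true(d$pass)
  expect_lt(abs(d$relative_drift), 0.01)
})

test_that("a strongly drifting energy series fails the tolerance", {
  tms <- seq(0, 990, by = 10)
  e <- 1000 + 0.1 * tms
  d <- energy_drift(e, tms)
  expect_false(d$pass)
  expect_equal(d$slope_per_ns, 100, tolerance = 1e-8)
})

test_that("drift check rejects degenerate input", {
  expect_error(energy_drift(rnorm(5), 1:5), "10")
  expect_error(energy_drift(rnorm(10), rep(1, 10)), "constant")
})

test_that("frozen residues have exactly zero RMSF", {
  g <- gen_trajectory(5, n_residues = 6, n_frames = 40, sigma = 0)
  r <- rmsf(g$trajectory, superpose = FALSE)
  expect_equal(r$rmsf, rep(0, 6))
})

test_that("RMSF recovers the planted isotropic jitter amplitude", {
  g <- gen_trajectory(11, n_residues = 10, n_frames = 10000, sigma = 0.5)
  r <- rmsf(g$trajectory, superpose = FALSE)
  expected <- 0.5 * sqrt(3)
  expect_true(all(abs(r$rmsf - expected) / expected < 0.02))
})

test_that("RMSF matches a brute-force double loop", {
  g <- gen_trajectory(23, n_residues = 4, n_frames = 30, sigma = 1)
  r <- rmsf(g$trajectory, superpose = FALSE)
  X <- g$trajectory$coords
  for (a in 1:4) {
    P <- X[, a, ]
    mu <- colMeans(P)
    msd <- mean((P[, 1] - mu[1])^2 + (P[, 2] - mu[2])^2 +
                  (P[, 3] - mu[3])^2)
    expect_equal(r$rmsf[a], sqrt(msd), tolerance = 1e-10)
  }
})

test_that("superposition removes planted rigid-body motion", {
  g <- gen_trajectory(7, n_residues = 8, n_frames = 50, sigma = 0)
  X <- g$trajectory$coords
  # translate every frame by a different offset: raw RMSF inflates,
  # superposed RMSF stays zero
  for (f in seq_len(dim(X)[1])) X[f, , ] <- X[f, , ] + (f - 1) * 0.2
  tr <- trajectory(g$trajectory$times, X, g$trajectory$atoms)
  raw <- rmsf(tr, superpose = FALSE)
  fit <- rmsf(tr, superpose = TRUE)
  expect_gt(min(raw$rmsf), 1)
  expect_lt(max(fit$rmsf), 1e-8)
})

test_that("planted contact fraction is recovered exactly", {
  g <- gen_trajectory(13, n_frames = 500, frac_within = 0.164)
  md <- min_distance_series(g$trajectory, "A:THR:1")
  expect_equal(fraction_within(md), 0.164)
})

test_that("fraction_within uses a strict inequality at the cutoff", {
  series <- c(4.9, 5.0, 5.1)
  expect_equal(fraction_within(series), 1 / 3)
})

test_that("minimum distance matches a brute-force pair scan", {
  g <- gen_trajectory(3, n_residues = 5, n_frames = 20, sigma = 1,
                      frac_within = 0.5)
  md <- min_distance_series(g$trajectory, "A:THR:1")
  X <- g$trajectory$coords
  lig <- which(g$trajectory$atoms$ligand)
  res <- which(g$trajectory$atoms$residue_id == 1 &
                 !g$trajectory$atoms$ligand)
  for (f in c(1, 10, 20)) {
    dists <- outer(res, lig, Vectorize(function(i, j)
      sqrt(sum((X[f, i, ] - X[f, j, ])^2))))
    expect_equal(md$d_min[f], min(dists), tolerance = 1e-10)
  }
})

test_that("distance distribution integrates to one", {
  g <- gen_trajectory(4, n_frames = 200, frac_within = 0.3)
  md <- min_distance_series(g$trajectory, "A:THR:1")
  dd <- distance_distribution(md)
  area <- sum(dd$y) * diff(dd$x)[1]
  expect_equal(area, 1, tolerance = 0.01)
})

test_that("hydrogen bonds obey the distance and angle cutoffs", {
  near_straight <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  too_far <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0))
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0))  # ~90 deg H-D-A
  tr <- toy_hbond_traj(list(near_straight, too_far, bent))
  hb <- detect_hbonds(tr)
  expect_equal(as.vector(hb$existence), c(1L, 0L, 0L))
})

test_that("hydrogen-bond detection is invariant to rotation and translation", {
  set.seed(41)
  geoms <- lapply(1:50, function(i) matrix(rnorm(9, sd = 2), 3, 3))
  base <- detect_hbonds(toy_hbond_traj(geoms))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(5, -3, 11)
  moved <- lapply(geoms, function(G) sweep(G %*% t(R), 2, shift, `+`))
  transformed <- detect_hbonds(toy_hbond_traj(moved))
  expect_equal(base$existence, transformed$existence)
})

test_that("hydrogen-bond detection matches a brute-force oracle", {
  set.seed(42)
  n <- 1000
  geoms <- lapply(seq_len(n), function(i) {
    D <- rnorm(3, sd = 1.5)
    H <- D + rnorm(3, sd = 0.8)
    A <- D + rnorm(3, sd = 2.5)
    rbind(D, H, A)
  })
  tr <- toy_hbond_traj(geoms)
  hb <- detect_hbonds(tr, r_cut = 3.5, angle_cut = 30)
  oracle <- vapply(geoms, function(G) {
    d <- sqrt(sum((G[1, ] - G[3, ])^2))
    v1 <- G[2, ] - G[1, ]; v2 <- G[3, ] - G[1, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    as.integer(d <= 3.5 && ang <= 30)
  }, integer(1))
  expect_equal(as.vector(hb$existence), oracle)
})

test_that("a donor without an attached hydrogen is an error", {
  atoms <- data.frame(
    atom_id = 1:2, residue_id = c(1, 99),
    residue_name = c("SER", "LIG"), chain = c("A", "X"),
    element = c("O", "O"), role = c("donor", "acceptor"),
    ligand = c(FALSE, TRUE), bonded_to = NA)
  co <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  tr <- trajectory(c(0, 10), co, atoms)
  expect_error(detect_hbonds(tr), "hydrogen")
})

test_that("occupancy statistics recover exactly planted occupancies", {
  occ <- c("A:ASP:10" = 0.40, "A:SER:20" = 0.25, "A:LYS:30" = 0.10)
  gh <- gen_hbond_matrix(occ, n_frames = 100, seed = 3)
  os <- occupancy_stats(gh$matrix)
  expect_equal(os$per_residue[names(occ)], occ)
  expect_equal(os$frac_any, unname(gh$truth$frac_any))
  expect_equal(os$frac_two_residues, unname(gh$truth$frac_two_residues))
})

test_that("simultaneity never exceeds single-bond occupancy", {
  for (seed in 1:5) {
    occ <- c("A:ASP:10" = 0.5, "A:SER:20" = 0.3)
    gh <- gen_hbond_matrix(occ, n_frames = 200, seed = seed,
                           mode = "bernoulli")
    os <- occupancy_stats(gh$matrix)
    expect_lte(os$frac_two_residues, os$frac_any)
    expect_lte(os$frac_any, 1)
    expect_gte(os$frac_any, max(os$per_residue))
  }
})

test_that("binned hydrogen-bond counts use inclusive 10-20 boundaries", {
  occ <- c("A:ASP:10" = 0.20, "A:SER:20" = 0.10)
  gh <- gen_hbond_matrix(occ, n_frames = 100, seed = 1)
  bc <- binned_hbond_counts(gh$matrix, bin_width = 0.2)  # 20 frames per bin
  expect_equal(unname(bc$counts[, 1]), c(20, 10))
  expect_equal(unname(bc$category[, 1]), c("10-20", "10-20"))
  expect_equal(unname(bc$category[, 2]), c("<10", "<10"))
})

test_that("bin widths that do not divide the run are rejected", {
  gh <- gen_hbond_matrix(c("A:ASP:10" = 0.4), n_frames = 100, seed = 2)
  expect_error(binned_hbond_counts(gh$matrix, bin_width = 0.33))
  expect_error(binned_hbond_counts(gh$matrix, bin_width = 0.001))
})

test_that("trajectories round-trip through disk", {
  g <- gen_trajectory(6, n_residues = 4, n_frames = 10, sigma = 0.4)
  f <- tempfile(); fa <- tempfile()
  write_trajectory(g$trajectory, f, fa)
  back <- read_trajectory(f, fa)
  expect_equal(back$coords, g$trajectory$coords, tolerance = 1e-12)
  expect_equal(back$times, g$trajectory$times)
  expect_equal(back$atoms$residue_id, g$trajectory$atoms$residue_id)
})
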