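two_node_tm <- function() tm_from_counts(matrix(c(0, 3, 3, 0), 2))

test_that("uniform perturbations spread mass equally over the site", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  p3 <- uniform_perturbation(tm, c("B:1", "B:13", "B:3"))
  expect_equal(sum(p3$p0), 1)
  expect_equal(sort(unique(p3$p0)), c(0, 1 / 3))
  p1 <- uniform_perturbation(tm, "B:13")
  expect_equal(p1$p0[p1$index], 1)
  expect_equal(sum(p1$p0 > 0), 1)
  p6 <- uniform_perturbation(tm, residue_key("B", 1:6))
  expect_equal(sum(p6$p0 == 1 / 6), 6)
  expect_error(uniform_perturbation(tm, c("B:13", "Z:99", "Q:1")), "Z:99")
})

test_that("2-state relaxation matches the closed form 1/2 + exp(-2t)/2", {
  tm <- two_node_tm()
  times <- time_grid(1e-3, 10, 60)
  traj <- propagate(tm, c(1, 0), times)
  expect_equal(traj$P[1, ], 0.5 + 0.5 * exp(-2 * times), tolerance = 1e-10)
  expect_equal(traj$P[2, ], 0.5 - 0.5 * exp(-2 * times), tolerance = 1e-10)
  # flux closed forms: f1 = -exp(-2t) (outflow), f2 = +exp(-2t) (inflow)
  expect_equal(traj$F[1, ], -exp(-2 * times), tolerance = 1e-10)
  expect_equal(traj$F[2, ], exp(-2 * times), tolerance = 1e-10)
})

test_that("signed flux-peak convention on the 2-state system", {
  tm <- two_node_tm()
  times <- time_grid(1e-3, 10, 60)
  traj <- propagate(tm, c(1, 0), times)
  mt <- max_flux_time(traj)
  # perturbed node: flux is negative throughout; its signed maximum sits at
  # the end of the grid (weakest outflow), |f| would peak at t = 0
  expect_equal(mt$max_flux_time[1], times[length(times)])
  expect_equal(max_flux_time(traj, signed = FALSE)$max_flux_time[1], 0)
  # receiving node: inflow peaks at the first grid point
  expect_equal(mt$max_flux_time[2], 0)
})

test_that("initial condition is reproduced exactly at t = 0", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  pert <- uniform_perturbation(tm, c("B:13", "B:1"))
  traj <- propagate(tm, pert, time_grid(n = 20))
  expect_equal(traj$P[, 1], pert$p0, tolerance = 1e-12)
})

test_that("starting at equilibrium is stationary with zero flux", {
  fx <- make_fixture("ring_pentamer", n_residues_per_chain = 8)
  tm <- build_transition_model(count_contacts(fx$model))
  pi_eq <- equilibrium_distribution(tm)
  traj <- propagate(tm, pi_eq, time_grid(n = 25))
  expect_lt(max(abs(traj$P - pi_eq)), 1e-10)
  expect_lt(max(abs(traj$F)), 1e-10)
})

test_that("probability is conserved, non-negative, and flux sums to zero", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  traj <- propagate(tm, uniform_perturbation(tm, "B:13"), time_grid(n = 100))
  expect_lt(max(abs(colSums(traj$P) - 1)), 1e-9)
  expect_lt(max(abs(colSums(traj$F))), 1e-9)
  expect_gt(min(traj$P), -1e-12)
  expect_lte(max(traj$P), 1 + 1e-12)
  expect_lte(max(abs(traj$normalized_F)), 1)
})

test_that("equilibrium is the contact-degree distribution", {
  expect_equal(equilibrium_distribution(two_node_tm()), c(0.5, 0.5))
  # 3-node chain, n12 = 2, n23 = 6: degrees (2, 8, 6)
  n3 <- matrix(c(0, 2, 0, 2, 0, 6, 0, 6, 0), 3)
  expect_equal(equilibrium_distribution(tm_from_counts(n3)),
               c(0.125, 0.5, 0.375))
  # closed form vs left-eigenvector of M to 1e-10
  fx <- make_fixture("random_cloud", n_residues_per_chain = 40,
                     spacing = 2.5, seed = 3)
  tm <- build_transition_model(count_contacts(fx$model))
  pi_eq <- equilibrium_distribution(tm)
  e <- eigen(t(as.matrix(tm$M)))
  i1 <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i1]); v <- v / sum(v)
  expect_equal(pi_eq, v, tolerance = 1e-10, ignore_attr = TRUE)
  # long-time propagation converges to it
  traj <- propagate(tm, uniform_perturbation(tm, "A:1"), c(0, 500))
  expect_lt(max(abs(traj$P[, 2] - pi_eq)), 1e-6)
  # disconnected graph has no unique equilibrium
  n <- matrix(0, 4, 4); n[1, 2] <- n[2, 1] <- 1; n[3, 4] <- n[4, 3] <- 1
  expect_error(equilibrium_distribution(tm_from_counts(n)), "components")
})

test_that("detailed balance holds on the contact-degree equilibrium", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  pi_eq <- equilibrium_distribution(tm)
  M <- as.matrix(tm$M)
  expect_lt(max(abs(pi_eq * M - t(pi_eq * M))), 1e-12)
})

test_that("spectral propagation agrees with the dense matrix exponential", {
  fx <- make_fixture("ring_pentamer", n_residues_per_chain = 60)  # N = 300
  tm <- build_transition_model(count_contacts(fx$model))
  pert <- uniform_perturbation(tm, c("B:1", "B:30"))
  times <- c(0, 0.01, 0.5, 3, 40)
  traj <- propagate(tm, pert, times)
  R <- as.matrix(tm$R)
  for (ti in seq_along(times)) {
    pt <- as.numeric(pert$p0 %*% as.matrix(Matrix::expm(times[ti] * R)))
    expect_lt(max(abs(traj$P[, ti] - pt)), 1e-8)
  }
})

test_that("a non-monotone or negative time grid is rejected", {
  tm <- two_node_tm()
  expect_error(propagate(tm, c(1, 0), c(0, 2, 1)), "increasing")
  expect_error(propagate(tm, c(1, 0), c(-1, 1)), "increasing|t >= 0")
  expect_error(propagate(tm, c(0.7, 0.7), c(0, 1)), "probability")
})

test_that("signal arrival times increase with network distance", {
  # 6-node chain, perturb node 1: flux peaks arrive in order
  n <- matrix(0, 6, 6)
  for (i in 1:5) n[i, i + 1] <- n[i + 1, i] <- 1
  tm <- tm_from_counts(n)
  traj <- propagate(tm, c(1, rep(0, 5)), time_grid(1e-3, 100, 300))
  mt <- max_flux_time(traj)$max_flux_time
  expect_true(mt[3] <= mt[4] && mt[4] <= mt[5])
})

test_that("C5-symmetric perturbation yields chain-permutation-invariant flux", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  keys <- tm$residues$key
  pert <- uniform_perturbation(tm, residue_key(LETTERS[1:5], 13))
  traj <- propagate(tm, pert, time_grid(n = 40))
  p <- match(chartr("ABCDE", "BCDEA", keys), keys)
  expect_lt(max(abs(traj$P[p, ] - traj$P)), 1e-9)
  expect_lt(max(abs(traj$F[p, ] - traj$F)), 1e-9)
})

test_that("trajectories export as long-format CSV", {
  tm <- two_node_tm()
  traj <- propagate(tm, c(1, 0), c(0, 1, 2))
  f <- tempfile(fileext = ".csv")
  export_trajectory(traj, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$p[tab$time == 0], c(1, 0))
  expect_equal(names(tab), c("key", "chain", "resno", "time", "p", "flux",
                             "normalized_flux"))
})
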