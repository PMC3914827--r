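# Replicator dynamics mechanics and numerical contracts.

test_that("mixed payoff is the elementwise convex combination", {
  A <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  B <- matrix(4:1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mixed_payoff(A, B, 0), A)
  expect_equal(mixed_payoff(A, B, 1), B)
  expect_equal(mixed_payoff(A, B, 0.5), (A + B) / 2)
  C <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(mixed_payoff(A, C, 0.5), "phenotype")
  expect_error(mixed_payoff(A, B, 1.5), "omega")
})

test_that("equal fitness and vertex states are replicator fixed points", {
  M <- matrix(2, 4, 4)
  f0 <- c(0.4, 0.3, 0.2, 0.1)
  tr <- replicator_trajectory(M, f0, t_max = 5, record_every = 10)
  expect_equal(tr$states[nrow(tr$states), ], f0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # extinct phenotypes never revive
  M2 <- matrix(stats::runif(16), 4, 4)
  v <- c(0, 1, 0, 0)
  tr2 <- replicator_trajectory(M2, v, t_max = 5, record_every = 10)
  expect_equal(tr2$states[nrow(tr2$states), ], v, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("states stay on the simplex along every trajectory", {
  M <- matrix(c(0, 3, -1, 1, 0, 2, 2, -2, 0), 3, 3)
  tr <- replicator_trajectory(M, c(0.2, 0.5, 0.3), t_max = 50, record_every = 5)
  sums <- rowSums(tr$states)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tr$states >= 0))
})

test_that("the compiled integrator matches the R reference step by step", {
  M <- matrix(c(0, 2, -1, 0.5, 0, 1, -0.5, 1, 0), 3, 3)
  F0 <- matrix(c(0.5, 0.3, 0.2, 0.1, 0.1, 0.8), 2, 3, byrow = TRUE)
  Fr <- F0
  for (s in 1:200) Fr <- ktom:::rk4_renorm_step(Fr, M, 0.01)
  res <- ktom:::.replicator_rk4(M, F0, 0.01, 200, 0, 0L)
  expect_equal(res$F, Fr, tolerance = 1e-12)
})

test_that("payoff shifts leave the dynamics unchanged", {
  M <- matrix(c(0, 1, 2, -1, 0, 1, 0.5, -2, 0), 3, 3)
  F0 <- matrix(c(0.3, 0.3, 0.4), 1)
  a <- ktom:::.replicator_rk4(M, F0, 0.01, 500, 0, 0L)$F
  b <- ktom:::.replicator_rk4(M + 3.7, F0, 0.01, 500, 0, 0L)$F
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("two-phenotype equilibria match the closed-form solution", {
  # anti-coordination (hawk-dove-like) game M = [[a, b], [c, d]] with a < c
  # and d < b: unique stable interior point at p* = (d - b)/((a - c) + (d - b))
  a <- 0; b <- 3; c <- 1; d <- 2
  M <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  p_star <- (d - b) / ((a - c) + (d - b)) # = 0.5 for these payoffs
  ess <- find_ess(M, n_init = 16, seed = 5, tol = 1e-10)
  expect_true(all(ess$converged))
  expect_equal(unname(ess$equilibrium[1]), p_star, tolerance = 1e-6)
  expect_true(ess$unique)
  # coordination game: two vertex attractors, so no unique equilibrium
  ess2 <- find_ess(diag(2), n_init = 64, seed = 6)
  expect_false(ess2$unique)
  verts <- apply(ess2$endpoints, 1, max)
  expect_true(all(verts > 1 - 1e-6))
})

test_that("payoff matrices can be mixed at any shared checkpoint", {
  hs <- hs_pm5(); bs <- bos_pm5()
  M64 <- mixed_payoff(hs, bs, 0.25, tau = 64)
  expect_equal(M64, 0.75 * hs$by_tau[["64"]] + 0.25 * bs$by_tau[["64"]])
  expect_error(mixed_payoff(hs, bs, 0.5, tau = 63), "checkpoint")
})

test_that("competitive extinctions follow sophistication order", {
  M <- hs_pm5()$matrix
  tr <- replicator_trajectory(M, rep(0.2, 5), t_max = 2000, record_every = 10)
  ext_time <- vapply(1:5, function(i) {
    hit <- which(tr$states[, i] < 1e-3)
    if (length(hit)) tr$times[min(hit)] else Inf
  }, numeric(1))
  expect_true(all(diff(ext_time[1:4]) > 0)) # tom0 first, then tom1, tom2, tom3
  expect_identical(ext_time[5], Inf)        # the deepest phenotype survives
})
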