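# Decision policy and learning rules.

test_that("softmax policy has the analytic fixed points and limits", {
  expect_equal(softmax_policy(c(1, 1), beta = 0.3), 0.5)
  # payoff difference beta * ln 3 gives probability 3/4
  expect_equal(softmax_policy(c(0, 0.7 * log(3)), beta = 0.7), 0.75)
  expect_gt(softmax_policy(c(0, 1e-3), beta = 1e-9), 1 - 1e-12) # greedy limit
  expect_error(softmax_policy(c(0, 1), beta = 0), "beta")
  # strictly increasing in the payoff difference
  p <- softmax_policy(cbind(0, seq(-2, 2, 0.5)), beta = 0.5)
  expect_true(all(diff(p) > 0))
})

test_that("expected payoffs are the correct mixture of table columns", {
  hs <- hs_game()
  bos <- bos_game()
  # degenerate mixture picks out one column
  expect_equal(unname(expected_payoffs(hs, 1, 1)), c(hs$u1[1, 2], hs$u1[2, 2]))
  expect_equal(unname(expected_payoffs(hs, 2, 0)), c(hs$u2[1, 1], hs$u2[1, 2]))
  # hide and seek at p = 0.5 is worthless for both actions
  expect_equal(unname(expected_payoffs(hs, 1, 0.5)), c(0, 0))
  # if the partner certainly plays 0, matching on 0 is the best action
  ep <- expected_payoffs(bos, 1, 0)
  expect_gt(ep[1], ep[2])
  ep2 <- expected_payoffs(bos, 2, 0)
  expect_gt(ep2[1], ep2[2])
})

test_that("0-ToM updates move with the prediction error and track frequency", {
  b <- tom0_belief()
  up <- tom0_update(b, 1)
  dn <- tom0_update(b, 0)
  expect_gt(up$mu, b$mu)
  expect_lt(dn$mu, b$mu)
  expect_true(up$Sigma > 0 && dn$Sigma > 0)
  # fictitious-play limit: small volatility, i.i.d. opponent
  for (f in c(0.3, 0.7)) {
    acts <- scripted_actions(1000, "iid", prob = f, seed = 31)
    b <- tom0_belief(sigma = 1e-6)
    for (a in acts) b <- tom0_update(b, a)
    expect_lt(abs(sigmoid(b$mu) - mean(acts)), 0.02)
  }
  # alternating opponent: time-averaged tendency estimate is near 0.5
  b <- tom0_belief()
  s <- numeric(1e4)
  acts <- scripted_actions(1e4, "alternating")
  for (t in seq_along(acts)) {
    s[t] <- sigmoid(b$mu)
    b <- tom0_update(b, acts[t])
  }
  expect_lt(abs(mean(s) - 0.5), 0.02)
})

test_that("0-ToM predictive probability matches numerical quadrature", {
  expect_equal(tom0_predict(tom0_belief(mu = 0, Sigma = 4)), 0.5)
  # delta limit
  b <- tom0_belief(mu = 1.3, Sigma = 1e-12, sigma = 1e-12)
  expect_equal(tom0_predict(b), sigmoid(1.3), tolerance = 1e-5)
  # moment-matched closure vs direct Gaussian integral
  for (mu in c(-2, 0.5, 2)) for (v in c(0.1, 1, 5)) {
    exact <- stats::integrate(function(x) stats::plogis(x) * stats::dnorm(x, mu, sqrt(v)),
                              -Inf, Inf)$value
    expect_lt(abs(smoothed_sigmoid(mu, v) - exact), 0.02)
  }
  # uncertainty shrinks confidence towards 0.5
  b <- tom0_belief(mu = 2, Sigma = 10)
  p <- tom0_predict(b)
  expect_gt(p, 0.5)
  expect_lt(p, sigmoid(2))
})

test_that("1-ToM beliefs have a single candidate with fixed level posterior", {
  g <- hs_game()
  b <- ktom_belief(1, g, role = 1)
  expect_equal(as.numeric(b$lambda), 1)
  expect_equal(ktom_predict(b), 0.5) # symmetric prior
  for (t in 1:25) {
    b <- ktom_update(b, own_action = t %% 2L, opp_action = (t + 1L) %% 2L)
    expect_equal(as.numeric(b$lambda), 1)
    p <- ktom_predict(b)
    expect_true(p > 0 && p < 1)
  }
})

test_that("k-ToM level posterior agrees with an exact Bayesian oracle", {
  # a 2-ToM observer watches a scripted exchange between a fixed 0-ToM
  # opponent (seat 2) and a scripted partner; the variational level
  # posterior must concentrate on level 0 and agree with exact Bayes on the
  # argmax
  g <- hs_game()
  tau <- 200
  own <- scripted_actions(tau, "iid", prob = 0.5, seed = 41)
  opp <- scripted_actions(tau, "tom0", game = g, role = 2,
                          partner_actions = own, seed = 42)
  b <- ktom_belief(2, g, role = 1)
  for (t in seq_len(tau)) b <- ktom_update(b, own[t], opp[t])
  expect_gt(b$lambda[1, 1], 0.9)

  # oracle: exact level posterior with known true parameters, multiplying
  # Bernoulli likelihoods of the observed opponent actions under a live
  # 0-ToM and a live 1-ToM simulant (both watching the same stream)
  pr <- agent_priors()
  loglik <- c(0, 0)
  sim0 <- tom0_belief()
  sim1 <- ktom_belief(1, g, role = 2)
  ab <- unname(g$coef[["2"]])
  for (t in seq_len(tau)) {
    p0 <- sigmoid((ab[1] + ab[2] * tom0_predict(sim0)) / pr$beta)
    p1 <- sigmoid((ab[1] + ab[2] * ktom_predict(sim1)) / pr$beta)
    loglik[1] <- loglik[1] + stats::dbinom(opp[t], 1, p0, log = TRUE)
    loglik[2] <- loglik[2] + stats::dbinom(opp[t], 1, p1, log = TRUE)
    sim0 <- tom0_update(sim0, own[t])
    sim1 <- ktom_update(sim1, own_action = opp[t], opp_action = own[t])
  }
  expect_equal(which.max(loglik), which.max(b$lambda[, 1])) # both say level 0
})

test_that("belief statistics stay finite and positive under stress", {
  g <- hs_game()
  acts <- scripted_actions(1e4, "iid", prob = 0.9, seed = 51)
  b0 <- tom0_belief()
  for (a in acts) b0 <- tom0_update(b0, a)
  expect_true(is.finite(b0$mu) && b0$Sigma > 0)
  b2 <- ktom_belief(2, g, role = 1)
  own <- scripted_actions(1e4, "iid", prob = 0.1, seed = 52)
  for (t in seq_len(1e4)) b2 <- ktom_update(b2, own[t], acts[t])
  expect_true(all(b2$lambda >= 0))
  expect_lt(abs(sum(b2$lambda) - 1), 1e-9)
  for (L in b2$levels) {
    expect_true(all(is.finite(c(L$th1, L$th2))))
    expect_true(all(L$v1 > 0) && all(L$v2 > 0))
  }
})

test_that("constructing a k-ToM agent allocates the full simulant hierarchy", {
  g <- hs_game()
  expect_identical(belief_depth(tom0_belief()), 1L)
  # a level-k belief embeds one simulant per candidate level, recursively:
  # total object count doubles with each level
  for (k in 1:4)
    expect_identical(belief_depth(ktom_belief(k, g, 1)), as.integer(2^k))
})

test_that("Rescorla-Wagner updates have their closed-form behaviour", {
  s <- rl_state(alpha = 1)
  s <- rl_update(s, 1L, 3.5)
  expect_equal(unname(s$q[1, ]), c(0, 3.5)) # full jump at alpha = 1
  # geometric approach to a constant payoff
  s <- rl_state(alpha = 0.25)
  for (i in 1:10) s <- rl_update(s, 1L, 2)
  expect_equal(s$q[1, 2], 2 * (1 - 0.75^10), tolerance = 1e-12)
  expect_equal(s$q[1, 1], 0)
})

test_that("RL pairs mostly lock onto one coordination cell", {
  g <- bos_game()
  recs <- play_many("rl", "rl", g, tau = TAU, n_reps = 100, seed = 61)
  locked <- vapply(recs, function(r) {
    late <- (r$tau - 99):r$tau
    agree <- mean(r$actions[late, 1] == r$actions[late, 2])
    agree > 0.8 # coordinated on a matched cell over the last 100 trials
  }, logical(1))
  expect_gt(mean(locked), 0.5)
})

test_that("the Nash phenotype plays the fixed equilibrium mixture", {
  expect_equal(nash_policy(hs_game(), 1), 0.5)
  expect_equal(nash_policy(bos_game(), 1), 1 / 3, tolerance = 1e-12)
  expect_equal(nash_policy(bos_game(), 2), 2 / 3, tolerance = 1e-12)
  # invariant to history: policy probabilities identical on every trial
  rec <- play_game("nash", "tom1", bos_game(), tau = 50, seed = 71)
  expect_true(all(rec$policy[, 1] == rec$policy[1, 1]))
})
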