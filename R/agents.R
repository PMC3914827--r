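# Decision policy and learning rules for all phenotypes:
# 0-ToM, k-ToM (k >= 1), reinforcement learner, Nash player.
#
# All belief statistics are plain numeric vectors of common length n, so a
# single belief object can track n independent Monte-Carlo repetitions in
# lock-step; n = 1 gives the ordinary single-game case.

#' Default agent priors
#'
#' Reads the shipped `defaults.yaml`: every tunable that the agents use
#' (own volatility prior, exploration temperature, RL learning rate, priors
#' on the simulated opponent's log-volatility/log-temperature) lives in that
#' file, not in code.
#'
#' @return Named list: `sigma` (own volatility prior, `exp(log_sigma)`),
#'   `beta` (softmax temperature), `rl_alpha`, `theta_mu0`, `theta_var0`.
#' @export
agent_priors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- yaml::read_yaml(system.file("extdata", "defaults.yaml", package = "ktom"))
      cache <<- list(
        sigma = exp(d$agents$log_sigma),
        beta = d$agents$beta,
        rl_alpha = d$agents$rl_alpha,
        theta_mu0 = as.numeric(d$agents$theta_prior$mean),
        theta_var0 = as.numeric(d$agents$theta_prior$variance)
      )
    }
    cache
  }
})

#' Softmax decision policy
#'
#' Probability of choosing action 1 given the two actions' expected payoffs:
#' `sigmoid((E[U(1)] - E[U(0)]) / beta)`. Higher temperature `beta` means
#' noisier, more exploratory choices; the probability is strictly increasing
#' in the payoff difference and never exactly 0 or 1 for finite `beta`.
#'
#' @param expected_payoffs Length-2 numeric `c(EU0, EU1)`, or an n x 2 matrix
#'   (rows = independent cases).
#' @param beta Positive exploration temperature.
#' @return Probability (or vector of probabilities) of action 1.
#' @export
softmax_policy <- function(expected_payoffs, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    fail_field("beta", "must be a positive finite scalar")
  ep <- if (is.matrix(expected_payoffs)) expected_payoffs else
    matrix(expected_payoffs, ncol = 2)
  if (ncol(ep) != 2 || !all(is.finite(ep)))
    fail_field("expected_payoffs", "must be finite pairs (EU0, EU1)")
  out <- sigmoid((ep[, 2] - ep[, 1]) / beta)
  if (!is.matrix(expected_payoffs)) out[[1]] else out
}

#' Expected payoffs of both own actions against an opponent mixture
#'
#' @param game A [game_spec()].
#' @param role Player index (1 or 2) of the acting agent.
#' @param p_opponent Probability (vector allowed) that the opponent plays
#'   action 1.
#' @return Length-2 `c(EU0, EU1)` for scalar input, else an n x 2 matrix.
#' @export
expected_payoffs <- function(game, role, p_opponent) {
  stopifnot(inherits(game, "game_spec"), role %in% c(1, 2))
  if (any(p_opponent < 0 | p_opponent > 1)) fail_field("p_opponent", "must lie in [0, 1]")
  u <- if (role == 1) game$u1 else t(game$u2) # rows: own action, cols: opponent action
  e0 <- (1 - p_opponent) * u[1, 1] + p_opponent * u[1, 2]
  e1 <- (1 - p_opponent) * u[2, 1] + p_opponent * u[2, 2]
  if (length(p_opponent) == 1L) c(e0, e1) else cbind(e0, e1, deparse.level = 0)
}

# ---------------------------------------------------------------------------
# 0-ToM: Gaussian posterior on the opponent's choice log-odds
# ---------------------------------------------------------------------------

#' Construct a 0-ToM belief
#'
#' A 0-ToM agent tracks the opponent's probability of playing action 1 through
#' a Gaussian posterior N(mu, Sigma) on the log-odds x of that probability,
#' assuming x drifts across trials as a random walk with variance `sigma`
#' (the volatility prior, which sets the effective learning rate).
#'
#' @param mu,Sigma Initial posterior mean and variance (vectors of common
#'   length for batched beliefs).
#' @param sigma Volatility prior (> 0).
#' @param n Number of parallel belief copies.
#' @return Object of class `tom0_belief`.
#' @export
tom0_belief <- function(mu = 0, Sigma = 1, sigma = agent_priors()$sigma, n = 1) {
  stopifnot(sigma > 0, all(Sigma > 0), all(is.finite(mu)))
  structure(list(mu = rep_len(as.numeric(mu), n),
                 Sigma = rep_len(as.numeric(Sigma), n),
                 sigma = sigma),
            class = "tom0_belief")
}

#' One-trial 0-ToM belief update
#'
#' Variational (Laplace) update of the Gaussian posterior on the opponent's
#' choice log-odds under a Gaussian random walk: the predictive variance is
#' inflated by the volatility, the mean moves in the direction of the
#' prediction error `observed - sigmoid(mu)` with a step size set by the
#' inflated variance, and the variance contracts by the Bernoulli curvature.
#' At small `sigma` the posterior mean tracks the opponent's empirical choice
#' frequency (the fictitious-play limit).
#'
#' @param belief A [tom0_belief()].
#' @param observed_action Observed opponent action(s), 0 or 1.
#' @param sigma Volatility; defaults to the belief's own prior.
#' @return Updated `tom0_belief` (variance stays strictly positive).
#' @export
tom0_update <- function(belief, observed_action, sigma = belief$sigma) {
  stopifnot(inherits(belief, "tom0_belief"))
  if (!all(is.finite(belief$mu)) || !all(is.finite(belief$Sigma)))
    stop("non-finite 0-ToM belief", call. = FALSE)
  check_action(observed_action, "observed_action")
  V <- belief$Sigma + sigma
  p <- sigmoid(belief$mu)
  S_new <- 1 / (1 / V + p * (1 - p))
  belief$mu <- belief$mu + S_new * (observed_action - p)
  belief$Sigma <- S_new
  belief
}

#' 0-ToM posterior-predictive probability of opponent action 1
#'
#' `E[sigmoid(x)]` under the volatility-inflated posterior N(mu, Sigma +
#' sigma), via the moment-matched closure [smoothed_sigmoid()]: uncertainty
#' shrinks the prediction towards 0.5.
#'
#' @inheritParams tom0_update
#' @return Probability (vector) that the opponent plays action 1.
#' @export
tom0_predict <- function(belief, sigma = belief$sigma) {
  stopifnot(inherits(belief, "tom0_belief"))
  smoothed_sigmoid(belief$mu, belief$Sigma + sigma)
}

# ---------------------------------------------------------------------------
# k-ToM (k >= 1): recursive opponent models + level posterior
# ---------------------------------------------------------------------------

#' Construct a k-ToM belief (k >= 1)
#'
#' A k-ToM agent assumes its opponent is a k'-ToM agent for some k' < k. It
#' maintains (i) a posterior `lambda` over the candidate levels 0..k-1,
#' (ii) per candidate level, Gaussian posteriors on the opponent's hidden
#' parameters theta = (log-volatility, log-temperature), and (iii) per
#' candidate level, an embedded simulated opponent of that level, tracked
#' from the opponent's seat (the simulant observes *my* actions as its
#' opponent's actions). The recursion terminates at 0-ToM.
#'
#' @param k Sophistication level (>= 1).
#' @param game A [game_spec()].
#' @param role Seat (1 or 2) of the agent holding this belief.
#' @param level_prior Prior over candidate opponent levels 0..k-1 (defaults
#'   to uniform).
#' @param sigma Own volatility prior: assumed drift variance of the hidden
#'   opponent parameters across trials.
#' @param theta_mu0,theta_var0 Prior moments of (log-volatility,
#'   log-temperature) for every candidate level.
#' @param n Number of parallel belief copies.
#' @return Object of class `ktom_belief` with fields `k`, `role`, `lambda`
#'   (k x n), `levels` (per-candidate records incl. the nested simulant),
#'   and `s_cache` (k x n, last computed per-level opponent action
#'   probabilities).
#' @export
ktom_belief <- function(k, game, role,
                        level_prior = rep(1 / k, k),
                        sigma = agent_priors()$sigma,
                        theta_mu0 = agent_priors()$theta_mu0,
                        theta_var0 = agent_priors()$theta_var0,
                        n = 1) {
  stopifnot(inherits(game, "game_spec"), k >= 1, role %in% c(1, 2))
  if (length(level_prior) != k || any(level_prior < 0) ||
      abs(sum(level_prior) - 1) > 1e-8)
    fail_field("level_prior", "must be a length-k probability vector")
  stopifnot(sigma > 0, length(theta_mu0) == 2, length(theta_var0) == 2,
            all(theta_var0 > 0))
  opp <- 3L - role
  levels <- vector("list", k)
  for (j in seq_len(k)) {
    lev <- j - 1L
    sim <- if (lev == 0) {
      tom0_belief(sigma = sigma, n = n) # operative volatility supplied at use
    } else {
      ktom_belief(lev, game, opp, sigma = sigma,
                  theta_mu0 = theta_mu0, theta_var0 = theta_var0, n = n)
    }
    levels[[j]] <- list(
      level = lev,
      th1 = rep(theta_mu0[1], n), th2 = rep(theta_mu0[2], n),
      v1 = rep(theta_var0[1], n), v2 = rep(theta_var0[2], n),
      sim = sim
    )
  }
  structure(
    list(k = as.integer(k), role = role,
         game_name = game$name,
         opp_coef = unname(game$coef[[as.character(opp)]]),
         lambda = matrix(rep(level_prior, n), nrow = k),
         levels = levels,
         s_cache = matrix(NA_real_, nrow = k, ncol = n),
         sigma = sigma),
    class = "ktom_belief"
  )
}

# Finite-difference step for gradients of the candidate-opponent log-odds
FD_H <- 1e-4

# For candidate record L, return the log-odds l of the simulated level-L$level
# opponent's action-1 probability, evaluated at the parameter posterior means,
# together with central finite-difference gradients wrt theta = (th1, th2).
# l = (a + b * p_sim) * exp(-th2), where p_sim is the simulant's prediction of
# MY next action and (a, b) are the opponent seat's expected-payoff-difference
# coefficients. For level >= 1 simulants p_sim does not depend on th1 at the
# last step, so that gradient component is identically zero.
cand_logodds <- function(L, coef) {
  a <- coef[1]; b <- coef[2]
  h <- FD_H
  if (L$level == 0) {
    p  <- smoothed_sigmoid(L$sim$mu, L$sim$Sigma + exp(L$th1))
    pp <- smoothed_sigmoid(L$sim$mu, L$sim$Sigma + exp(L$th1 + h))
    pm <- smoothed_sigmoid(L$sim$mu, L$sim$Sigma + exp(L$th1 - h))
    g1 <- ((a + b * pp) - (a + b * pm)) * exp(-L$th2) / (2 * h)
  } else {
    p <- ktom_predict(L$sim, sigma = exp(L$th1))
    g1 <- 0
  }
  x <- a + b * p
  l <- x * exp(-L$th2)
  g2 <- (x * exp(-(L$th2 + h)) - x * exp(-(L$th2 - h))) / (2 * h)
  list(l = l, g1 = g1, g2 = g2)
}

# Per-candidate marginal predictive probability that the opponent plays 1,
# integrating the parameter posterior (volatility-inflated) through the
# moment-matched sigmoid; also returns the adjusted log-odds gradients used
# by the update. Shared by ktom_predict and ktom_update.
cand_predictive <- function(L, coef, sigma) {
  cl <- cand_logodds(L, coef)
  V1 <- L$v1 + sigma
  V2 <- L$v2 + sigma
  Vl <- cl$g1^2 * V1 + cl$g2^2 * V2
  shrink <- 1 / sqrt(1 + C_MM * Vl)
  list(s = sigmoid(cl$l * shrink),
       g1 = cl$g1 * shrink, g2 = cl$g2 * shrink,
       V1 = V1, V2 = V2)
}

#' k-ToM prediction of the opponent's next action
#'
#' Mixture over candidate sophistication levels: `sum_k' lambda_k' *
#' s_tilde_k'`, where `s_tilde_k'` is the probability that a level-k'
#' opponent plays action 1, marginalised over the Gaussian posterior on that
#' opponent's hidden (log-volatility, log-temperature) parameters via the
#' moment-matched sigmoid.
#'
#' @param belief A [ktom_belief()].
#' @param sigma Own volatility (drift variance of the hidden opponent
#'   parameters); defaults to the belief's prior.
#' @return Probability (vector) that the opponent plays action 1.
#' @export
ktom_predict <- function(belief, sigma = belief$sigma) {
  stopifnot(inherits(belief, "ktom_belief"))
  out <- 0
  for (j in seq_len(belief$k)) {
    cp <- cand_predictive(belief$levels[[j]], belief$opp_coef, sigma)
    out <- out + belief$lambda[j, ] * cp$s
  }
  out
}

#' One-trial k-ToM belief update
#'
#' Performs, in order: (1) for each candidate level k', compute `s_k'`, the
#' (parameter-posterior-marginal) probability that a level-k' opponent would
#' play action 1 given the history, from the embedded simulant's pre-trial
#' state; (2) update the level posterior `lambda` by Bayes' rule on the
#' Bernoulli likelihoods of the observed opponent action; (3) update each
#' candidate's Gaussian parameter posterior with a prediction-error step: the
#' error `opp_action - s_k'` is propagated through the (finite-difference)
#' gradient of `s_k'` with respect to the hidden parameters, weighted by the
#' current level posterior, with volatility inflation as in [tom0_update()];
#' (4) advance each embedded simulant one trial with roles swapped (the
#' simulant observes my action as its opponent's action), under the refreshed
#' parameter estimates.
#'
#' @param belief A [ktom_belief()].
#' @param own_action,opp_action This trial's actions (0/1 vectors) of the
#'   belief holder and of the opponent.
#' @param sigma Own volatility prior; defaults to the belief's.
#' @return Updated `ktom_belief`.
#' @export
ktom_update <- function(belief, own_action, opp_action, sigma = belief$sigma) {
  stopifnot(inherits(belief, "ktom_belief"))
  check_action(own_action, "own_action")
  check_action(opp_action, "opp_action")
  k <- belief$k
  n <- ncol(belief$lambda)
  cps <- vector("list", k)
  lik <- matrix(NA_real_, k, n)
  for (j in seq_len(k)) {
    cp <- cand_predictive(belief$levels[[j]], belief$opp_coef, sigma)
    if (!all(is.finite(cp$s)))
      stop("non-finite k-ToM sufficient statistics (level ", j - 1L, ")", call. = FALSE)
    cps[[j]] <- cp
    lik[j, ] <- ifelse(opp_action == 1, cp$s, 1 - cp$s)
  }
  # (2) Bayes on the level indicator; guard against total underflow by
  # keeping the previous posterior when all likelihoods vanish numerically
  w <- belief$lambda * lik
  cs <- colSums(w)
  bad <- !is.finite(cs) | cs <= 0
  if (any(bad)) w[, bad] <- belief$lambda[, bad]
  lam_new <- sweep(w, 2, colSums(w), "/")
  # (3) + (4) per-candidate parameter step and simulant advance
  for (j in seq_len(k)) {
    L <- belief$levels[[j]]
    cp <- cps[[j]]
    wj <- lam_new[j, ]
    e <- opp_action - cp$s
    sfac <- cp$s * (1 - cp$s)
    v1_new <- 1 / (1 / cp$V1 + wj * sfac * cp$g1^2)
    v2_new <- 1 / (1 / cp$V2 + wj * sfac * cp$g2^2)
    L$th1 <- L$th1 + wj * v1_new * cp$g1 * e
    L$th2 <- L$th2 + wj * v2_new * cp$g2 * e
    L$v1 <- v1_new
    L$v2 <- v2_new
    L$sim <- if (L$level == 0) {
      tom0_update(L$sim, observed_action = own_action, sigma = exp(L$th1))
    } else {
      ktom_update(L$sim, own_action = opp_action, opp_action = own_action,
                  sigma = exp(L$th1))
    }
    belief$levels[[j]] <- L
    belief$s_cache[j, ] <- cp$s
  }
  belief$lambda <- lam_new
  belief
}

#' Count nested simulant layers of a belief
#'
#' A k-ToM belief embeds one simulant per candidate level 0..k-1, each of
#' which recurses; construction terminates at 0-ToM.
#'
#' @param belief A `ktom_belief` or `tom0_belief`.
#' @return Total number of belief objects in the recursion (this one
#'   included).
#' @export
belief_depth <- function(belief) {
  if (inherits(belief, "tom0_belief")) return(1L)
  1L + sum(vapply(belief$levels, function(L) belief_depth(L$sim), integer(1)))
}

# ---------------------------------------------------------------------------
# Reinforcement learner and Nash player
# ---------------------------------------------------------------------------

#' Construct a reinforcement-learning state
#'
#' Two action values updated by a Rescorla-Wagner delta rule; choices follow
#' the same softmax policy as the ToM agents, with the action values playing
#' the role of expected payoffs.
#'
#' @param q Initial action values `c(q0, q1)` (or an n x 2 matrix).
#' @param alpha Learning rate in (0, 1].
#' @param beta Softmax temperature.
#' @param n Number of parallel copies.
#' @return Object of class `rl_state`.
#' @export
rl_state <- function(q = c(0, 0), alpha = agent_priors()$rl_alpha,
                     beta = agent_priors()$beta, n = 1) {
  stopifnot(alpha > 0, alpha <= 1, beta > 0)
  qm <- if (is.matrix(q)) q else matrix(q, nrow = n, ncol = 2, byrow = TRUE)
  stopifnot(all(is.finite(qm)), ncol(qm) == 2)
  structure(list(q = qm, alpha = alpha, beta = beta), class = "rl_state")
}

#' Rescorla-Wagner value update
#'
#' `q[own_action] <- q[own_action] + alpha * (payoff - q[own_action])`; the
#' unchosen action's value is unchanged.
#'
#' @param state An [rl_state()].
#' @param own_action Chosen action(s), 0/1.
#' @param received_payoff Obtained payoff(s).
#' @return Updated `rl_state`.
#' @export
rl_update <- function(state, own_action, received_payoff) {
  stopifnot(inherits(state, "rl_state"))
  check_action(own_action, "own_action")
  idx <- cbind(seq_len(nrow(state$q)), own_action + 1L)
  state$q[idx] <- state$q[idx] + state$alpha * (received_payoff - state$q[idx])
  state
}

#' Nash policy
#'
#' The role's mixed-equilibrium probability of action 1; constant across
#' trials (the Nash phenotype does not learn).
#'
#' @param game A [game_spec()].
#' @param role Player index (1 or 2).
#' @return Probability of action 1.
#' @export
nash_policy <- function(game, role) {
  stopifnot(role %in% c(1, 2))
  eq <- mixed_nash(game)
  if (role == 1) eq$p1 else eq$p2
}
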