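# Iterated dyadic games, Monte-Carlo payoff matrices, behavioural metrics.

#' Play one iterated dyadic game
#'
#' Per trial, each agent forms its prediction of the opponent's next action,
#' converts it to expected payoffs, samples an action from the softmax
#' policy, then both agents observe both actions, receive payoffs and update
#' their beliefs. Fully reproducible from the seed.
#'
#' @param agent1,agent2 Phenotype strings (`"tom0"`..`"tom4"`, `"rl"`,
#'   `"nash"`) or lists with `phenotype` plus optional overrides (`sigma`,
#'   `beta`, `alpha`, `level_prior`).
#' @param game A [game_spec()].
#' @param tau Number of trials (>= 1).
#' @param seed Integer seed.
#' @param checkpoints Trial indices at which cumulative payoffs are recorded
#'   (always includes `tau`).
#' @return A `play_record`: per-trial `actions`, `policy` (probability of
#'   action 1), `pred` (prediction of the opponent's action-1 probability;
#'   `NA` for phenotypes that do not model the opponent), `payoffs`,
#'   cumulative payoffs at the checkpoints, and the final belief state of
#'   both players.
#' @export
play_game <- function(agent1, agent2, game, tau, seed, checkpoints = tau) {
  res <- run_dyad(parse_agent(agent1, "agent1"), parse_agent(agent2, "agent2"),
                  game, tau, seeds = as.integer(seed),
                  checkpoints = checkpoints, record = TRUE)
  extract_record(res, 1L)
}

#' Play many independent repetitions of a dyad
#'
#' Repetition `r` uses the derived seed `child_seed(seed, r)`; each returned
#' record is bit-identical to [play_game()] run with that seed.
#'
#' @inheritParams play_game
#' @param n_reps Number of repetitions.
#' @return List of `play_record` objects.
#' @export
play_many <- function(agent1, agent2, game, tau, n_reps, seed, checkpoints = tau) {
  seeds <- vapply(seq_len(n_reps), function(r) child_seed(seed, r), integer(1))
  res <- run_dyad(parse_agent(agent1, "agent1"), parse_agent(agent2, "agent2"),
                  game, tau, seeds = seeds, checkpoints = checkpoints,
                  record = TRUE)
  lapply(seq_len(n_reps), function(r) extract_record(res, r))
}

#' @export
print.play_record <- function(x, ...) {
  cat(sprintf("<play_record> %s vs %s, %s, tau = %d, seed = %d\n",
              x$phenotypes[1], x$phenotypes[2], x$game, x$tau, x$seed))
  cat(sprintf("accumulated payoffs: %.1f / %.1f\n",
              sum(x$payoffs[, 1]), sum(x$payoffs[, 2])))
  invisible(x)
}

#' Monte-Carlo expected payoff matrix
#'
#' Element (i, j) is the Monte-Carlo mean, over `n_reps` independently seeded
#' iterated games, of phenotype i's accumulated payoff when facing phenotype
#' j, measured at trial `tau` (and at any intermediate `checkpoints`). The
#' (i, j) and (j, i) entries come from the same set of games, so the matrix
#' of a zero-sum game is anti-symmetric by construction; diagonal (twin-pair)
#' entries average the two seats of the same games.
#'
#' @inheritParams play_game
#' @param phenotypes Character vector (or list of agent specs) of the
#'   competing phenotypes.
#' @param n_reps Repetitions per pair (>= 1); pair q, repetition r uses the
#'   derived seed `child_seed(seed, q, r)`.
#' @return Object of class `payoff_matrix`: `matrix` and `se` (at `tau`),
#'   `by_tau`/`se_by_tau` (named lists over checkpoints), plus the run
#'   metadata.
#' @export
payoff_matrix <- function(phenotypes, game, tau, n_reps, seed, checkpoints = tau) {
  stopifnot(n_reps >= 1)
  specs <- lapply(phenotypes, parse_agent)
  labels <- vapply(specs, function(s) s$phenotype, character(1))
  K <- length(specs)
  checkpoints <- sort(unique(c(as.integer(checkpoints), as.integer(tau))))
  ncp <- length(checkpoints)
  m <- lapply(seq_len(ncp), function(i)
    matrix(NA_real_, K, K, dimnames = list(labels, labels)))
  se <- lapply(seq_len(ncp), function(i)
    matrix(NA_real_, K, K, dimnames = list(labels, labels)))
  q <- 0L
  for (i in seq_len(K)) for (j in i:K) {
    q <- q + 1L
    seeds <- vapply(seq_len(n_reps), function(r) child_seed(seed, q, r), integer(1))
    res <- run_dyad(specs[[i]], specs[[j]], game, tau, seeds,
                    checkpoints = checkpoints, record = FALSE)
    for (ci in seq_len(ncp)) {
      x1 <- res$cum1[ci, ]
      x2 <- res$cum2[ci, ]
      if (i == j) {
        tw <- (x1 + x2) / 2
        m[[ci]][i, i] <- mean(tw)
        se[[ci]][i, i] <- stats::sd(tw) / sqrt(n_reps)
      } else {
        m[[ci]][i, j] <- mean(x1)
        m[[ci]][j, i] <- mean(x2)
        se[[ci]][i, j] <- stats::sd(x1) / sqrt(n_reps)
        se[[ci]][j, i] <- stats::sd(x2) / sqrt(n_reps)
      }
    }
  }
  names(m) <- names(se) <- as.character(checkpoints)
  structure(list(phenotypes = labels, game = game$name, tau = tau,
                 n_reps = n_reps, seed = seed, checkpoints = checkpoints,
                 matrix = m[[ncp]], se = se[[ncp]],
                 by_tau = m, se_by_tau = se),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoff_matrix> %s, tau = %d, %d reps (seed %d)\n",
              x$game, x$tau, x$n_reps, x$seed))
  print(round(x$matrix, 2))
  invisible(x)
}

stop_not_record <- function(record) {
  if (!inherits(record, "play_record"))
    stop("expected a play_record", call. = FALSE)
}

#' Prediction-accuracy slope
#'
#' Ordinary-least-squares slope of a player's per-trial prediction of the
#' opponent's action-1 probability, regressed on the opponent's true
#' behavioural tendency (the opponent's recorded policy probability at the
#' same trial). A slope near 1 means the player tracks the opponent well;
#' near 0, predictions carry no information.
#'
#' @param record A `play_record` from [play_game()].
#' @param which_player 1 or 2.
#' @return The OLS slope, or `NA` when the regressor has (numerically) zero
#'   variance or the player makes no predictions.
#' @export
prediction_accuracy_slope <- function(record, which_player) {
  stop_not_record(record)
  stopifnot(which_player %in% c(1, 2), record$tau >= 3)
  y <- record$pred[, which_player]
  x <- record$policy[, 3 - which_player]
  if (anyNA(y)) return(NA_real_)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < 1e-12) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Fraction of correctly predicted opponent actions
#'
#' Thresholds each prediction at 0.5 (`p > 0.5` predicts action 1; exact
#' ties are resolved by an unbiased coin flip drawn from a stream derived
#' from the record's seed) and scores it against the opponent's sampled
#' action.
#'
#' @inheritParams prediction_accuracy_slope
#' @return Fraction in [0, 1], or `NA` for non-predicting phenotypes.
#' @export
correct_prediction_rate <- function(record, which_player) {
  stop_not_record(record)
  stopifnot(which_player %in% c(1, 2))
  p <- record$pred[, which_player]
  if (anyNA(p)) return(NA_real_)
  a <- record$actions[, 3 - which_player]
  guess <- as.integer(p > 0.5)
  tie <- p == 0.5
  if (any(tie)) {
    u <- with_seed(child_seed(record$seed, which_player),
                   stats::runif(sum(tie)))
    guess[tie] <- as.integer(u < 0.5)
  }
  mean(guess == a)
}

#' Sophistication level attributed to the opponent
#'
#' The argmax of the player's final posterior over candidate opponent levels;
#' ties break toward the lower level.
#'
#' @inheritParams prediction_accuracy_slope
#' @return Attributed level (integer >= 0).
#' @export
attributed_level <- function(record, which_player) {
  stop_not_record(record)
  st <- record$final[[which_player]]
  if (!inherits(st, "ktom_belief"))
    stop("attributed_level requires a k-ToM player with k >= 1", call. = FALSE)
  unname(which.max(st$lambda[, 1]) - 1L)
}

#' Scripted opponent action streams for testing and diagnostics
#'
#' Generates deterministic or generative action sequences that can be fed to
#' belief updates without running a live opponent: `"iid"` draws i.i.d.
#' Bernoulli(`prob`) actions; `"alternating"` yields 1, 0, 1, 0, ...;
#' `"tom0"` runs a 0-ToM agent (from seat `role`) that responds to the
#' supplied `partner_actions`, sampling its softmax policy.
#'
#' @param n Number of trials (ignored for `"tom0"`, which follows
#'   `partner_actions`).
#' @param type One of `"iid"`, `"alternating"`, `"tom0"`.
#' @param prob Bernoulli probability for `"iid"`.
#' @param game,role,sigma,beta 0-ToM configuration for `"tom0"`.
#' @param partner_actions 0/1 vector of the scripted partner for `"tom0"`.
#' @param seed Integer seed for the generative types.
#' @return Integer vector of 0/1 actions.
#' @export
scripted_actions <- function(n, type = c("iid", "alternating", "tom0"),
                             prob = 0.5, game = NULL, role = 2,
                             sigma = agent_priors()$sigma,
                             beta = agent_priors()$beta,
                             partner_actions = NULL, seed = 1) {
  type <- match.arg(type)
  if (type == "iid")
    return(with_seed(seed, as.integer(stats::runif(n) < prob)))
  if (type == "alternating")
    return(rep_len(c(1L, 0L), n))
  stopifnot(inherits(game, "game_spec"), !is.null(partner_actions))
  check_action(partner_actions, "partner_actions")
  ab <- unname(game$coef[[as.character(role)]])
  b <- tom0_belief(sigma = sigma)
  u <- with_seed(seed, stats::runif(length(partner_actions)))
  out <- integer(length(partner_actions))
  for (t in seq_along(partner_actions)) {
    p_opp <- tom0_predict(b)
    pol <- sigmoid((ab[1] + ab[2] * p_opp) / beta)
    out[t] <- as.integer(u[t] < pol)
    b <- tom0_update(b, partner_actions[t])
  }
  out
}
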