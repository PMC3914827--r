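# Internal dyadic simulation engine. All agent state is vectorised over n
# Monte-Carlo repetitions: repetition r consumes its own pre-generated
# uniform stream (derived from its own seed), so results are bit-identical
# whether reps run batched here or one at a time via play_game().

PHENO_RE <- "^(tom([0-9]+)|rl|nash)$"

# Normalise an agent argument: either a phenotype string ("tom0".."tomK",
# "rl", "nash") or a list(phenotype = ..., sigma/beta/alpha/level_prior = ...)
parse_agent <- function(x, lab = "agent") {
  if (is.character(x)) x <- list(phenotype = x)
  if (!is.list(x) || is.null(x$phenotype) || !grepl(PHENO_RE, x$phenotype))
    fail_field(lab, "phenotype must match tom<k>, rl or nash")
  pr <- agent_priors()
  defaults <- list(sigma = pr$sigma, beta = pr$beta, alpha = pr$rl_alpha,
                   level_prior = NULL)
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  x
}

pheno_level <- function(phenotype) {
  if (grepl("^tom", phenotype)) as.integer(sub("tom", "", phenotype)) else NA_integer_
}

init_player <- function(spec, game, role, n) {
  pheno <- spec$phenotype
  lev <- pheno_level(pheno)
  ab <- unname(game$coef[[as.character(role)]])
  st <- if (!is.na(lev) && lev == 0) {
    tom0_belief(sigma = spec$sigma, n = n)
  } else if (!is.na(lev)) {
    lp <- if (is.null(spec$level_prior)) rep(1 / lev, lev) else spec$level_prior
    ktom_belief(lev, game, role, level_prior = lp, sigma = spec$sigma, n = n)
  } else if (pheno == "rl") {
    rl_state(alpha = spec$alpha, beta = spec$beta, n = n)
  } else {
    nash_policy(game, role)
  }
  list(phenotype = pheno, level = lev, beta = spec$beta, role = role,
       coef = ab, state = st, n = n)
}

# Prediction of the opponent's action-1 probability (NA for phenotypes that
# do not model the opponent)
player_predict <- function(pl) {
  if (is.na(pl$level)) return(rep(NA_real_, pl$n))
  if (pl$level == 0) tom0_predict(pl$state) else ktom_predict(pl$state)
}

# Own action-1 probability
player_policy <- function(pl, pred) {
  if (!is.na(pl$level))
    return(sigmoid((pl$coef[1] + pl$coef[2] * pred) / pl$beta))
  if (pl$phenotype == "rl")
    return(sigmoid((pl$state$q[, 2] - pl$state$q[, 1]) / pl$state$beta))
  rep(pl$state, pl$n) # nash: constant mixture
}

player_update <- function(pl, own, opp, pay) {
  if (!is.na(pl$level)) {
    pl$state <- if (pl$level == 0) tom0_update(pl$state, opp)
                else ktom_update(pl$state, own, opp)
  } else if (pl$phenotype == "rl") {
    pl$state <- rl_update(pl$state, own, pay)
  }
  pl
}

# Extract repetition r of a (possibly batched) player state
slice_state <- function(st, r) {
  if (inherits(st, "tom0_belief")) {
    st$mu <- st$mu[r]; st$Sigma <- st$Sigma[r]
  } else if (inherits(st, "ktom_belief")) {
    st$lambda <- st$lambda[, r, drop = FALSE]
    st$s_cache <- st$s_cache[, r, drop = FALSE]
    st$levels <- lapply(st$levels, function(L) {
      L$th1 <- L$th1[r]; L$th2 <- L$th2[r]
      L$v1 <- L$v1[r]; L$v2 <- L$v2[r]
      L$sim <- slice_state(L$sim, r)
      L
    })
  } else if (inherits(st, "rl_state")) {
    st$q <- st$q[r, , drop = FALSE]
  }
  st
}

# Run n repetitions of an iterated dyadic game in lock-step.
# seeds: integer vector, one per repetition. checkpoints: sorted trial
# indices at which cumulative payoffs are recorded (last one == tau).
run_dyad <- function(spec1, spec2, game, tau, seeds,
                     checkpoints = tau, record = TRUE) {
  stopifnot(tau >= 1)
  n <- length(seeds)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 1 | checkpoints > tau))
    fail_field("checkpoints", "must lie in 1..tau")
  if (checkpoints[length(checkpoints)] != tau) checkpoints <- c(checkpoints, tau)
  U1 <- matrix(NA_real_, tau, n)
  U2 <- matrix(NA_real_, tau, n)
  for (r in seq_len(n)) {
    u <- with_seed(seeds[r], matrix(stats::runif(2 * tau), tau, 2))
    U1[, r] <- u[, 1]
    U2[, r] <- u[, 2]
  }
  p1 <- init_player(spec1, game, 1L, n)
  p2 <- init_player(spec2, game, 2L, n)
  cum1 <- numeric(n); cum2 <- numeric(n)
  ncp <- length(checkpoints)
  cp1 <- matrix(NA_real_, ncp, n); cp2 <- matrix(NA_real_, ncp, n)
  cp_i <- 1L
  if (record) {
    A1 <- matrix(NA_integer_, tau, n); A2 <- A1
    P1 <- matrix(NA_real_, tau, n); P2 <- P1; Q1 <- P1; Q2 <- P1
    Y1 <- P1; Y2 <- P1
  }
  for (t in seq_len(tau)) {
    pred1 <- player_predict(p1)
    pred2 <- player_predict(p2)
    pol1 <- player_policy(p1, pred1)
    pol2 <- player_policy(p2, pred2)
    a1 <- as.integer(U1[t, ] < pol1)
    a2 <- as.integer(U2[t, ] < pol2)
    i1 <- cbind(a1 + 1L, a2 + 1L)
    pay1 <- game$u1[i1]
    pay2 <- game$u2[i1]
    tryCatch({
      p1 <- player_update(p1, a1, a2, pay1)
      p2 <- player_update(p2, a2, a1, pay2)
    }, error = function(e) {
      stop(sprintf("agent update failed at trial %d: %s", t, conditionMessage(e)),
           call. = FALSE)
    })
    cum1 <- cum1 + pay1
    cum2 <- cum2 + pay2
    if (t == checkpoints[cp_i]) {
      cp1[cp_i, ] <- cum1
      cp2[cp_i, ] <- cum2
      cp_i <- cp_i + 1L
    }
    if (record) {
      A1[t, ] <- a1; A2[t, ] <- a2
      P1[t, ] <- pol1; P2[t, ] <- pol2
      Q1[t, ] <- pred1; Q2[t, ] <- pred2
      Y1[t, ] <- pay1; Y2[t, ] <- pay2
    }
  }
  out <- list(game = game$name, tau = tau, seeds = seeds,
              phenotypes = c(spec1$phenotype, spec2$phenotype),
              checkpoints = checkpoints, cum1 = cp1, cum2 = cp2,
              final1 = p1, final2 = p2)
  if (record) {
    out$actions <- list(A1, A2)
    out$policy <- list(P1, P2)
    out$pred <- list(Q1, Q2)
    out$payoffs <- list(Y1, Y2)
  }
  out
}

# Assemble the per-repetition play_record from a batched run
extract_record <- function(res, r) {
  structure(list(
    game = res$game, tau = res$tau, seed = res$seeds[r],
    phenotypes = res$phenotypes,
    actions = cbind(p1 = res$actions[[1]][, r], p2 = res$actions[[2]][, r]),
    policy = cbind(p1 = res$policy[[1]][, r], p2 = res$policy[[2]][, r]),
    pred = cbind(p1 = res$pred[[1]][, r], p2 = res$pred[[2]][, r]),
    payoffs = cbind(p1 = res$payoffs[[1]][, r], p2 = res$payoffs[[2]][, r]),
    checkpoints = res$checkpoints,
    cum_payoffs = cbind(p1 = res$cum1[, r], p2 = res$cum2[, r]),
    final = list(slice_state(res$final1$state, r), slice_state(res$final2$state, r))
  ), class = "play_record")
}
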