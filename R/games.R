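# 2x2 stage games: construction, payoff lookup, analytic mixed Nash equilibria.

#' Define a 2x2 stage game
#'
#' A game is a pair of 2x2 payoff tables, one per player, indexed by the two
#' players' binary actions: `u1[a1 + 1, a2 + 1]` is player 1's payoff when
#' player 1 plays `a1` and player 2 plays `a2` (actions are coded 0/1, and
#' "action 1" is the reference action whose probability every policy reports).
#'
#' @param name Identifier for the game.
#' @param u1,u2 2x2 numeric matrices (or row-major lists of two length-2
#'   vectors) of payoffs for players 1 and 2.
#' @return An object of class `game_spec` with elements `name`, `u1`, `u2`
#'   and precomputed per-role linear coefficients of the expected-payoff
#'   difference (see [expected_payoffs()]).
#' @examples
#' g <- default_games()$hide_and_seek
#' payoff(g, 1, 1)
#' @export
game_spec <- function(name, u1, u2) {
  as_tab <- function(u, lab) {
    if (is.list(u)) u <- do.call(rbind, lapply(u, as.numeric))
    u <- as.matrix(u)
    if (!all(dim(u) == c(2, 2)) || !all(is.finite(u)))
      fail_field(lab, "must be a finite 2x2 payoff table")
    storage.mode(u) <- "double"
    dimnames(u) <- list(a_self = c("0", "1"), a_other = c("0", "1"))
    u
  }
  u1 <- as_tab(u1, "u1")
  u2 <- as_tab(u2, "u2")
  # Expected-payoff difference for a role is linear in the opponent's
  # probability p of playing 1: E[U(1)] - E[U(0)] = a + b p. Precomputed once.
  a1c <- u1[2, 1] - u1[1, 1]
  b1c <- (u1[2, 2] - u1[1, 2]) - a1c
  a2c <- u2[1, 2] - u2[1, 1]
  b2c <- (u2[2, 2] - u2[2, 1]) - a2c
  structure(
    list(name = as.character(name), u1 = u1, u2 = u2,
         coef = list(`1` = c(a = a1c, b = b1c), `2` = c(a = a2c, b = b2c))),
    class = "game_spec"
  )
}

#' @export
print.game_spec <- function(x, ...) {
  cat("<game_spec>", x$name, "\n")
  cat("player 1 payoffs:\n"); print(x$u1)
  cat("player 2 payoffs:\n"); print(x$u2)
  invisible(x)
}

#' Load game definitions from a configuration file
#'
#' @param path Path to a YAML (or JSON) file mapping game names to `u1`/`u2`
#'   tables. Defaults to the file shipped with the package, which defines
#'   `hide_and_seek` (symmetric zero-sum) and `battle_of_the_sexes`
#'   (unbalanced coordination).
#' @return Named list of [game_spec()] objects.
#' @export
load_games <- function(path = system.file("extdata", "games.yaml", package = "ktom")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) game_spec(nm, raw[[nm]]$u1, raw[[nm]]$u2))
  names(out) <- names(raw)
  out
}

#' @rdname load_games
#' @export
default_games <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_games()
    cache
  }
})

check_action <- function(a, lab) {
  if (!all(a %in% c(0, 1))) fail_field(lab, "actions must be 0 or 1")
  a
}

#' Payoff lookup
#'
#' @param game A [game_spec()].
#' @param a1,a2 Actions (0 or 1) of players 1 and 2; vectors are recycled
#'   elementwise.
#' @return For scalar input, a length-2 numeric `c(u1, u2)`; for vector input
#'   a 2-column matrix with one row per action pair.
#' @export
payoff <- function(game, a1, a2) {
  stopifnot(inherits(game, "game_spec"))
  check_action(a1, "a1"); check_action(a2, "a2")
  i <- a1 + 1L; j <- a2 + 1L
  out <- cbind(u1 = game$u1[cbind(i, j)], u2 = game$u2[cbind(i, j)])
  if (length(a1) == 1L && length(a2) == 1L) c(out) else out
}

#' Mixed Nash equilibrium of a 2x2 game
#'
#' Solves the indifference conditions: each player's mixture makes the
#' opponent indifferent between their two actions. For the configured
#' hide-and-seek this is (0.5, 0.5); for the configured battle of the sexes
#' (1/3, 2/3).
#'
#' @param game A [game_spec()].
#' @return List with `p1`, `p2` (each player's equilibrium probability of
#'   action 1) and `degenerate` (TRUE when the indifference system has no
#'   interior solution; `p1`/`p2` then fall back to a best-response pure
#'   equilibrium probability).
#' @export
mixed_nash <- function(game) {
  stopifnot(inherits(game, "game_spec"))
  # p1 makes player 2 indifferent; p2 makes player 1 indifferent.
  solve_one <- function(d0, d1) {
    # d0 = (payoff diff favouring action 0) at opponent action 0, d1 at 1
    den <- d0 - d1
    if (abs(den) < 1e-12) return(NA_real_)
    p <- d0 / den
    if (p < 0 || p > 1) NA_real_ else p
  }
  p1 <- solve_one(game$u2[1, 1] - game$u2[1, 2], game$u2[2, 1] - game$u2[2, 2])
  p2 <- solve_one(game$u1[1, 1] - game$u1[2, 1], game$u1[1, 2] - game$u1[2, 2])
  degenerate <- is.na(p1) || is.na(p2)
  if (degenerate) {
    # fall back to a pure best-response equilibrium probability (or 0.5 when
    # a player is fully indifferent, e.g. a constant payoff table)
    pure <- pure_nash_fallback(game)
    p1 <- if (is.na(p1)) pure[1] else p1
    p2 <- if (is.na(p2)) pure[2] else p2
  }
  list(p1 = p1, p2 = p2, degenerate = degenerate)
}

pure_nash_fallback <- function(game) {
  best <- matrix(FALSE, 2, 2)
  for (a2 in 1:2) {
    b1 <- which.max(game$u1[, a2])
    for (a1 in 1:2) {
      b2 <- which.max(game$u2[a1, ])
      if (a1 == b1 && a2 == b2) best[a1, a2] <- TRUE
    }
  }
  idx <- which(best, arr.ind = TRUE)
  if (nrow(idx) >= 1) c(idx[1, 1] - 1, idx[1, 2] - 1) else c(0.5, 0.5)
}
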