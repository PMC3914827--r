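# Replicator dynamics over phenotype frequencies, evolutionary-stable-state
# detection, and the (omega, tau) phase diagram.

egt_defaults <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "defaults.yaml",
                                            package = "ktom"))$egt
    cache
  }
})

payoff_at <- function(pm, tau) {
  key <- as.character(as.integer(tau))
  if (!key %in% names(pm$by_tau))
    fail_field("tau", sprintf("no checkpoint %s in payoff matrix", key))
  pm$by_tau[[key]]
}

#' Mix competitive and cooperative payoff matrices
#'
#' Elementwise convex combination `(1 - omega) * M_hs + omega * M_bos`:
#' `omega` is the probability that a pairwise encounter is the cooperative
#' game rather than the competitive one. Raw expected accumulated payoffs
#' are combined without cross-game normalisation (the two games' absolute
#' payoff levels are therefore not directly comparable; see the package
#' vignette); set `standardise = TRUE` to divide each matrix by its largest
#' absolute entry first.
#'
#' @param M_hs,M_bos [payoff_matrix()] objects (or plain matrices) sharing
#'   the same phenotype list.
#' @param omega Cooperation proportion in [0, 1].
#' @param tau Checkpoint at which to take the payoffs when matrix objects are
#'   supplied (defaults to their final trial).
#' @param standardise Per-game max-abs standardisation before mixing
#'   (default off).
#' @return Plain numeric matrix with phenotype dimnames.
#' @export
mixed_payoff <- function(M_hs, M_bos, omega, tau = NULL, standardise = FALSE) {
  if (omega < 0 || omega > 1) fail_field("omega", "must lie in [0, 1]")
  take <- function(M) {
    if (inherits(M, "payoff_matrix")) {
      if (is.null(tau)) M$matrix else payoff_at(M, tau)
    } else as.matrix(M)
  }
  A <- take(M_hs); B <- take(M_bos)
  if (!identical(dim(A), dim(B)) || !identical(rownames(A), rownames(B)))
    fail_field("phenotypes", "competitive and cooperative matrices must share the same phenotype list")
  if (standardise) {
    A <- A / max(abs(A), 1e-12)
    B <- B / max(abs(B), 1e-12)
  }
  (1 - omega) * A + omega * B
}

# Replicator vector field on the simplex: df_i = f_i ((M f)_i - f' M f).
# Vectorised across initial conditions: F is an n x K matrix of row-states.
replicator_field <- function(F, M) {
  G <- tcrossprod(F, M)
  phi <- rowSums(F * G)
  F * (G - phi)
}

# One classical RK4 step followed by renormalisation onto the simplex.
# k1 (the field at the current state) may be supplied to avoid recomputing
# it when the caller also uses it as a convergence measure.
rk4_renorm_step <- function(F, M, dt, k1 = replicator_field(F, M)) {
  k2 <- replicator_field(F + (dt / 2) * k1, M)
  k3 <- replicator_field(F + (dt / 2) * k2, M)
  k4 <- replicator_field(F + dt * k3, M)
  F <- F + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  F[F < 0] <- 0
  F / rowSums(F)
}

# Normalise the payoff scale so integration time units are comparable across
# matrices: dynamics are invariant to a payoff shift, and a positive rescale
# only rescales time.
scale_payoff <- function(M) {
  s <- max(abs(M))
  if (s < 1e-12) M else M / s
}

#' Integrate a replicator trajectory
#'
#' Fixed-step 4th-order Runge-Kutta on `df_i = f_i ((M f)_i - f' M f)`, with
#' the state renormalised onto the simplex after every step. The payoff
#' matrix is rescaled by its largest absolute entry so that `dt` and `t_max`
#' are in normalised fitness units.
#'
#' @param M Square payoff matrix (a [payoff_matrix()] object is accepted).
#' @param f0 Initial frequency vector on the simplex.
#' @param t_max,dt Integration horizon and step (normalised fitness units).
#' @param record_every Record the state every this many steps (the initial
#'   and final states are always included).
#' @param tol Early-stopping tolerance on the vector field's infinity norm.
#' @return Object of class `replicator_trajectory`: `times`, `states` (one
#'   row per recorded time), and the `converged` flag with the final
#'   infinity-norm of the vector field.
#' @export
replicator_trajectory <- function(M, f0, t_max = egt_defaults()$t_max,
                                  dt = egt_defaults()$dt,
                                  record_every = 100L,
                                  tol = egt_defaults()$tol) {
  if (inherits(M, "payoff_matrix")) M <- M$matrix
  f0 <- as.numeric(f0)
  if (any(f0 < 0) || abs(sum(f0) - 1) > 1e-9)
    fail_field("f0", "must lie on the probability simplex")
  Mn <- scale_payoff(M)
  n_steps <- ceiling(t_max / dt)
  res <- .replicator_rk4(Mn, matrix(f0, nrow = 1), dt, n_steps, tol,
                         as.integer(record_every))
  nt <- length(res$times)
  states <- t(matrix(res$states, nrow = ncol(Mn)))
  if (res$steps * dt > res$times[nt]) {
    states <- rbind(states, as.numeric(res$F))
    res$times <- c(res$times, res$steps * dt)
  }
  colnames(states) <- colnames(M)
  speed <- max(abs(replicator_field(res$F, Mn)))
  structure(list(times = res$times, states = states,
                 phenotypes = colnames(M),
                 converged = res$converged[1], final_speed = speed),
            class = "replicator_trajectory")
}

# Uniform sample on the simplex (Dirichlet(1, ..., 1))
runif_simplex <- function(n, K) {
  x <- matrix(-log(stats::runif(n * K)), n, K)
  x / rowSums(x)
}

#' Find the evolutionarily stable state of a payoff matrix
#'
#' Integrates replicator dynamics from `n_init` initial conditions sampled
#' uniformly on the simplex, batched through the same fixed-step RK4 scheme
#' as [replicator_trajectory()]. Convergence is declared when the
#' infinity-norm of the vector field falls below `tol`; trajectories that
#' never converge within `t_max` are flagged as potential cycles.
#'
#' @inheritParams replicator_trajectory
#' @param n_init Number of initial conditions (>= 1).
#' @param seed Integer seed for the initial-condition sample.
#' @param tol Convergence tolerance on the vector-field infinity norm.
#' @param uniqueness_tol Endpoints closer than this (max-norm) count as one
#'   equilibrium.
#' @param extinction_threshold Phenotypes below this equilibrium frequency
#'   are reported extinct.
#' @return Object of class `ess_result`: `equilibrium` (mean endpoint),
#'   `endpoints` (n_init x K), `converged` (per-trajectory flags), `unique`
#'   (TRUE when all endpoints coincide within tolerance), `cycling` (TRUE
#'   when any trajectory failed to converge), and `extinct` (phenotype
#'   names).
#' @export
find_ess <- function(M, n_init = egt_defaults()$n_init, seed = 1,
                     tol = egt_defaults()$tol,
                     t_max = egt_defaults()$t_max, dt = egt_defaults()$dt,
                     uniqueness_tol = egt_defaults()$uniqueness_tol,
                     extinction_threshold = egt_defaults()$extinction_threshold) {
  if (inherits(M, "payoff_matrix")) M <- M$matrix
  stopifnot(n_init >= 1)
  K <- ncol(M)
  labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("p", seq_len(K))
  Mn <- scale_payoff(M)
  F0 <- with_seed(seed, runif_simplex(n_init, K))
  res <- .replicator_rk4(Mn, F0, dt, ceiling(t_max / dt), tol, 0L)
  F <- res$F
  converged <- as.logical(res$converged)
  colnames(F) <- labels
  eq <- colMeans(F)
  dmax <- 0
  if (n_init > 1) {
    rng <- apply(F, 2, range)
    dmax <- max(rng[2, ] - rng[1, ])
  }
  structure(list(
    equilibrium = eq, endpoints = F, converged = converged,
    unique = dmax < uniqueness_tol, max_endpoint_distance = dmax,
    cycling = !all(converged),
    extinct = labels[eq < extinction_threshold],
    n_init = n_init, seed = seed, tol = tol
  ), class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat("<ess_result>", if (x$unique) "unique" else "multiple",
      "equilibrium;", if (x$cycling) "cycling detected" else "all converged", "\n")
  print(round(x$equilibrium, 4))
  if (length(x$extinct)) cat("extinct:", paste(x$extinct, collapse = ", "), "\n")
  invisible(x)
}

#' Evolutionary phase diagram over cooperation proportion and game length
#'
#' For every combination of `omega` (cooperation proportion) and `tau`
#' (number of game iterations), mixes the two games' payoff matrices at that
#' checkpoint and locates the evolutionarily stable state.
#'
#' @param M_hs,M_bos [payoff_matrix()] objects for the competitive and
#'   cooperative games, computed with checkpoints covering `tau_grid`.
#' @param omega_grid Cooperation proportions in [0, 1].
#' @param tau_grid Game lengths; defaults to the checkpoints shared by the
#'   two matrices.
#' @param ... Passed to [find_ess()] (e.g. `n_init`, `seed`).
#' @return List with `results` (named list of [find_ess()] outputs, keyed
#'   `omega=..,tau=..`) and `table`, a long-format data frame with one row
#'   per (omega, tau, phenotype) giving the equilibrium frequency plus the
#'   uniqueness/cycling flags.
#' @export
phase_diagram <- function(M_hs, M_bos, omega_grid = egt_defaults()$omega_grid,
                          tau_grid = NULL, ...) {
  stopifnot(inherits(M_hs, "payoff_matrix"), inherits(M_bos, "payoff_matrix"))
  if (is.null(tau_grid)) {
    tau_grid <- intersect(M_hs$checkpoints, M_bos$checkpoints)
    if (!length(tau_grid))
      fail_field("tau_grid", "the two payoff matrices share no checkpoints")
  }
  results <- list()
  rows <- list()
  for (tau in tau_grid) for (omega in omega_grid) {
    M <- mixed_payoff(M_hs, M_bos, omega, tau = tau)
    key <- sprintf("omega=%g,tau=%d", omega, as.integer(tau))
    ess <- find_ess(M, ...)
    results[[key]] <- ess
    rows[[key]] <- data.frame(
      omega = omega, tau = as.integer(tau),
      phenotype = names(ess$equilibrium),
      frequency = unname(ess$equilibrium),
      unique = ess$unique, cycling = ess$cycling,
      row.names = NULL
    )
  }
  list(results = results, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}
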