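# Heavy shared artifacts, computed once per test run and memoised.
# Study conditions: tau = 512 trials, 500 Monte-Carlo repetitions per pair,
# payoffs checkpointed at powers of two for the evolutionary analyses.

.artifacts <- new.env(parent = emptyenv())

artifact <- function(name, fn) {
  if (is.null(.artifacts[[name]])) .artifacts[[name]] <- fn()
  .artifacts[[name]]
}

PHENO5 <- c("tom0", "tom1", "tom2", "tom3", "tom4")
PHENO7 <- c(PHENO5, "rl", "nash")
TAU <- 512L
N_REPS <- 500L
CHECKPOINTS <- 2^(0:9)

hs_game <- function() default_games()$hide_and_seek
bos_game <- function() default_games()$battle_of_the_sexes

# 7-phenotype tournaments; the 5-phenotype matrices are the tom0..tom4 block
hs_pm7 <- function() artifact("hs_pm7", function()
  payoff_matrix(PHENO7, hs_game(), tau = TAU, n_reps = N_REPS, seed = 1,
                checkpoints = CHECKPOINTS))
bos_pm7 <- function() artifact("bos_pm7", function()
  payoff_matrix(PHENO7, bos_game(), tau = TAU, n_reps = N_REPS, seed = 2,
                checkpoints = CHECKPOINTS))

subset_pm <- function(pm, keep) {
  pm$by_tau <- lapply(pm$by_tau, function(m) m[keep, keep])
  pm$se_by_tau <- lapply(pm$se_by_tau, function(m) m[keep, keep])
  pm$matrix <- pm$by_tau[[length(pm$by_tau)]]
  pm$se <- pm$se_by_tau[[length(pm$se_by_tau)]]
  pm$phenotypes <- keep
  pm
}
hs_pm5 <- function() subset_pm(hs_pm7(), PHENO5)
bos_pm5 <- function() subset_pm(bos_pm7(), PHENO5)

twin_records <- function(pheno, game_name, n = 100, seed_off = 0) {
  key <- paste("twin", pheno, game_name, n, seed_off, sep = "_")
  artifact(key, function() {
    g <- default_games()[[game_name]]
    play_many(pheno, pheno, g, tau = TAU, n_reps = n,
              seed = child_seed(101, seed_off))
  })
}

phase5 <- function() artifact("phase5", function()
  phase_diagram(hs_pm5(), bos_pm5(), omega_grid = seq(0, 1, 0.1),
                n_init = 32, seed = 11))
# 7-phenotype grid: thinned tau grid and fewer initial conditions to bound
# runtime (the zero-sum column is payoff-neutral for Nash and integrates to
# the full step budget)
phase7 <- function() artifact("phase7", function()
  phase_diagram(hs_pm7(), bos_pm7(), omega_grid = seq(0, 1, 0.1),
                tau_grid = c(2, 8, 32, 128, 512), n_init = 8, seed = 13))

pair_average <- function(M, i, j) (M[i, j] + M[j, i]) / 2
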