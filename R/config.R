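# Reproducible experiment driver: configuration, validation, end-to-end runs.

#' Read and validate a run configuration
#'
#' Configurations are YAML (JSON is valid YAML and therefore also accepted).
#' Missing blocks are filled from the shipped `defaults.yaml`. Validation
#' reports offending field paths before any computation starts.
#'
#' @param path Path to a YAML/JSON config file, or a named list with the
#'   same structure.
#' @return Validated config list with fields `games` (named [game_spec()]
#'   list), `phenotypes`, `agents`, `tournament` (`tau`, `n_reps`, `seed`,
#'   `checkpoints`), `egt` and `output`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) fail_field("config", "must be a YAML file or a list")
  def <- yaml::read_yaml(system.file("extdata", "defaults.yaml", package = "ktom"))
  merge_block <- function(user, fallback) {
    if (is.null(user)) return(fallback)
    for (nm in names(fallback)) if (is.null(user[[nm]])) user[[nm]] <- fallback[[nm]]
    user
  }
  cfg <- list()
  cfg$games <- if (is.null(raw$games)) default_games() else {
    if (is.character(raw$games)) load_games(raw$games) else {
      out <- lapply(names(raw$games), function(nm)
        game_spec(nm, raw$games[[nm]]$u1, raw$games[[nm]]$u2))
      stats::setNames(out, names(raw$games))
    }
  }
  for (nm in c("hide_and_seek", "battle_of_the_sexes"))
    if (is.null(cfg$games[[nm]]))
      fail_field(paste0("games.", nm), "game definition missing")
  cfg$phenotypes <- if (is.null(raw$phenotypes))
    c("tom0", "tom1", "tom2", "tom3", "tom4") else as.character(raw$phenotypes)
  for (i in seq_along(cfg$phenotypes))
    if (!grepl(PHENO_RE, cfg$phenotypes[i]))
      fail_field(sprintf("phenotypes[%d]", i), "must match tom<k>, rl or nash")
  cfg$agents <- merge_block(raw$agents, def$agents)
  if (cfg$agents$beta <= 0) fail_field("agents.beta", "must be positive")
  cfg$tournament <- merge_block(raw$tournament, def$tournament)
  tb <- cfg$tournament
  if (!is.numeric(tb$tau) || tb$tau < 1) fail_field("tournament.tau", "must be >= 1")
  if (!is.numeric(tb$n_reps) || tb$n_reps < 1) fail_field("tournament.n_reps", "must be >= 1")
  if (is.null(tb$checkpoints)) {
    cps <- 2^(0:floor(log2(tb$tau)))
    cfg$tournament$checkpoints <- sort(unique(c(cps, tb$tau)))
  }
  cfg$egt <- merge_block(raw$egt, def$egt)
  if (any(cfg$egt$omega_grid < 0 | cfg$egt$omega_grid > 1))
    fail_field("egt.omega_grid", "entries must lie in [0, 1]")
  user_tau_grid <- !is.null(raw$egt) && !is.null(raw$egt$tau_grid)
  if (is.null(cfg$egt$tau_grid)) cfg$egt$tau_grid <- cfg$tournament$checkpoints
  if (!user_tau_grid) {
    # the default grid is clipped to what this tournament actually records
    cfg$egt$tau_grid <- intersect(cfg$egt$tau_grid, cfg$tournament$checkpoints)
    if (!length(cfg$egt$tau_grid)) cfg$egt$tau_grid <- cfg$tournament$checkpoints
  }
  bad <- setdiff(cfg$egt$tau_grid, cfg$tournament$checkpoints)
  if (length(bad))
    fail_field("egt.tau_grid", paste("not among tournament checkpoints:",
                                     paste(bad, collapse = ", ")))
  cfg$output <- if (is.null(raw$output)) "." else raw$output
  cfg
}

agent_spec_from_config <- function(phenotype, agents_block) {
  list(phenotype = phenotype,
       sigma = exp(agents_block$log_sigma),
       beta = agents_block$beta,
       alpha = agents_block$rl_alpha)
}

write_matrix_csv <- function(pm, path) {
  rows <- list()
  for (key in names(pm$by_tau)) {
    M <- pm$by_tau[[key]]; S <- pm$se_by_tau[[key]]
    idx <- expand.grid(row = rownames(M), col = colnames(M),
                       stringsAsFactors = FALSE)
    rows[[key]] <- data.frame(
      game = pm$game, tau = as.integer(key),
      phenotype_row = idx$row, phenotype_col = idx$col,
      mean_payoff = M[as.matrix(idx)], se = S[as.matrix(idx)]
    )
  }
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
                   path, row.names = FALSE)
}

#' Run a full experiment from a configuration
#'
#' Executes the tournament (both games, all phenotype pairs, with payoff
#' checkpoints), the behavioural metrics for every pair, and the
#' evolutionary phase diagram, writing CSV outputs plus a JSON manifest
#' (resolved configuration and content hashes) to the output directory.
#' Identical configurations and seeds give byte-identical CSVs.
#'
#' @param config Path to a YAML/JSON config, or a config list (see
#'   [read_run_config()]).
#' @param output Output directory; overrides the config's `output` field.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) the output directory path.
#' @export
run_experiment <- function(config, output = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  out_dir <- if (is.null(output)) cfg$output else output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tb <- cfg$tournament
  specs <- lapply(cfg$phenotypes, agent_spec_from_config,
                  agents_block = cfg$agents)
  t0 <- Sys.time()
  say("tournament: %d phenotypes, tau = %d, %d reps, seed %d",
      length(specs), tb$tau, tb$n_reps, tb$seed)
  pms <- list()
  for (gname in c("hide_and_seek", "battle_of_the_sexes")) {
    say("  game %s ...", gname)
    pms[[gname]] <- payoff_matrix(specs, cfg$games[[gname]], tau = tb$tau,
                                  n_reps = tb$n_reps, seed = tb$seed,
                                  checkpoints = tb$checkpoints)
    write_matrix_csv(pms[[gname]], file.path(out_dir, paste0("payoffs_", gname, ".csv")))
  }
  say("metrics ...")
  met <- metrics_table(specs, cfg, n_reps = min(tb$n_reps, 100))
  utils::write.csv(met, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  say("phase diagram ...")
  pd <- phase_diagram(pms$hide_and_seek, pms$battle_of_the_sexes,
                      omega_grid = cfg$egt$omega_grid,
                      tau_grid = cfg$egt$tau_grid,
                      n_init = cfg$egt$n_init, seed = tb$seed,
                      tol = cfg$egt$tol, t_max = cfg$egt$t_max,
                      dt = cfg$egt$dt,
                      uniqueness_tol = cfg$egt$uniqueness_tol,
                      extinction_threshold = cfg$egt$extinction_threshold)
  utils::write.csv(pd$table, file.path(out_dir, "phase_diagram.csv"),
                   row.names = FALSE)
  resolved <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(config_serialisable(cfg), resolved)
  files <- c("payoffs_hide_and_seek.csv", "payoffs_battle_of_the_sexes.csv",
             "metrics.csv", "phase_diagram.csv", "config_resolved.yaml")
  manifest <- list(
    package = "ktom",
    version = as.character(utils::packageVersion("ktom")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = tb$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(out_dir)
}

config_serialisable <- function(cfg) {
  cfg$games <- lapply(cfg$games, function(g)
    list(u1 = apply(g$u1, 1, as.numeric, simplify = FALSE),
         u2 = apply(g$u2, 1, as.numeric, simplify = FALSE)))
  cfg
}

# Behavioural metrics (prediction slope, thresholded prediction rate,
# attributed level) averaged over repetitions, for every unordered pair.
metrics_table <- function(specs, cfg, n_reps) {
  tb <- cfg$tournament
  rows <- list()
  for (gname in c("hide_and_seek", "battle_of_the_sexes")) {
    game <- cfg$games[[gname]]
    q <- 0L
    K <- length(specs)
    for (i in seq_len(K)) for (j in i:K) {
      q <- q + 1L
      recs <- play_many(specs[[i]], specs[[j]], game, tau = tb$tau,
                        n_reps = n_reps, seed = child_seed(tb$seed, 7L, q))
      met_one <- function(w) {
        lev <- pheno_level(specs[[if (w == 1) i else j]]$phenotype)
        slopes <- vapply(recs, prediction_accuracy_slope, numeric(1), which_player = w)
        rates <- vapply(recs, correct_prediction_rate, numeric(1), which_player = w)
        att <- if (!is.na(lev) && lev >= 1)
          vapply(recs, attributed_level, numeric(1), which_player = w) else NA_real_
        data.frame(
          game = gname, player = w,
          phenotype = specs[[if (w == 1) i else j]]$phenotype,
          opponent = specs[[if (w == 1) j else i]]$phenotype,
          mean_slope = mean(slopes, na.rm = FALSE),
          mean_prediction_rate = mean(rates),
          modal_attributed_level = if (all(is.na(att))) NA_integer_ else
            as.integer(names(which.max(table(att))))
        )
      }
      rows[[paste(gname, q, 1)]] <- met_one(1)
      rows[[paste(gname, q, 2)]] <- met_one(2)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
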