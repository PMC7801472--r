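test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(T = 0), "T")
  expect_error(simulation_config(N = 1), "N")
  expect_error(simulation_config(init_spiteful = 60), "init_spiteful")
  expect_error(simulation_config(snapshot_rounds = 10, T = 5),
               "snapshot_rounds")
  cfg <- simulation_config(N = 10, T = 100, init_spiteful = 0.5)
  expect_identical(cfg$init_spiteful, 5)
})

test_that("a two-agent mixed round converts the social agent", {
  # forced mutual visits: the social agent averages c, the spiteful b > c,
  # so with lam = 1 and no error the population ends all-spiteful
  cfg <- simulation_config(N = 2, T = 1, lam = 1, e = 0, epsilon = 0,
                           record_every = 1, seed = 1, init_spiteful = 1)
  sim <- run_simulation(cfg)
  expect_identical(fixation_state(sim$state$strategies), "spiteful_fixated")
})

test_that("a round without imitation or discounting only reinforces visited links", {
  # all-social so every visit pays 1 and visibly bumps exactly one link
  cfg <- simulation_config(N = 6, T = 1, lam = 0, delta = 0,
                           record_every = 1, seed = 2, init_spiteful = 0)
  set.seed(cfg$seed)
  state0 <- init_state(cfg)
  out <- run_round(state0, cfg)
  expect_identical(out$state$strategies, state0$strategies)
  changed <- out$state$w != state0$w
  expect_identical(unname(rowSums(changed)), rep(1, 6))
  for (i in 1:6)
    expect_identical(unname(which(changed[i, ])), out$record$visits[i])
})

test_that("interaction accounting: N games, 2N interaction slots per round", {
  cfg <- simulation_config(N = 9, T = 1, record_every = 1, seed = 3)
  set.seed(cfg$seed)
  out <- run_round(init_state(cfg), cfg)
  rec <- out$record
  expect_identical(length(rec$visits), 9L)
  expect_true(all(rec$visits != seq_len(9)))
  expect_identical(sum(rec$n_interactions), 18L)
  expect_true(all(rec$n_interactions >= 1L))
})

test_that("a homogeneous social population stays homogeneous without error", {
  cfg <- simulation_config(N = 8, T = 200, lam = 0.5, e = 0,
                           init_spiteful = 0, record_every = 200, seed = 4)
  sim <- run_simulation(cfg)
  expect_identical(fixation_state(sim$state$strategies), "social_fixated")
})

test_that("runs are deterministic given a seed", {
  cfg <- simulation_config(N = 12, T = 400, record_every = 100, seed = 99,
                           lam = 0.1)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$state, b$state)
})

test_that("compiled and reference engines agree bit-for-bit", {
  for (rule in c("average_payoff", "total_payoff", "moran")) {
    cfg <- simulation_config(N = 8, T = 80, record_every = 20, seed = 7,
                             lam = 0.3, e = 0.05, rule = rule)
    a <- run_simulation(cfg, use_compiled = TRUE)
    b <- run_simulation(cfg, use_compiled = FALSE)
    expect_identical(a$metrics, b$metrics)
    expect_identical(a$state$w, b$state$w)
    expect_identical(a$state$strategies, b$state$strategies)
  }
  # population-wide candidate pool path as well
  cfg <- simulation_config(N = 8, T = 80, record_every = 20, seed = 8,
                           lam = 0.3, candidate_pool = "all_agents")
  expect_identical(run_simulation(cfg, TRUE)$metrics,
                   run_simulation(cfg, FALSE)$metrics)
})

test_that("metrics are recorded on the cadence plus the final round", {
  cfg <- simulation_config(N = 6, T = 2500, record_every = 1000, seed = 5)
  sim <- run_simulation(cfg)
  expect_identical(sim$metrics$round, c(1000L, 2000L, 2500L))
  expect_identical(sim$metrics$seed, rep(5L, 3))
})

test_that("snapshots are taken at the requested rounds", {
  cfg <- simulation_config(N = 6, T = 50, record_every = 25, seed = 6,
                           snapshot_rounds = c(10L, 50L))
  sim <- run_simulation(cfg)
  expect_identical(names(sim$snapshots), c("10", "50"))
  expect_identical(dim(sim$snapshots[["10"]]), c(6L, 6L))
  # snapshot-only rounds do not add metrics rows
  expect_identical(sim$metrics$round, c(25L, 50L))
})

test_that("stop_on_fixation halts a homogeneous run at the first record", {
  cfg <- simulation_config(N = 6, T = 5000, record_every = 100, seed = 7,
                           init_spiteful = 0, e = 0, stop_on_fixation = TRUE)
  sim <- run_simulation(cfg)
  expect_true(sim$stopped_early)
  expect_identical(nrow(sim$metrics), 1L)
})

test_that("sweeps combine runs with config columns and derived seeds", {
  grid <- expand.grid(N = c(6, 8), b = 10 / 11)
  grid$c <- 1 - grid$b
  out <- run_sweep(grid, seeds = 2, master_seed = 1, T = 60,
                   record_every = 60, lam = 0.1)
  expect_identical(nrow(out), 4L)
  expect_identical(sort(unique(out$N)), c(6, 8))
  expect_true(all(c("config_id", "seed", "frac_spiteful") %in% names(out)))
  expect_identical(anyDuplicated(out[, c("config_id", "seed")]), 0L)
  # a single-cell sweep reproduces run_simulation under the derived seed
  one <- run_sweep(grid[1, , drop = FALSE], seeds = 1, master_seed = 1,
                   T = 60, record_every = 60, lam = 0.1)
  direct <- run_simulation(simulation_config(N = 6, T = 60, record_every = 60,
                                             lam = 0.1,
                                             seed = derive_seeds(1, 1)))
  expect_identical(one$frac_spiteful, direct$metrics$frac_spiteful)
  expect_error(run_sweep(grid[0, , drop = FALSE]), "non-empty")
  expect_error(run_sweep(data.frame(bogus = 1)), "unknown configuration")
})

test_that("metrics CSV export has the fixed header", {
  cfg <- simulation_config(N = 6, T = 40, record_every = 20, seed = 8)
  sim <- run_simulation(cfg)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(sim, path)
  got <- read.csv(path)
  expect_identical(names(got), c(
    "seed", "round", "frac_spiteful", "a_bar", "a_social", "a_spiteful",
    "share_soc_soc", "share_soc_spite", "share_spite_soc",
    "share_spite_spite", "mean_payoff_social", "median_payoff_social",
    "mean_payoff_spiteful", "median_payoff_spiteful"))
  expect_identical(nrow(got), 2L)
  unlink(path)
})

test_that("network edge lists carry weights and strategies", {
  w <- matrix(0, 3, 3); w[1, 2] <- 2.5; w[3, 1] <- 0.5
  df <- network_edgelist(c(1L, 0L, 0L), w, round = 7L)
  expect_identical(nrow(df), 2L)
  expect_identical(df$source, c(1L, 3L))
  expect_identical(df$source_strategy, c("spiteful", "social"))
  expect_identical(df$weight, c(2.5, 0.5))
})

test_that("without network learning spite does not take over (population-wide pool)", {
  # frozen uniform weights (R = 0, delta = 0) and population-wide
  # candidates: random mixing, where the dominated spiteful strategy is
  # driven out
  outcomes <- vapply(1:6, function(sd) {
    cfg <- simulation_config(N = 20, T = 8000, R = 0, delta = 0, lam = 0.05,
                             record_every = 8000, seed = sd,
                             candidate_pool = "all_agents")
    final_outcome(run_simulation(cfg))$frac_spiteful
  }, numeric(1))
  expect_gte(mean(outcomes < 0.5), 5 / 6)
})

test_that("a single spiteful invader spreads through the full model", {
  outcomes <- vapply(1:4, function(sd) {
    cfg <- simulation_config(N = 30, T = 1e5, init_spiteful = 1,
                             record_every = 1e5, seed = sd)
    final_outcome(run_simulation(cfg))$frac_spiteful
  }, numeric(1))
  expect_gte(mean(outcomes > 0.5), 3 / 4)
})
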