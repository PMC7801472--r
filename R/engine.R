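# Simulation orchestration: round structure, recording cadence, seeds.
#
# Phase order within a round (fixed): every agent selects a partner ->
# all games are played -> all link weights are discounted and reinforced
# simultaneously -> agents consider imitation. One master RNG per run;
# all stochastic sub-steps consume draws from the single seeded stream in
# a fixed documented order, so runs are bit-reproducible.

#' Simulation configuration
#'
#' Bundles and validates every parameter of a run. Defaults are the
#' baseline conditions of the model: `N = 50` agents, payoff ratio
#' `b/c = 10` (`b = 10/11`, `c = 1/11`), imitation rate `lam = 0.01`,
#' imitation error `e = 0.01`, partner-choice error `epsilon = 0.01`,
#' discount `delta = 0.01`, learning rate `R = 1`, initial-weight constant
#' `L = 9`, and an initial half/half strategy split assigned at random.
#'
#' @param N population size (>= 2).
#' @param b,c Prisoner's Delight payoffs, validated by [payoff_params()].
#' @param epsilon partner-choice error rate in `[0, 1]`.
#' @param delta link-weight discount factor in `[0, 1]`.
#' @param R network learning rate, `>= 0` (`R = 0` together with
#'   `delta = 0` freezes the initial uniform network, disabling network
#'   learning).
#' @param L initial-weight constant, positive.
#' @param lam strategy imitation rate in `[0, 1]`.
#' @param e imitation error chance in `[0, 1]`.
#' @param rule imitation rule: `"average_payoff"`, `"total_payoff"`, or
#'   `"moran"`.
#' @param candidate_pool imitation candidate pool, see
#'   [imitation_params()]: `"interaction_partners"` (default) or
#'   `"all_agents"`.
#' @param discount_scope `"all"` or `"visited_only"`, see
#'   [reinforce_weights()].
#' @param T number of rounds, at least 1.
#' @param seed integer RNG seed for the run.
#' @param record_every recording cadence in rounds (the final round is
#'   always recorded).
#' @param init_spiteful initial spiteful count (integer >= 1) or fraction
#'   (in `[0, 1)`); default 0.5, i.e. half the population.
#' @param stop_on_fixation if `TRUE`, stop at the first *recorded* round
#'   at which the population is homogeneous. Off by default: with `e > 0`
#'   fixation is not absorbing.
#' @param snapshot_rounds optional integer vector of rounds at which to
#'   keep a copy of the weight matrix.
#' @param normalize passed to [payoff_params()].
#' @return an object of class `"sim_config"`.
#' @export
simulation_config <- function(N = 50, b = 10 / 11, c = 1 / 11,
                              epsilon = 0.01, delta = 0.01, R = 1, L = 9,
                              lam = 0.01, e = 0.01,
                              rule = c("average_payoff", "total_payoff", "moran"),
                              candidate_pool = c("interaction_partners",
                                                 "all_agents"),
                              discount_scope = c("all", "visited_only"),
                              T = 1e6, seed = 1L, record_every = 1000,
                              init_spiteful = 0.5, stop_on_fixation = FALSE,
                              snapshot_rounds = integer(),
                              normalize = FALSE) {
  rule <- match.arg(rule)
  discount_scope <- match.arg(discount_scope)
  stopifnot(N == as.integer(N), N >= 2,
            epsilon >= 0, epsilon <= 1, delta >= 0, delta <= 1,
            R >= 0, L > 0, T == as.integer(T), T >= 1,
            record_every == as.integer(record_every), record_every >= 1,
            seed == as.integer(seed))
  payoffs <- payoff_params(b, c, normalize = normalize)
  imit <- imitation_params(lam, e, rule, candidate_pool)
  if (init_spiteful < 0 || init_spiteful > N)
    stop("init_spiteful must lie in [0, N]")
  k <- if (init_spiteful < 1 && init_spiteful > 0) round(N * init_spiteful)
       else as.integer(init_spiteful)
  snapshot_rounds <- as.integer(snapshot_rounds)
  if (length(snapshot_rounds) && any(snapshot_rounds < 1 | snapshot_rounds > T))
    stop("snapshot_rounds must lie in [1, T]")
  structure(list(N = as.integer(N), payoffs = payoffs,
                 epsilon = epsilon, delta = delta, R = R, L = L,
                 imitation = imit, discount_scope = discount_scope,
                 T = as.integer(T), seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 init_spiteful = k, stop_on_fixation = stop_on_fixation,
                 snapshot_rounds = snapshot_rounds),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: N = %d, b = %.4g, c = %.4g, rule = %s\n  epsilon = %g, delta = %g, R = %g, L = %g, lam = %g, e = %g\n  T = %d rounds, seed = %d, record_every = %d, init spiteful = %d\n",
    x$N, x$payoffs$b, x$payoffs$c, x$imitation$rule,
    x$epsilon, x$delta, x$R, x$L, x$imitation$lam, x$imitation$e,
    x$T, x$seed, x$record_every, x$init_spiteful))
  invisible(x)
}

#' Initial population state for a configuration
#'
#' Assigns `init_spiteful` agents the spiteful strategy at random positions
#' (consuming RNG draws) and builds the uniform initial weight matrix.
#'
#' @param config a [simulation_config()] object.
#' @return a list with elements `strategies`, `w`, `round` (0).
#' @export
init_state <- function(config) {
  s <- sample(c(rep(1L, config$init_spiteful),
                rep(0L, config$N - config$init_spiteful)))
  list(strategies = s, w = init_weights(config$N, config$L), round = 0L)
}

#' One full round (reference implementation)
#'
#' Pure-R implementation of one round: partner selection, play, weight
#' update, imitation. The compiled engine used by [run_simulation()]
#' mirrors this function draw-for-draw; it exists as the readable
#' reference and for unit tests on small populations.
#'
#' @param state list with `strategies`, `w`, `round`.
#' @param config a [simulation_config()] object.
#' @return list with the new `state` and the round `record` (a list with
#'   `visits`, `payoff_total`, `n_interactions`, `strategies_played`).
#' @export
run_round <- function(state, config) {
  s <- as_strategy(state$strategies)
  w <- state$w
  n <- config$N
  b <- config$payoffs$b
  c <- config$payoffs$c
  visits <- integer(n)
  for (i in seq_len(n)) visits[i] <- .choose_host(i, w, config$epsilon)
  ptot <- numeric(n)
  nint <- integer(n)
  vpay <- numeric(n)
  for (i in seq_len(n)) {
    j <- visits[i]
    pv <- 1 - c * s[i] - b * s[j]   # visitor i's payoff
    ph <- 1 - c * s[j] - b * s[i]   # host j's payoff
    vpay[i] <- pv
    ptot[i] <- ptot[i] + pv
    nint[i] <- nint[i] + 1L
    ptot[j] <- ptot[j] + ph
    nint[j] <- nint[j] + 1L
  }
  w <- reinforce_weights(w, visits, vpay, config$delta, config$R,
                         config$discount_scope)
  new_s <- if (config$imitation$rule == "moran") {
    moran_step(s, ptot, nint, config$imitation$e)
  } else {
    imitation_step(s, w, ptot, nint, config$imitation, visits)
  }
  list(state = list(strategies = new_s, w = w, round = state$round + 1L),
       record = list(visits = visits, payoff_total = ptot,
                     n_interactions = nint, strategies_played = s))
}

# Metrics row assembled from the post-round state and the round record.
# Correlations and the spiteful fraction describe the state after
# imitation; coupling shares and payoff summaries describe the round as
# played (pre-imitation strategies).
.metrics_row <- function(seed, round, state, record) {
  corr <- correlation_summary(state$strategies, state$w)
  shares <- coupling_shares(record$visits, record$strategies_played)
  pays <- payoff_summary(record$payoff_total, record$n_interactions,
                         record$strategies_played)
  data.frame(seed = seed, round = round,
             frac_spiteful = mean(as_strategy(state$strategies) == 1L),
             a_bar = corr$a_bar, a_social = corr$a_social,
             a_spiteful = corr$a_spiteful,
             share_soc_soc = shares[["soc_soc"]],
             share_soc_spite = shares[["soc_spite"]],
             share_spite_soc = shares[["spite_soc"]],
             share_spite_spite = shares[["spite_spite"]],
             mean_payoff_social = pays[["mean_payoff_social"]],
             median_payoff_social = pays[["median_payoff_social"]],
             mean_payoff_spiteful = pays[["mean_payoff_spiteful"]],
             median_payoff_spiteful = pays[["median_payoff_spiteful"]])
}

#' Run one simulation
#'
#' Runs `config$T` rounds from a fresh seeded state, recording a metrics
#' row every `record_every` rounds and at the final round. Deterministic:
#' the same configuration and seed yield bit-identical output.
#'
#' @param config a [simulation_config()] object.
#' @param use_compiled if `TRUE` (default) run rounds in the compiled
#'   engine; `FALSE` uses the pure-R [run_round()] reference. Both consume
#'   the RNG stream identically, so results agree exactly.
#' @return an object of class `"spite_sim"`: a list with `metrics` (a
#'   data.frame of recorded rows), `state` (final `strategies`, `w`,
#'   `round`), `config`, and `snapshots` (named list of weight matrices at
#'   `snapshot_rounds`).
#' @examples
#' cfg <- simulation_config(N = 10, T = 200, record_every = 100, seed = 42)
#' sim <- run_simulation(cfg)
#' sim$metrics
#' @export
run_simulation <- function(config, use_compiled = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_state(config)
  marks <- sort(unique(c(seq(0L, config$T, by = config$record_every)[-1],
                         config$T, config$snapshot_rounds)))
  rows <- vector("list", length(marks))
  snapshots <- list()
  imit <- config$imitation
  rule_code <- match(imit$rule, c("average_payoff", "total_payoff", "moran")) - 1L
  done <- 0L
  stopped_early <- FALSE
  for (k in seq_along(marks)) {
    nsteps <- marks[k] - done
    if (use_compiled) {
      res <- run_rounds_cpp(state$w, state$strategies, nsteps,
                            config$payoffs$b, config$payoffs$c,
                            config$epsilon, config$delta, config$R,
                            imit$lam, imit$e, rule_code,
                            config$discount_scope == "all",
                            imit$candidate_pool == "interaction_partners")
      state <- list(strategies = res$strategies, w = res$w,
                    round = state$round + nsteps)
      record <- list(visits = res$visits, payoff_total = res$payoff_total,
                     n_interactions = res$n_interactions,
                     strategies_played = res$strategies_played)
    } else {
      for (step in seq_len(nsteps)) {
        out <- run_round(state, config)
        state <- out$state
        record <- out$record
      }
    }
    done <- marks[k]
    rows[[k]] <- .metrics_row(config$seed, done, state, record)
    if (done %in% config$snapshot_rounds)
      snapshots[[as.character(done)]] <- state$w
    if (config$stop_on_fixation && fixation_state(state$strategies) != "none") {
      rows <- rows[seq_len(k)]
      stopped_early <- TRUE
      break
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  keep <- metrics$round %% config$record_every == 0 | metrics$round == config$T
  structure(list(metrics = metrics[keep, , drop = FALSE], state = state,
                 config = config, snapshots = snapshots,
                 stopped_early = stopped_early),
            class = "spite_sim")
}

#' @export
print.spite_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "spite_sim: N = %d, %d rounds run (seed %d)\n  final: %s, spiteful fraction %.3f, a_bar %.4f (social %.4f, spiteful %.4f)\n",
    x$config$N, x$state$round, x$config$seed,
    fixation_state(x$state$strategies), last$frac_spiteful,
    last$a_bar, last$a_social, last$a_spiteful))
  invisible(x)
}

#' Final outcome of a run
#'
#' @param sim a `"spite_sim"` object.
#' @return list with `fixation` (final [fixation_state()]), `frac_spiteful`
#'   at the final round, and `round` reached.
#' @export
final_outcome <- function(sim) {
  stopifnot(inherits(sim, "spite_sim"))
  list(fixation = fixation_state(sim$state$strategies),
       frac_spiteful = mean(as_strategy(sim$state$strategies) == 1L),
       round = sim$state$round)
}
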