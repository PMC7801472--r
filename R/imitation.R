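# Strategy updating by imitation. Baseline rule: with probability lam each
# agent considers imitation; it samples a candidate in proportion to the
# combined outgoing + incoming weight (how often the two interact) and
# copies the candidate's strategy iff the candidate's average payoff per
# interaction this round was strictly greater than its own. An imitation
# error (probability e) replaces the whole outcome with a uniform draw over
# the two strategies. Variants: total-payoff comparison, and a Moran-style
# birth-death event.

#' Imitation parameters
#'
#' @param lam per-agent per-round probability of considering imitation, in
#'   `[0, 1]`. (The imitation rate; one symbol for what the source model
#'   writes as either lambda or gamma.)
#' @param e imitation error chance in `[0, 1]`: when an agent considers
#'   imitation, with probability `e` it adopts a uniformly random strategy
#'   instead (which can reproduce its own strategy with probability 1/2).
#' @param rule `"average_payoff"` (default), `"total_payoff"`, or
#'   `"moran"`. Under `"moran"` the per-agent considerations are replaced
#'   by one birth-death event per round (see [moran_step()]).
#' @param candidate_pool `"interaction_partners"` (default): candidates are
#'   the agents interacted with in the just-finished round, weighted by
#'   combined link weight; `"all_agents"`: candidates are all other agents
#'   with the full [imitation_candidate_probs()] distribution. The partner
#'   pool is the behavior under which spite spreads at the baseline
#'   parameters and mirrors the interaction-set imitation of the
#'   best-response analytic model; the population-wide pool is retained for
#'   sensitivity analysis.
#' @return an object of class `"imitation_params"`.
#' @export
imitation_params <- function(lam = 0.01, e = 0.01,
                             rule = c("average_payoff", "total_payoff", "moran"),
                             candidate_pool = c("interaction_partners",
                                                "all_agents")) {
  rule <- match.arg(rule)
  candidate_pool <- match.arg(candidate_pool)
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0, lam <= 1,
            is.numeric(e), length(e) == 1L, e >= 0, e <= 1)
  structure(list(lam = lam, e = e, rule = rule,
                 candidate_pool = candidate_pool),
            class = "imitation_params")
}

#' @export
print.imitation_params <- function(x, ...) {
  cat(sprintf("imitation: rule = %s, lam = %g, e = %g, pool = %s\n",
              x$rule, x$lam, x$e, x$candidate_pool))
  invisible(x)
}

#' Imitation-candidate probabilities for one agent
#'
#' The chance of considering agent `j` is proportional to the combined
#' weight `w[i, j] + w[j, i]`, i.e. to how often `i` and `j` interact in
#' either direction. Self is excluded.
#'
#' @param i agent index (1-based).
#' @param w weight matrix.
#' @return numeric vector of length `N` summing to 1, with `p[i] = 0`.
#' @export
imitation_candidate_probs <- function(i, w) {
  n <- nrow(w)
  stopifnot(i >= 1, i <= n)
  m <- w[i, ] + w[, i]
  m[i] <- 0
  s <- sum(m)
  if (s <= 0) stop("agent ", i, " has zero combined link weight (degenerate state)")
  m / s
}

# Candidate draw for agent i consuming one uniform (the caller supplies it
# so the draw order stays fixed and mirrored in the compiled engine).
.choose_candidate <- function(i, w, u) {
  n <- nrow(w)
  others <- seq_len(n)[-i]
  m <- w[i, others] + w[others, i]
  others[.walk_index(m, u)]
}

# Comparison value per agent under a rule: average payoff per interaction
# (baseline) or round total.
.imitation_values <- function(payoff_total, n_interactions, rule) {
  if (rule == "total_payoff") payoff_total else payoff_total / n_interactions
}

# Per-agent lists of this round's interaction partners, in the canonical
# order (ascending visitor index, host inserted at the owner's own turn),
# deduplicated by first occurrence. Mirrored in the compiled engine.
.partner_pools <- function(visits) {
  n <- length(visits)
  pools <- vector("list", n)
  for (i in seq_len(n)) {
    j <- visits[i]
    pools[[i]] <- c(pools[[i]], j)
    pools[[j]] <- c(pools[[j]], i)
  }
  lapply(pools, unique)
}

# Candidate draw from agent i's partner pool, proportional to combined
# link weight, consuming one supplied uniform.
.choose_pool_candidate <- function(i, pool, w, u) {
  m <- w[i, pool] + w[pool, i]
  pool[.walk_index(m, u)]
}

#' One synchronous imitation phase
#'
#' Each agent independently considers imitation with probability `lam`.
#' A considering agent errs with probability `e` (uniform random strategy);
#' otherwise it samples a candidate — by default from the agents it
#' interacted with in the just-finished round, in proportion to the
#' combined link weight `w[i, j] + w[j, i]` (with
#' `candidate_pool = "all_agents"`, from the whole population via
#' [imitation_candidate_probs()]) — and copies the candidate's strategy if
#' and only if the candidate's comparison value this round (average payoff
#' per interaction, or round total under `rule = "total_payoff"`) is
#' strictly greater than its own. All adoptions are applied simultaneously
#' from the pre-update strategy vector, so decisions within a round never
#' cascade.
#'
#' @param strategies strategy vector (see [as_strategy()]).
#' @param w weight matrix after this round's reinforcement.
#' @param payoff_total numeric vector of per-agent total payoff this round.
#' @param n_interactions integer vector of per-agent interaction counts
#'   this round (each at least 1: every agent visits once).
#' @param params an [imitation_params()] object with rule
#'   `"average_payoff"` or `"total_payoff"`.
#' @param visits integer vector of this round's hosts, required when
#'   `params$candidate_pool == "interaction_partners"`.
#' @return the new integer strategy vector.
#' @export
imitation_step <- function(strategies, w, payoff_total, n_interactions,
                           params, visits = NULL) {
  stopifnot(inherits(params, "imitation_params"),
            params$rule %in% c("average_payoff", "total_payoff"))
  s <- as_strategy(strategies)
  n <- length(s)
  stopifnot(nrow(w) == n, length(payoff_total) == n,
            length(n_interactions) == n, all(n_interactions >= 1))
  partner_pool <- params$candidate_pool == "interaction_partners"
  if (partner_pool) {
    if (is.null(visits))
      stop("visits required for candidate_pool = \"interaction_partners\"")
    pools <- .partner_pools(visits)
  }
  vals <- .imitation_values(payoff_total, n_interactions, params$rule)
  new_s <- s
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u >= params$lam) next
    u2 <- runif(1)
    if (u2 < params$e) {
      u3 <- runif(1)
      new_s[i] <- if (u3 < 0.5) 0L else 1L
    } else {
      u3 <- runif(1)
      j <- if (partner_pool) .choose_pool_candidate(i, pools[[i]], w, u3)
           else .choose_candidate(i, w, u3)
      if (vals[j] > vals[i]) new_s[i] <- s[j]
    }
  }
  new_s
}

#' One Moran-style birth-death event
#'
#' A reproducing agent is chosen with probability proportional to its
#' average payoff per interaction this round (uniformly if all payoffs are
#' zero); a uniformly random distinct agent adopts the reproducer's
#' strategy. With probability `e` the adopted strategy is replaced by a
#' uniform random one.
#'
#' @param strategies strategy vector.
#' @param payoff_total,n_interactions per-agent round totals and counts.
#' @param e imitation error chance.
#' @return the new integer strategy vector.
#' @export
moran_step <- function(strategies, payoff_total, n_interactions, e) {
  s <- as_strategy(strategies)
  n <- length(s)
  stopifnot(length(payoff_total) == n, length(n_interactions) == n,
            all(n_interactions >= 1), all(payoff_total >= 0))
  fit <- payoff_total / n_interactions
  u <- runif(1)
  rep_i <- .walk_index(fit, u)  # uniform fallback when all payoffs zero
  u2 <- runif(1)
  others <- seq_len(n)[-rep_i]
  target <- others[min(floor(u2 * (n - 1)) + 1, n - 1)]
  u3 <- runif(1)
  if (u3 < e) {
    u4 <- runif(1)
    s[target] <- if (u4 < 0.5) 0L else 1L
  } else {
    s[target] <- s[rep_i]
  }
  s
}
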