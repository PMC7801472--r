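# Simplified best-response analytic model and mean-field benchmark.
#
# In the simplified model each agent holds exactly one discrete outgoing
# link, re-formed every step by myopic best response: link to whichever
# partner maximizes one's own payoff, ties broken uniformly at random.
# Because social partners are the best target for both strategies, in any
# mixed population every link points at a social agent. Interaction sets
# are the undirected union of in- and out-links; imitation draws uniformly
# from the weakly-better performers in one's interaction set (self
# included). Closed forms follow for the invasion of a single spiteful
# agent: the spread condition 3b - c > 2, the expected number of extra
# visitors z of the invaded host (exactly 1), and the aggregate
# correlation at invasion, (1/N)(2/3 - 2/N).

#' Best-response link formation
#'
#' Each agent links uniformly at random into its optimal-target set
#' (partners maximizing its own payoff, self excluded). Social targets
#' strictly dominate for both strategies, so in a mixed population every
#' agent links to a uniformly chosen social agent (the lone social agent
#' links uniformly among the rest); in a homogeneous population all
#' targets tie and links are uniform over all others.
#'
#' @param strategies strategy vector of length at least 2.
#' @return integer vector `out_link`, `out_link[i]` = target of agent `i`.
#' @export
best_response_links <- function(strategies) {
  s <- as_strategy(strategies)
  n <- length(s)
  if (n < 2) stop("need at least two agents")
  out <- integer(n)
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    soc <- others[s[others] == 0L]
    pool <- if (length(soc)) soc else others
    out[i] <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
  }
  out
}

#' Interaction sets implied by a link state
#'
#' `I_i` is the set of agents joined to `i` by a link in either direction.
#' Never empty: every agent has its own out-link.
#'
#' @param out_link integer vector of link targets.
#' @return list of integer vectors.
#' @export
interaction_sets <- function(out_link) {
  n <- length(out_link)
  stopifnot(all(out_link >= 1), all(out_link <= n),
            all(out_link != seq_len(n)))
  lapply(seq_len(n), function(i)
    sort(unique(c(out_link[i], which(out_link == i)))))
}

#' Average payoff per interaction in the link state
#'
#' @param out_link integer vector of link targets.
#' @param strategies strategy vector.
#' @param params a [payoff_params()] object.
#' @return numeric vector of per-agent average payoffs.
#' @export
analytic_mean_payoffs <- function(out_link, strategies, params) {
  s <- as_strategy(strategies)
  sets <- interaction_sets(out_link)
  vapply(seq_along(s), function(i)
    mean(payoff(s[i], s[sets[[i]]], params)), numeric(1))
}

#' Imitation candidate sets
#'
#' `B_i`: the members of `i`'s interaction set, plus `i` itself, whose
#' average payoff is at least `i`'s. Imitation draws uniformly from `B_i`.
#'
#' @inheritParams analytic_mean_payoffs
#' @param mean_payoffs optional precomputed [analytic_mean_payoffs()].
#' @return list of integer vectors, each containing at least `i`.
#' @export
imitation_sets <- function(out_link, strategies, params,
                           mean_payoffs = NULL) {
  if (is.null(mean_payoffs))
    mean_payoffs <- analytic_mean_payoffs(out_link, strategies, params)
  sets <- interaction_sets(out_link)
  lapply(seq_along(out_link), function(i) {
    cand <- c(i, sets[[i]])
    sort(cand[mean_payoffs[cand] >= mean_payoffs[i]])
  })
}

#' Single-invader spread condition
#'
#' A lone spiteful invader is expected to spread by imitation iff
#' `3b - c > 2` (equivalently `b > (c + 2)/3`, the expected average payoff
#' of the social host it visits).
#'
#' @param params a [payoff_params()] object.
#' @return list with `spreads` (logical) and `margin` (`3b - c - 2`).
#' @examples
#' single_invader_condition(payoff_params(10 / 11, 1 / 11))  # TRUE, 7/11
#' @export
single_invader_condition <- function(params) {
  stopifnot(inherits(params, "payoff_params"))
  margin <- 3 * params$b - params$c - 2
  list(spreads = margin > 0, margin = margin)
}

#' General invasion condition for x social, y spiteful agents
#'
#' A social agent interacting with at least one spiteful agent is expected
#' to host `(y - 1)/x` other spiteful visitors and one social visitor, so
#' its expected average payoff is
#' `(2 + c (1 + (y-1)/x)) / (3 + (y-1)/x)`; spite is expected to spread
#' whenever that falls below `b`, i.e.
#' `b (3 + (y-1)/x) - c (1 + (y-1)/x) > 2`. At `y = 1` this reduces to the
#' single-invader condition. The left-hand side is increasing in `y/x`
#' whenever the single-invader condition holds, so once spite starts
#' spreading it is expected to keep spreading.
#'
#' @param x number of social agents (>= 1).
#' @param y number of spiteful agents (>= 1).
#' @param params a [payoff_params()] object.
#' @return list with `expected_host_payoff`, `spreads`, and `lhs` (the
#'   left-hand side of the inequality, compared against 2).
#' @export
general_invasion_condition <- function(x, y, params) {
  stopifnot(inherits(params, "payoff_params"), x >= 1, y >= 1)
  ratio <- (y - 1) / x
  expected <- (2 + params$c * (1 + ratio)) / (3 + ratio)
  lhs <- params$b * (3 + ratio) - params$c * (1 + ratio)
  list(expected_host_payoff = expected, spreads = lhs > 2, lhs = lhs)
}

#' Expected number of extra visitors of the invaded host
#'
#' With a single spiteful invader visiting social agent `j`, each of the
#' other `N - 2` social agents links uniformly among the `N - 2` social
#' agents other than itself, so the number `z` of them landing on `j` is
#' Binomial(`N - 2`, `1/(N - 2)`) with expectation exactly 1.
#' `method = "exact"` sums `z` against that pmf; `method = "mc"` draws the
#' link choices themselves.
#'
#' @param N population size (>= 3).
#' @param method `"exact"` or `"mc"`.
#' @param draws Monte-Carlo sample size (ignored for `"exact"`).
#' @return list with `value`, `se` (`NA` for exact), `method`, `draws`.
#' @export
expected_extra_visitors <- function(N, method = c("exact", "mc"),
                                    draws = 1e5) {
  method <- match.arg(method)
  stopifnot(N >= 3)
  m <- N - 2       # choosers, and also each chooser's number of options
  if (method == "exact") {
    z <- 0:m
    list(value = sum(z * dbinom(z, m, 1 / m)), se = NA_real_,
         method = "exact", draws = NA_integer_)
  } else {
    # Each chooser's option list contains the host j exactly once, so a
    # uniform index draw hits j iff it falls in the first 1/m of (0, 1).
    hits <- matrix(runif(draws * m), nrow = draws) < 1 / m
    z <- rowSums(hits)
    list(value = mean(z), se = stats::sd(z) / sqrt(draws),
         method = "mc", draws = as.integer(draws))
  }
}

#' Invasion threshold as a constant on 3b - c
#'
#' Recovers, from the model itself, the constant `T` such that a single
#' spiteful invader is expected to spread iff `3b - c > T`. The expected
#' extra-visitor count `z` is computed by exact summation
#' ([expected_extra_visitors()]); the critical `b*(c)` solves
#' `b = (c + 1 + z)/(z + 2)`, and `3 b*(c) - c` is evaluated over a grid
#' of `c` and checked to be constant.
#'
#' @param N population size used for the expectation (any `N >= 3` gives
#'   the same answer since `E[z] = 1` exactly).
#' @param c_grid grid of cost values to scan.
#' @return list with `constant` (the threshold, 2), `spread` (max - min
#'   over the grid, ~ 0), and `zbar` (the expected visitor count used).
#' @export
invasion_threshold_constant <- function(N = 50,
                                        c_grid = seq(0.05, 0.45, by = 0.05)) {
  zbar <- expected_extra_visitors(N, "exact")$value
  b_crit <- (c_grid + 1 + zbar) / (zbar + 2)
  t_vals <- 3 * b_crit - c_grid
  list(constant = mean(t_vals), spread = max(t_vals) - min(t_vals),
       zbar = zbar)
}

#' Aggregate correlation at single-invader invasion (closed form)
#'
#' Expected population-mean correlation measure the moment a single
#' spiteful invader has formed its link: `(1/N)(2/3 - 2/N)`. Positive for
#' all `N > 3` and zero at `N = 3`: spite begins to invade populations of
#' four or more while strategies are, on average, positively correlated.
#' (The closed form substitutes the expected visitor count `E[z] = 1` into
#' the host's same-type share, a first-order step; the Monte-Carlo
#' cross-check [mc_abar_at_invasion()] agrees to that order.)
#'
#' @param N population size(s), each at least 2. Vectorized.
#' @return numeric vector of expected aggregate correlations.
#' @examples
#' abar_at_invasion(c(3, 4, 50))  # 0, 1/24, ~0.01253
#' @export
abar_at_invasion <- function(N) {
  stopifnot(all(N >= 2))
  (1 / N) * (2 / 3 - 2 / N)
}

#' Smallest population size with positive correlation at invasion
#'
#' Scans [abar_at_invasion()] over `N = 2..N_max` and returns the smallest
#' `N` with a strictly positive value.
#'
#' @param N_max upper end of the scan.
#' @return integer.
#' @export
smallest_positive_abar_N <- function(N_max = 10) {
  Ns <- 2:N_max
  pos <- Ns[abar_at_invasion(Ns) > 0]
  if (!length(pos)) stop("no N <= ", N_max, " gives positive a-bar")
  min(pos)
}

#' Monte-Carlo aggregate correlation at invasion
#'
#' Builds the single-invader best-response link state explicitly
#' (unit-weight matrix from [best_response_links()]) and evaluates the
#' population correlation with the same [correlation_summary()] machinery
#' used for the full model.
#'
#' @param N population size (>= 3).
#' @param replicates number of independent link draws.
#' @return numeric vector of `a_bar` values, one per replicate.
#' @export
mc_abar_at_invasion <- function(N, replicates = 50) {
  stopifnot(N >= 3, replicates >= 1)
  vapply(seq_len(replicates), function(rep) {
    s <- sample(c(1L, rep(0L, N - 1)))
    links <- best_response_links(s)
    w <- matrix(0, N, N)
    w[cbind(seq_len(N), links)] <- 1
    correlation_summary(s, w)$a_bar
  }, numeric(1))
}

#' Mean-field fitness gap under exogenous anti-correlation
#'
#' In the classic mean-field benchmark, with probability `r` an individual
#' interacts with the opposite strategy and with probability `1 - r` it
#' interacts randomly. The expected-payoff gap
#' `W_spiteful - W_social` is computed from the full expectations and
#' equals `r b - c` identically (checked internally to 1e-12), so it is
#' independent of the social frequency: spite outperforms exactly when the
#' anti-correlation exceeds the cost-to-harm ratio, `r > c/b`.
#'
#' @param r degree of anti-correlated interaction, in `[0, 1]`. Vectorized.
#' @param params a [payoff_params()] object.
#' @param freq_social frequency of the social strategy in `[0, 1]`.
#' @return numeric vector `W_spiteful - W_social`.
#' @export
meanfield_fitness_gap <- function(r, params, freq_social = 0.5) {
  stopifnot(inherits(params, "payoff_params"),
            all(r >= 0), all(r <= 1), freq_social >= 0, freq_social <= 1)
  b <- params$b; c <- params$c; x <- freq_social
  w_spite <- r * b + (1 - r) * (x * b + (1 - x) * 0)
  w_social <- r * c + (1 - r) * (x * 1 + (1 - x) * c)
  gap <- w_spite - w_social
  stopifnot(all(abs(gap - (r * b - c)) < 1e-12))
  gap
}

#' Mean-field threshold located by bisection
#'
#' Finds the zero crossing of [meanfield_fitness_gap()] in `r` by plain
#' bisection on `[0, 1]`; equals `c/b` (requires `b > c`, else no crossing
#' exists inside the interval).
#'
#' @param params a [payoff_params()] object with `b > c`.
#' @param tol bisection half-width at termination.
#' @return the crossing point `r*`.
#' @export
meanfield_threshold <- function(params, tol = 1e-12) {
  if (params$b <= params$c)
    stop("no interior crossing: requires b > c")
  lo <- 0; hi <- 1
  g_lo <- meanfield_fitness_gap(lo, params)
  stopifnot(g_lo < 0, meanfield_fitness_gap(hi, params) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (meanfield_fitness_gap(mid, params) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Stochastic simulation of the simplified model
#'
#' Iterates best-response link formation, payoff evaluation, and uniform
#' imitation from the candidate sets until the population is homogeneous
#' or `max_steps` is reached. Serves as the stochastic oracle for the
#' invasion conditions. `synchronous = TRUE` (default) updates all agents
#' from the time-t payoffs; the asynchronous variant applies copies
#' sequentially in a random order (payoffs still from time t).
#'
#' @param strategies initial strategy vector.
#' @param params a [payoff_params()] object.
#' @param max_steps step budget.
#' @param synchronous update mode, see above.
#' @return list with `outcome` (a [fixation_state()] label or `"none"`),
#'   `steps` taken, and `trajectory` (spiteful fraction per step,
#'   including the initial state).
#' @export
simulate_simplified <- function(strategies, params, max_steps = 1000,
                                synchronous = TRUE) {
  s <- as_strategy(strategies)
  n <- length(s)
  traj <- numeric(max_steps + 1)
  for (t in 0:max_steps) {
    traj[t + 1] <- mean(s == 1L)
    fx <- fixation_state(s)
    if (fx != "none")
      return(list(outcome = fx, steps = t, trajectory = traj[seq_len(t + 1)]))
    if (t == max_steps) break
    links <- best_response_links(s)
    U <- analytic_mean_payoffs(links, s, params)
    B <- imitation_sets(links, s, params, U)
    pick <- vapply(seq_len(n), function(i) {
      cand <- B[[i]]
      if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }, integer(1))
    if (synchronous) {
      s <- s[pick]
    } else {
      for (i in sample.int(n)) s[i] <- s[pick[i]]
    }
  }
  list(outcome = "none", steps = max_steps, trajectory = traj)
}
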