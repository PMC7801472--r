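# Summary statistics of a population state and of a round of play:
# per-agent and aggregate correlated-interaction measures, ordered
# visitor-host coupling shares, per-strategy payoff summaries, and
# fixation detection.

#' Per-agent measure of correlated interaction
#'
#' For agent `i`, the share of its combined (outgoing + incoming) link
#' weight held with agents of its own strategy type, minus the share
#' expected under random interaction:
#' \deqn{a_i = \frac{\sum_{j \in Same_i} (w_{ij} + w_{ji})}
#'                  {\sum_k (w_{ik} + w_{ki})} - \frac{|Same_i|}{N}.}
#' The same-type set `Same_i` includes `i` itself in the cardinality (it
#' contributes zero weight since `w[i, i] = 0`); this is the convention
#' under which a lone spiteful agent has `a_i = -1/N` and a homogeneous
#' population has `a_i = 0` for everyone. Positive values mean `i`
#' interacts with its own type more than random mixing would predict;
#' negative values mean anti-correlated interaction.
#'
#' @param i agent index (1-based).
#' @param strategies strategy vector.
#' @param w weight matrix.
#' @return `a_i`, a number in `[-1, 1]`.
#' @examples
#' w <- init_weights(50)
#' s <- c(1L, rep(0L, 49))
#' agent_correlation(1, s, w)  # -1/50
#' @export
agent_correlation <- function(i, strategies, w) {
  s <- as_strategy(strategies)
  n <- length(s)
  stopifnot(nrow(w) == n, i >= 1, i <= n)
  m <- w[i, ] + w[, i]
  total <- sum(m)
  if (total <= 0) stop("agent ", i, " has zero combined link weight (degenerate state)")
  same <- s == s[i]
  sum(m[same]) / total - sum(same) / n
}

#' Aggregate and per-strategy correlation measures
#'
#' @param strategies strategy vector.
#' @param w weight matrix.
#' @return a list with elements `a_bar` (mean of `a_i` over all agents),
#'   `a_social` and `a_spiteful` (means over each strategy's agents,
#'   reported as 0 when that strategy is extinct, the plotting convention
#'   under which extinct types sit on the zero line until imitation error
#'   reintroduces them).
#' @export
correlation_summary <- function(strategies, w) {
  s <- as_strategy(strategies)
  a <- vapply(seq_along(s), agent_correlation, numeric(1),
              strategies = s, w = w)
  list(
    a_bar      = mean(a),
    a_social   = if (any(s == 0L)) mean(a[s == 0L]) else 0,
    a_spiteful = if (any(s == 1L)) mean(a[s == 1L]) else 0
  )
}

#' Ordered visitor-host coupling shares
#'
#' Classifies this round's `N` visits by (visitor strategy, host strategy)
#' and normalizes by the number of visits, giving the share of each of the
#' four possible ordered couplings.
#'
#' @param visits integer vector of hosts, `visits[i]` = agent visited by `i`.
#' @param strategies strategies the agents played this round.
#' @return named numeric vector
#'   `c(soc_soc, soc_spite, spite_soc, spite_spite)` summing to 1.
#' @export
coupling_shares <- function(visits, strategies) {
  s <- as_strategy(strategies)
  n <- length(s)
  stopifnot(length(visits) == n, n >= 1, all(visits >= 1), all(visits <= n))
  vs <- s[seq_len(n)]
  hs <- s[visits]
  c(soc_soc     = mean(vs == 0L & hs == 0L),
    soc_spite   = mean(vs == 0L & hs == 1L),
    spite_soc   = mean(vs == 1L & hs == 0L),
    spite_spite = mean(vs == 1L & hs == 1L))
}

#' Per-strategy payoff summaries
#'
#' Each agent's average payoff per interaction this round (total / count)
#' is summarized by strategy with both the mean and the median (the
#' imitation rule compares per-agent averages; the median is the more
#' robust display for skewed per-agent payoff distributions). Strategies
#' with no agents are reported as `NA`.
#'
#' @param payoff_total,n_interactions per-agent round totals and counts.
#' @param strategies strategies the agents played this round.
#' @return named numeric vector with elements `mean_payoff_social`,
#'   `median_payoff_social`, `mean_payoff_spiteful`,
#'   `median_payoff_spiteful`.
#' @export
payoff_summary <- function(payoff_total, n_interactions, strategies) {
  s <- as_strategy(strategies)
  stopifnot(length(payoff_total) == length(s),
            length(n_interactions) == length(s), all(n_interactions >= 1))
  avg <- payoff_total / n_interactions
  one <- function(k) {
    if (any(s == k)) c(mean(avg[s == k]), median(avg[s == k]))
    else c(NA_real_, NA_real_)
  }
  soc <- one(0L); spi <- one(1L)
  c(mean_payoff_social = soc[1], median_payoff_social = soc[2],
    mean_payoff_spiteful = spi[1], median_payoff_spiteful = spi[2])
}

#' Fixation state of a population
#'
#' @param strategies strategy vector.
#' @return `"social_fixated"`, `"spiteful_fixated"`, or `"none"`.
#' @export
fixation_state <- function(strategies) {
  s <- as_strategy(strategies)
  if (all(s == 0L)) "social_fixated"
  else if (all(s == 1L)) "spiteful_fixated"
  else "none"
}

#' Incoming weight received by each strategy type
#'
#' Sums of incoming link weight by host strategy, the quantity behind the
#' core-periphery pattern (social agents accumulate incoming weight,
#' spiteful agents shed it).
#'
#' @param strategies strategy vector.
#' @param w weight matrix.
#' @return named numeric vector `c(incoming_social, incoming_spiteful)`.
#' @export
incoming_weight_by_strategy <- function(strategies, w) {
  s <- as_strategy(strategies)
  inc <- colSums(w)
  c(incoming_social = sum(inc[s == 0L]),
    incoming_spiteful = sum(inc[s == 1L]))
}
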