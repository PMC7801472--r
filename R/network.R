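# The weighted directed interaction network: initialization, partner
# selection probabilities, sampling, and Roth-Erev reinforcement with
# discounting.
#
# The weight matrix w has w[i, j] = agent i's outgoing weight toward j,
# zero diagonal (self-visits are not allowed), all entries >= 0 with every
# row holding at least one strictly positive entry.

#' Initial uniform weight matrix
#'
#' All off-diagonal weights start at `L / (N - 1)`, representing random
#' initial interaction; `L` is the initial-weight constant that sets the
#' network learning speed relative to the payoff scale (larger `L` makes a
#' single payoff a smaller relative nudge). With the conventional `L = 9`,
#' weights start at exactly 1 for `N = 10`.
#'
#' @param n population size, at least 2.
#' @param L initial-weight constant, positive. Default 9.
#' @return an `n` x `n` numeric matrix with zero diagonal.
#' @examples
#' init_weights(10, 9)[1, 2]  # 1
#' @export
init_weights <- function(n, L = 9) {
  stopifnot(is.numeric(n), length(n) == 1L, n == as.integer(n))
  if (n < 2) stop("population size must be at least 2 (no possible partner)")
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  w <- matrix(L / (n - 1), n, n)
  diag(w) <- 0
  w
}

#' Check weight-matrix invariants
#'
#' @param w candidate weight matrix.
#' @return `w`, invisibly; errors if invariants are violated.
#' @export
validate_weights <- function(w) {
  stopifnot(is.matrix(w), is.numeric(w), nrow(w) == ncol(w), nrow(w) >= 2)
  if (any(diag(w) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(rowSums(w) <= 0))
    stop("every agent must have positive total outgoing weight")
  invisible(w)
}

#' Partner-selection probabilities for one agent
#'
#' With probability `1 - epsilon` agent `i` picks a host in proportion to
#' its outgoing weights; with probability `epsilon` it errs and picks
#' uniformly among the other `N - 1` agents. The error mass is spread over
#' partners only, so the self-visit probability is exactly zero and the
#' vector is a proper distribution.
#'
#' @param i agent index (1-based).
#' @param w weight matrix.
#' @param epsilon partner-choice error rate in `[0, 1]`.
#' @return numeric vector of length `N` summing to 1, with `p[i] = 0`.
#' @examples
#' w <- init_weights(5)
#' selection_probs(1, w, epsilon = 0)  # uniform 1/4 over partners
#' @export
selection_probs <- function(i, w, epsilon) {
  n <- nrow(w)
  stopifnot(i >= 1, i <= n, epsilon >= 0, epsilon <= 1)
  row <- w[i, ]
  s <- sum(row)
  if (s <= 0) stop("agent ", i, " has no positive outgoing weight (degenerate state)")
  p <- (1 - epsilon) * row / s + epsilon / (n - 1)
  p[i] <- 0
  p
}

# Shared inverse-CDF walk used by both the R reference engine and (in
# mirrored form) the compiled engine: index among the supplied weights of
# the first cumulative weight >= u * total. cumsum() accumulates in long
# double, matching the compiled path bit-for-bit. If the total is not
# positive — possible only once every relevant link has decayed to
# floating-point zero, the random-mixing limit of a payoff-free
# population — the draw falls back to a uniform index from the same
# uniform deviate.
.walk_index <- function(weights, u) {
  m <- length(weights)
  cum <- cumsum(weights)
  s <- cum[m]
  if (s > 0) which(cum >= u * s)[1L]
  else min(floor(u * m) + 1, m)
}

# One host draw for agent i, consuming runif(1) draws in the documented
# fixed order: u1 (error branch), then u2 (uniform index or weighted walk).
.choose_host <- function(i, w, epsilon) {
  n <- nrow(w)
  others <- seq_len(n)[-i]
  u1 <- runif(1)
  if (u1 < epsilon) {
    u2 <- runif(1)
    k <- min(floor(u2 * (n - 1)) + 1, n - 1)
    others[k]
  } else {
    u2 <- runif(1)
    others[.walk_index(w[i, others], u2)]
  }
}

#' Sample one host per agent
#'
#' Draws, for every agent, the partner it visits this round, following
#' [selection_probs()]. Uses the global R random number stream.
#'
#' @param w weight matrix.
#' @param epsilon partner-choice error rate in `[0, 1]`.
#' @return integer vector of hosts, `visits[i] != i` for all `i`.
#' @export
select_partners <- function(w, epsilon) {
  validate_weights(w)
  n <- nrow(w)
  vapply(seq_len(n), .choose_host, integer(1), w = w, epsilon = epsilon)
}

#' Roth-Erev reinforcement with discounting
#'
#' Updates all link weights simultaneously at the end of a round: every
#' off-diagonal weight is first multiplied by `1 - delta` (fading memory of
#' past payoffs), then each visitor's used link gains `R` times the payoff
#' it received in the interaction it initiated. Updating is asymmetric:
#' being visited never changes one's own outgoing weights.
#'
#' `discount_scope = "visited_only"` restricts the discount to the link each
#' agent actually used this round (update
#' `w'[i, j] = (1 - delta) w[i, j] + R * payoff` on the used link only),
#' retained as a sensitivity toggle; the default discounts every link,
#' which is what lets agents unlearn links to partners they no longer
#' visit.
#'
#' @param w weight matrix before the update.
#' @param visits integer vector, `visits[i]` = host visited by agent `i`.
#' @param visitor_payoffs numeric vector, `visitor_payoffs[i]` = payoff
#'   agent `i` received in the interaction it initiated. Must be
#'   non-negative (always true in this game).
#' @param delta discount factor in `[0, 1]`.
#' @param R network learning rate, `>= 0` (0 disables reinforcement).
#' @param discount_scope `"all"` (default) or `"visited_only"`.
#' @return the updated weight matrix.
#' @examples
#' w <- init_weights(10, 9)
#' w2 <- reinforce_weights(w, visits = c(2:10, 1), rep(10 / 11, 10),
#'                         delta = 0.01, R = 1)
#' w2[1, 2]  # 0.99 + 10/11
#' @export
reinforce_weights <- function(w, visits, visitor_payoffs, delta, R,
                              discount_scope = c("all", "visited_only")) {
  discount_scope <- match.arg(discount_scope)
  n <- nrow(w)
  stopifnot(length(visits) == n, length(visitor_payoffs) == n,
            all(visits >= 1), all(visits <= n), all(visits != seq_len(n)),
            delta >= 0, delta <= 1, R >= 0)
  if (any(visitor_payoffs < 0)) stop("negative payoff cannot be reinforced")
  used <- cbind(seq_len(n), visits)
  if (discount_scope == "all") {
    w <- w * (1 - delta)
    w[w < 1e-280] <- 0  # flush decayed weights before the denormal range
  } else {
    w[used] <- w[used] * (1 - delta)
    w[used][w[used] < 1e-280] <- 0
  }
  w[used] <- w[used] + R * visitor_payoffs
  w
}
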