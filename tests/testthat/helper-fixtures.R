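# Shared fixtures: all built in code, nothing on disk.

baseline_params <- function() payoff_params(10 / 11, 1 / 11)

# Random valid payoff pair with b > c (no warning).
random_params <- function() {
  b <- runif(1, 0.51, 0.95)
  payoff_params(b, 1 - b)
}

# Random small population state: strategies + strictly positive weights.
random_state <- function(n = 8) {
  w <- matrix(runif(n * n, 0.05, 2), n, n)
  diag(w) <- 0
  list(strategies = sample(0:1, n, replace = TRUE), w = w)
}

# Explicit single-invader link state with a prescribed number of extra
# host visitors: invader (agent 1) visits the host (agent 2); the host
# visits agent 3; agents 4..(3+z) also visit the host; every remaining
# social links to agent 3 (agent 3 itself links to agent 4). Unit weights,
# one out-link per agent.
invasion_weights <- function(n, z = 1) {
  stopifnot(n >= 3 + z, n >= 4)
  w <- matrix(0, n, n)
  w[1, 2] <- 1                                    # invader -> host
  w[2, 3] <- 1                                    # host -> other social
  w[3, 4] <- 1
  if (z > 0) w[seq_len(z) + 3, 2] <- 1            # z extra host visitors
  rest <- setdiff(4:n, seq_len(z) + 3)
  if (length(rest)) w[rest, 3] <- 1
  w
}

invasion_strategies <- function(n) c(1L, rep(0L, n - 1))
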