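test_that("best-response links always target social agents in mixed populations", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    s <- sample(c(rep(1L, sample(n - 1, 1)), 0L))
    s <- c(s, rep(0L, n - length(s)))[1:n]
    if (!any(s == 0L)) s[1] <- 0L
    links <- best_response_links(s)
    expect_true(all(s[links] == 0L))
    expect_true(all(links != seq_len(n)))
  }
  # N = 2 mixed: forced mutual links
  expect_identical(best_response_links(c(0L, 1L)), c(2L, 1L))
  # all-spiteful: every target ties, links uniform over others
  set.seed(31)
  hits <- replicate(2000, best_response_links(rep(1L, 4))[1])
  expect_gt(chisq.test(tabulate(hits, 4)[-1])$p.value, 1e-4)
})

test_that("analytic payoffs reproduce the invasion configuration values", {
  p <- baseline_params()
  n <- 6
  s <- invasion_strategies(n)
  set.seed(32)
  links <- best_response_links(s)
  U <- analytic_mean_payoffs(links, s, p)
  expect_equal(U[1], p$b)  # invader: visits one social, hosts nobody
  host <- links[1]
  z <- sum(links[-c(1, host)] == host)
  expect_equal(U[host], (p$c + 1 + z) / (z + 2))
  # all-social population: everyone averages 1
  set.seed(33)
  s0 <- rep(0L, 5)
  expect_equal(analytic_mean_payoffs(best_response_links(s0), s0, p),
               rep(1, 5))
})

test_that("imitation sets hold the weakly better performers including self", {
  p <- baseline_params()
  # chain 1 -> 2, 3 -> 2, 2 -> 3 with all-social strategies: equal payoffs,
  # so B_i is the whole interaction set plus self
  links <- c(2L, 3L, 2L)
  B <- imitation_sets(links, rep(0L, 3), p)
  expect_identical(B[[1]], c(1L, 2L))
  expect_identical(B[[2]], 1:3)
  # invader in its host's set when b exceeds the host payoff
  n <- 6
  s <- invasion_strategies(n)
  set.seed(34)
  links <- best_response_links(s)
  U <- analytic_mean_payoffs(links, s, p)
  B <- imitation_sets(links, s, p, U)
  host <- links[1]
  expect_true(1L %in% B[[host]])      # b >= (z+1+c)/(z+2) at these payoffs
  expect_identical(B[[1]], 1L)        # invader is strictly best locally
})

test_that("the single-invader condition is 3b - c > 2 with the right margin", {
  expect_true(single_invader_condition(baseline_params())$spreads)
  expect_equal(single_invader_condition(baseline_params())$margin, 7 / 11)
  weak <- payoff_params(2 / 3, 1 / 3)
  expect_false(single_invader_condition(weak)$spreads)
  expect_equal(single_invader_condition(weak)$margin, -1 / 3)
  # exact boundary is not spreading (strict inequality)
  expect_false(single_invader_condition(payoff_params(0.75, 0.25))$spreads)
})

test_that("the general invasion condition reduces to the single-invader case", {
  set.seed(35)
  for (rep in 1:10) {
    p <- random_params()
    g <- general_invasion_condition(x = sample(2:40, 1), y = 1, p)
    expect_equal(g$expected_host_payoff, (p$c + 2) / 3, tolerance = 1e-12)
    expect_identical(g$spreads, single_invader_condition(p)$spreads)
  }
  expect_equal(general_invasion_condition(5, 1, payoff_params(2 / 3, 1 / 3)
               )$expected_host_payoff, 7 / 9)
  expect_true(general_invasion_condition(10, 10, baseline_params())$spreads)
  # once spreading, more spiteful agents never turn the condition off
  p <- baseline_params()
  lhs <- vapply(1:20, function(y) general_invasion_condition(20, y, p)$lhs,
                numeric(1))
  expect_true(all(diff(lhs) >= 0))
  expect_true(all(lhs > 2))
})

test_that("expected extra visitors of the invaded host equal 1 exactly", {
  for (n in c(3, 10, 50))
    expect_equal(expected_extra_visitors(n)$value, 1, tolerance = 1e-12)
  set.seed(36)
  mc <- expected_extra_visitors(50, "mc", draws = 2e4)
  expect_lt(abs(mc$value - 1), 3 * mc$se)
})

test_that("the invasion threshold constant computed from the model is 2", {
  out <- invasion_threshold_constant(N = 50)
  expect_equal(out$constant, 2, tolerance = 1e-12)
  expect_lt(out$spread, 1e-12)
  expect_equal(out$zbar, 1, tolerance = 1e-12)
})

test_that("aggregate correlation at invasion follows the closed form", {
  expect_equal(abar_at_invasion(4), 1 / 24)
  expect_equal(abar_at_invasion(3), 0)
  expect_equal(abar_at_invasion(50), (1 / 50) * (2 / 3 - 2 / 50))
  Ns <- 4:100
  expect_true(all(abar_at_invasion(Ns) > 0))
  expect_identical(smallest_positive_abar_N(10), 4L)
})

test_that("Monte-Carlo correlation at invasion matches the exact expectation", {
  # exact oracle: a_bar = (1/N)(E[(1+z)/(2+z)] - 2/N) with
  # z ~ Binomial(N-2, 1/(N-2)); the closed form substitutes E[z] = 1 into
  # the host share, so it sits within ~0.04/N of the exact value
  exact_abar <- function(n) {
    z <- 0:(n - 2)
    g <- sum((1 + z) / (2 + z) * dbinom(z, n - 2, 1 / (n - 2)))
    (1 / n) * (g - 2 / n)
  }
  set.seed(37)
  for (n in c(3, 4, 10, 50)) {
    vals <- mc_abar_at_invasion(n, replicates = 400)
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - exact_abar(n)), max(3 * se, 1e-12))
    expect_lt(abs(abar_at_invasion(n) - exact_abar(n)), 0.04 / n + 1e-12)
  }
})

test_that("the mean-field gap is r*b - c and crosses zero at c/b", {
  p <- payoff_params(2 / 3, 1 / 3)
  expect_equal(meanfield_fitness_gap(p$c / p$b, p), 0, tolerance = 1e-12)
  expect_equal(meanfield_fitness_gap(0, p), -p$c)
  r <- seq(0, 1, by = 0.05)
  gaps <- meanfield_fitness_gap(r, p, freq_social = 0.3)
  expect_true(all(diff(gaps) > 0))
  expect_equal(meanfield_threshold(p), 0.5, tolerance = 1e-9)
  # frequency independence
  expect_equal(meanfield_fitness_gap(0.4, p, freq_social = 0.1),
               meanfield_fitness_gap(0.4, p, freq_social = 0.9))
})

test_that("the simplified-model oracle reproduces the invasion threshold", {
  set.seed(38)
  strong <- replicate(150, simulate_simplified(
    c(1L, rep(0L, 19)), baseline_params(), max_steps = 200)$outcome)
  expect_gt(mean(strong == "spiteful_fixated"), 0.5)
  set.seed(39)
  weak <- replicate(150, simulate_simplified(
    c(1L, rep(0L, 19)), payoff_params(2 / 3, 1 / 3), max_steps = 200)$outcome)
  expect_gt(mean(weak == "social_fixated"), 0.8)
  # homogeneous start: immediate fixation, no dynamics
  out <- simulate_simplified(rep(0L, 6), baseline_params())
  expect_identical(out$outcome, "social_fixated")
  expect_identical(out$steps, 0L)
  # asynchronous variant also runs to fixation
  set.seed(40)
  out2 <- simulate_simplified(c(1L, rep(0L, 9)), baseline_params(),
                              max_steps = 200, synchronous = FALSE)
  expect_true(out2$outcome %in% c("social_fixated", "spiteful_fixated"))
})
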