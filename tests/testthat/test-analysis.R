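# Helpers building synthetic two-step records with known choice rules.
make_records <- function(n, choice_rule, p_common = 0.7, seed = 1) {
  set.seed(seed)
  choice <- integer(n); common <- logical(n); reward <- integer(n)
  choice[1] <- 1
  common[1] <- runif(1) < p_common
  reward[1] <- rbinom(1, 1, 0.5)
  for (t in 2:n) {
    choice[t] <- choice_rule(choice[t - 1], reward[t - 1], common[t - 1])
    common[t] <- runif(1) < p_common
    reward[t] <- rbinom(1, 1, 0.5)
  }
  data.frame(agent = 1, trial = 1:n, choice1 = choice, common = common,
             reward = reward)
}

test_that("stay probabilities match a direct recount of the records", {
  rep_rule <- function(prev, r, cm) prev
  rec <- make_records(200, rep_rule)
  st <- stay_probabilities(rec)
  expect_true(all(st$prob == 1, na.rm = TRUE))       # always repeats
  alt_rule <- function(prev, r, cm) 3L - prev
  st2 <- stay_probabilities(make_records(200, alt_rule))
  expect_true(all(st2$prob == 0, na.rm = TRUE))      # always alternates
  # random chooser: all cells near 0.5, and the table equals a manual recount
  rnd_rule <- function(prev, r, cm) sample(1:2, 1)
  rec3 <- make_records(4000, rnd_rule, seed = 2)
  st3 <- stay_probabilities(rec3)
  expect_true(all(abs(st3$prob - 0.5) < 0.05))
  manual <- matrix(NA_real_, 2, 2)
  stay <- rec3$choice1[-1] == rec3$choice1[-4000]
  rw <- rec3$reward[-4000]; cm <- rec3$common[-4000]
  manual[1, 1] <- mean(stay[rw == 1 & cm]);  manual[1, 2] <- mean(stay[rw == 1 & !cm])
  manual[2, 1] <- mean(stay[rw == 0 & cm]);  manual[2, 2] <- mean(stay[rw == 0 & !cm])
  expect_equal(unname(st3$prob), manual)
  expect_equal(sum(st3$n), 3999)
})

test_that("the model-based index separates constructed choosers", {
  # transition-aware rule: repeat after rewarded-common or unrewarded-rare
  mb_rule <- function(prev, r, cm) {
    stay <- if ((r == 1) == cm) 0.85 else 0.15
    if (runif(1) < stay) prev else 3L - prev
  }
  mb <- mb_index(make_records(600, mb_rule, seed = 3))
  expect_gt(mb$mb_index, 0.5)
  # reward-only rule: a main effect of reward, no interaction
  mf_rule <- function(prev, r, cm) {
    stay <- if (r == 1) 0.8 else 0.3
    if (runif(1) < stay) prev else 3L - prev
  }
  mf <- mb_index(make_records(600, mf_rule, seed = 4))
  expect_gt(mf$reward_effect, 0.3)
  expect_lt(abs(mf$mb_index), 0.25)
  # a constant chooser carries no information: the ridge pins the index at 0
  const <- mb_index(make_records(200, function(p, r, cm) 1L, seed = 5))
  expect_lt(abs(const$mb_index), 0.1)
  # too few trials: excluded
  short <- mb_index(make_records(10, mf_rule, seed = 6))
  expect_true(is.na(short$mb_index))
})

test_that("strategy classification reads the probe endpoint", {
  rec <- structure(list(states = c(17, 16, 9, 13)), class = "trial_record")
  expect_equal(classify_strategy(rec, place_state = 13, response_state = 5), "place")
  rec$states <- c(17, 16, 9, 5)
  expect_equal(classify_strategy(rec, 13, 5), "response")
  rec$states <- c(17, 16, 9, 9)
  expect_equal(classify_strategy(rec, 13, 5), "unclassified")
})

test_that("place-memory score averages argmax distances", {
  expect_equal(place_memory_score(c(0, 0, 0)), 0)
  expect_equal(place_memory_score(c(NA, 2, 4)), 3)
})

test_that("correlation statistics match their closed forms and a permutation oracle", {
  expect_equal(compare_correlations(0.4, 30, 0.4, 12)$z, 0)
  expect_equal(correlation_z(0.5, 20)$z, atanh(0.5) * sqrt(17))
  # p decreases monotonically in |z|
  rs <- seq(0.05, 0.9, by = 0.05)
  ps <- sapply(rs, function(r) correlation_z(r, 20)$p)
  expect_true(all(diff(ps) < 0))
  expect_error(correlation_z(1, 20), "r")
  expect_error(compare_correlations(0.2, 3, 0.1, 20), "n >= 4")

  # permutation oracle for the two-arm comparison: shuffle arm labels and
  # recompute the difference statistic
  set.seed(15)
  n <- 20
  x1 <- rnorm(n); y1 <- 0.8 * x1 + 0.6 * rnorm(n)   # correlated arm
  x2 <- rnorm(n); y2 <- rnorm(n)                    # null arm
  obs <- compare_correlations(cor(x1, y1), n, cor(x2, y2), n)
  xs <- c(x1, x2); ys <- c(y1, y2)
  perm <- replicate(600, {
    idx <- sample(2 * n)
    a <- idx[1:n]; b <- idx[(n + 1):(2 * n)]
    atanh(cor(xs[a], ys[a])) - atanh(cor(xs[b], ys[b]))
  })
  p_perm <- mean(abs(perm) >= abs(atanh(cor(x1, y1)) - atanh(cor(x2, y2))))
  # both methods should call this difference significant
  expect_lt(obs$p, 0.05)
  expect_lt(p_perm, 0.05)
})

test_that("strategy proportions sum to one over classified probes", {
  probes <- data.frame(
    agent = rep(1:6, 2), probe = rep(1:2, each = 6),
    trained = 28, arm = "control", deval = FALSE,
    strategy = c("place", "place", "response", "unclassified", "place", "response",
                 "response", "response", "place", "response", "unclassified", "response"),
    stringsAsFactors = FALSE)
  pr <- strategy_proportions(probes)
  expect_equal(pr$p_place + pr$p_response, rep(1, nrow(pr)))
  expect_equal(pr$p_place[pr$probe == 1], 3 / 5)
  expect_equal(pr$p_place[pr$probe == 2], 1 / 5)
})

test_that("heterogeneous agent sampling stays inside the declared ranges", {
  set.seed(16)
  ranges <- list(A_alpha = c(0.02, 3), B_alpha = c(1, 16),
                 B_beta = c(0.25, 3), beta_softmax = c(6, 10))
  for (k in 1:25) {
    cfg <- sample_agent_config(ranges)
    for (nm in names(ranges)) {
      expect_gte(cfg[[nm]], ranges[[nm]][1])
      expect_lte(cfg[[nm]], ranges[[nm]][2])
    }
  }
})
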