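test_that("random-walk SR matches the matrix-inversion closed form", {
  T2 <- matrix(c(0, 1, 1, 0), 2, 2)           # 2-state symmetric chain
  expect_equal(random_walk_sr(T2, 0.5),
               matrix(c(4 / 3, 2 / 3, 2 / 3, 4 / 3), 2, 2))
  T3 <- matrix(runif(9), 3, 3); T3 <- T3 / rowSums(T3)
  expect_equal(random_walk_sr(T3, 0), diag(3))
  M <- random_walk_sr(T3, 0.9)
  expect_equal(unname(rowSums(M)), rep(1 / (1 - 0.9), 3))
  expect_identical(identity_sr(4), diag(4))
})

test_that("SR TD update applies the successor prediction error", {
  M <- identity_sr(3)
  up <- sr_td_update(M, s = 1, s_next = 2, terminal = FALSE,
                     alpha_m = 0.1, gamma = 0.9)
  expect_equal(up$M[1, 1], 1)          # delta at own state is 0 (1 + 0 - 1)
  expect_equal(up$M[1, 2], 0.09)       # gamma * M(s', s') * alpha
  expect_equal(up$M[2, ], M[2, ])      # other rows untouched (non-terminal)
  # at the true SR of a deterministic cycle the error vanishes
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  Mstar <- solve(diag(3) - 0.9 * P)
  up2 <- sr_td_update(Mstar, 1, 2, FALSE, 0.1, 0.9)
  expect_equal(max(abs(up2$delta)), 0, tolerance = 1e-12)
})

test_that("TD learning of the SR converges to the closed form on a cycle", {
  gamma <- 0.9; alpha <- 0.1
  P <- matrix(0, 5, 5)
  for (s in 1:5) P[s, s %% 5 + 1] <- 1
  Mstar <- solve(diag(5) - gamma * P)
  M <- identity_sr(5)
  s <- 1
  for (k in 1:6000) {
    s2 <- s %% 5 + 1
    M <- sr_td_update(M, s, s2, FALSE, alpha, gamma)$M
    s <- s2
  }
  expect_lt(norm(M - Mstar, "F"), 1e-2)
  # row sums never exceed the discounted-occupancy bound
  expect_true(all(rowSums(M) <= 1 / (1 - gamma) + 1e-6))
})

test_that("terminal transitions preserve and correct goal occupancy", {
  M <- random_walk_sr(matrix(c(0, 1, 1, 0), 2, 2), 0.9)
  up <- sr_td_update(M, 1, 2, TRUE, 0.5, 0.9)
  # row 1 moves toward 1(s1) + gamma * one-hot(s2)
  expect_equal(up$M[1, ], M[1, ] + 0.5 * (c(1, 0.9) - M[1, ]))
  # the absorbing state's own row relaxes toward its one-hot
  expect_equal(up$M[2, ], M[2, ] + 0.5 * (c(0, 1) - M[2, ]))
})

test_that("reward vector learns by a delta rule", {
  R <- c(0, 0, 0)
  expect_equal(reward_update(R, 2, 1, 0.1)[2], 0.1)
  R2 <- c(0.3, 0.7, 0)
  expect_identical(reward_update(R2, 2, 0.7, 0.5), R2)  # zero error
  # visiting without reward unlearns
  R3 <- reward_update(c(0, 1, 0), 2, 0, 0.4)
  expect_equal(R3[2], 0.6)
})

test_that("value factorizes as V = M R and revalues instantly", {
  R <- c(0, 0, 1)
  expect_equal(v_hpc(diag(3), R), R)
  set.seed(6)
  M <- matrix(runif(9), 3, 3); Rr <- runif(3)
  oracle <- sapply(1:3, function(s) sum(M[s, ] * Rr))
  expect_equal(v_hpc(M, Rr), oracle)
  # editing R alone changes V at predecessors while M is untouched
  M0 <- M
  V1 <- v_hpc(M, R); R[3] <- 0.2; V2 <- v_hpc(M, R)
  expect_false(isTRUE(all.equal(V1, V2)))
  expect_identical(M, M0)
  expect_error(v_hpc(M, c(1, 2)), "mismatch")
})

test_that("one-step lookahead values match exhaustive expectation", {
  expect_equal(q_hpc(0.3, c(0, 0), 0.9), c(0.3, 0.3))  # V == 0
  expect_equal(q_hpc(0, 2, 0.9), 1.8)                  # deterministic model
  set.seed(7)
  g <- build_task_graph("daw_two_step")
  V <- runif(7)
  for (a in 1:2) {
    q <- q_hpc(0, sum(g$P[1, a, ] * V), 0.95)
    oracle <- 0 + 0.95 * sum(sapply(1:7, function(sp) g$P[1, a, sp] * V[sp]))
    expect_equal(q, oracle)
  }
})

test_that("successor features reduce exactly to the tabular SR under one-hot", {
  set.seed(8)
  n <- 4; gamma <- 0.9; alpha <- 0.3
  M <- identity_sr(n)
  W <- identity_sr(n)
  for (k in 1:50) {
    s <- sample(n, 1); s2 <- sample(n, 1)
    term <- runif(1) < 0.2
    tab <- sr_td_update(M, s, s2, term, alpha, gamma)
    sf <- sf_td_update(W, one_hot(s - 1, n), one_hot(s2 - 1, n), term, alpha, gamma)
    M <- tab$M; W <- sf$W
    expect_equal(W, M, tolerance = 1e-12)
    expect_equal(sf$delta, tab$delta, tolerance = 1e-12)
  }
})

test_that("successor-feature estimates and updates behave at the edges", {
  W <- diag(3)
  expect_equal(sf_estimate(W, c(1, 2, 3)), c(1, 2, 3))
  expect_equal(sf_estimate(matrix(0, 3, 3), c(0, 0, 0)), c(0, 0, 0))
  set.seed(9)
  W <- matrix(rnorm(9), 3, 3); f <- runif(3)
  expect_equal(sf_estimate(W, f), as.numeric(t(W) %*% f))
  up <- sf_td_update(W, c(0, 0, 0), runif(3), FALSE, 0.1, 0.9)
  expect_equal(up$W, W)                                # f_t = 0: no update
  expect_error(sf_estimate(W, runif(4)), "mismatch")
})

test_that("feature-reward weights reduce to the delta rule under one-hot", {
  u <- c(0.2, 0.5, 0)
  expect_identical(feature_reward_update(c(0, 0, 0), c(0, 0, 0), 0, 0.3),
                   c(0, 0, 0))
  u2 <- feature_reward_update(u, one_hot(1, 3), 1, 0.3)
  expect_equal(u2, reward_update(u, 2, 1, 0.3))
  expect_equal(v_sf(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_equal(v_sf(c(1, 2, 0), c(0.5, 0.25, 9)), 1)
})

test_that("devaluation scales the reward representation only", {
  R <- c(0, 0.8, 0.1)
  expect_identical(devalue(R, 1), R)
  expect_equal(v_hpc(diag(3), devalue(R, 0)), c(0, 0, 0))
  expect_error(devalue(R, 1.5), "factor")
})

test_that("compound place-cell training survives removal of the first cue", {
  # three cells: cell 1 is driven by the first boundary and fires at the
  # goal; cell 2 is driven by the second boundary (compound phase) and
  # overlaps the goal; cell 3 is an approach cell. During compound training
  # cell 2 comes to predict cell 1 through the SF weights while the reward
  # weights stay on cell 1 (no reward-prediction error), so value at the
  # goal survives silencing of the first boundary.
  gamma <- 0.95; alpha <- 0.3
  W <- diag(3); u <- numeric(3)
  approach1 <- c(0, 0, 1); goal1 <- c(1, 0, 0)   # phase 1: boundary 1 only
  for (k in 1:100) {
    W <- sf_td_update(W, approach1, goal1, TRUE, alpha, gamma)$W
    u <- feature_reward_update(u, goal1, 1, 0.3)
  }
  expect_gt(u[1], 0.9)
  approach2 <- c(0, 0.8, 0.1); goal2 <- c(1, 1, 0)  # phase 2: compound
  u_before <- u
  for (k in 1:100) {
    W <- sf_td_update(W, approach2, goal2, TRUE, alpha, gamma)$W
    u <- feature_reward_update(u, goal2, 1, 0.3)
  }
  # reward weights essentially unchanged: value was already predicted
  expect_lt(abs(u[2]), 0.15)
  expect_equal(u[1], u_before[1], tolerance = 0.1)
  # the new cell now predicts the reward-associated cell
  expect_gt(W[2, 1], 0.2)
  # phase 3: first boundary removed; value where cell 2 fires survives
  v3 <- v_sf(sf_estimate(W, c(0, 1, 0)), u)
  expect_gt(v3, 0.25)
})
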