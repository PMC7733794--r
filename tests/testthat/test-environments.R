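test_that("linear track arena matches its task description", {
  tr <- build_arena("linear_track", n = 5)
  expect_s3_class(tr, "arena")
  expect_equal(tr$n_states, 5)
  expect_equal(tr$goal$reward_prob, 0.8)
  expect_equal(nrow(tr$landmarks), 5)
  expect_false(anyDuplicated(tr$landmarks$id) > 0)
  expect_error(build_arena("linear_track", n = 1), "degenerate")
})

test_that("stepping into a wall is a clipped no-op with no reward", {
  tr <- build_arena("linear_track", n = 5)
  out <- arena_step(tr, state = 1, action = 5)  # west, off the track
  expect_equal(out$next_state, 1)
  expect_equal(out$reward, 0)
  expect_false(out$terminal)
  expect_error(arena_step(tr, state = 99, action = 1), "outside")
})

test_that("goal entry draws a Bernoulli reward at the configured rate", {
  tr <- build_arena("linear_track", n = 5, reward_prob = 0.8)
  set.seed(1)
  draws <- replicate(10000, arena_step(tr, state = 4, action = 1)$reward)
  expect_true(all(replicate(20, arena_step(tr, state = 4, action = 1)$terminal)))
  expect_equal(mean(draws), 0.8, tolerance = 0.02)
})

test_that("water-maze sessions move platform and landmark jointly", {
  wm <- build_arena("water_maze", grid_n = 20, n_sessions = 11)
  offs <- sapply(1:11, function(i) {
    a <- configure_session(wm, i)
    c(a$landmarks$x - a$goal$center[1], a$landmarks$y - a$goal$center[2])
  })
  # landmark-minus-platform offset identical across sessions
  expect_true(all(apply(offs, 1, function(v) max(abs(v - v[1]))) < 1e-12))
  # idempotence
  a1 <- configure_session(wm, 1)
  expect_identical(configure_session(a1, 1), a1)
  # 11 distinct platform centers
  centers <- t(sapply(1:11, function(i) configure_session(wm, i)$goal$center))
  expect_equal(nrow(unique(round(centers, 6))), 11)
  expect_error(configure_session(wm, 12), "exceeds")
})

test_that("plus maze arms block, start and terminate as configured", {
  pm <- build_arena("plus_maze", arm_len = 4)
  c0 <- pm$arm_len + 1
  ctr <- pm$state_grid[c0, c0]
  # N arm blocked during training: move north from center is a no-op
  expect_equal(pm$adj[ctr, 3], ctr)
  # probe configuration: start at N end, S blocked, E/W ends terminal
  probe <- plus_configure(pm, start_arm = "N", blocked_arm = "S",
                          goal_arm = NULL, terminal_arms = c("E", "W"))
  expect_equal(probe$start_poses[[1]]$state, pm$arm_ends[["N"]])
  expect_equal(probe$adj[ctr, 7], ctr)  # south blocked
  expect_setequal(probe$terminal_states, unname(pm$arm_ends[c("E", "W")]))
  expect_null(probe$goal)
  expect_equal(probe$n_states, pm$n_states)  # state space unchanged
})

test_that("random-walk transition matrix is row stochastic", {
  for (kind in c("linear_track", "plus_maze", "open_field")) {
    arena <- build_arena(kind, grid_n = 8)
    T <- rw_transition_matrix(arena)
    expect_true(max(abs(rowSums(T) - 1)) < 1e-12)
  }
})

test_that("spatial steps never leave the arena", {
  pm <- build_arena("plus_maze", arm_len = 3)
  set.seed(2)
  s <- pm$start_poses[[1]]$state
  for (k in 1:500) {
    out <- arena_step(pm, s, sample(8, 1))
    expect_true(out$next_state >= 1 && out$next_state <= pm$n_states)
    s <- out$next_state
  }
})

test_that("two-step graph has common > rare transitions and bounded rewards", {
  set.seed(3)
  g <- build_task_graph("daw_two_step")
  for (a in 1:2) {
    p <- g$P[1, a, ]
    expect_gt(p[g$common_next[a]], p[setdiff(2:3, g$common_next[a])])
  }
  expect_true(all(g$reward_probs >= 0.25 & g$reward_probs <= 0.75))
  expect_true(all(abs(apply(g$P[1:3, , ], c(1, 2), sum) - 1) < 1e-12))
  gd <- build_task_graph("deterministic_two_step")
  expect_true(all(apply(gd$P[1:3, , ], c(1, 2), max) == 1))
  expect_error(graph_step(g, 4, 1), "invalid state")
  expect_error(graph_step(g, 1, 3), "invalid action")
})

test_that("reward-probability random walk stays inside its bounds", {
  set.seed(4)
  g <- build_task_graph("daw_two_step", drift_sd = 0.1)
  for (k in 1:10000) {
    g <- advance_reward_probs(g)
    if (any(g$reward_probs < 0.25 | g$reward_probs > 0.75)) {
      fail("reward probability left its bounds")
    }
  }
  succeed()
  g0 <- build_task_graph("daw_two_step", drift_sd = 0)
  p0 <- g0$reward_probs
  for (k in 1:50) g0 <- advance_reward_probs(g0)
  expect_identical(g0$reward_probs, p0)
})
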