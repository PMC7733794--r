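test_that("landmark-cell tuning peaks at the preferred distance and angle", {
  peak <- lc_activation(2, 0.3, d_star = 2, theta_star = 0.3)
  expect_equal(peak, 1)
  # one radial sigma away drops by exp(-1/2)
  expect_equal(lc_activation(2 + 1, 0.3, d_star = 2, theta_star = 0.3, sigma_d = 1),
               exp(-0.5))
  # grid search confirms the peak location
  dd <- seq(0.1, 6, by = 0.1)
  th <- seq(-pi, pi, by = 0.05)
  rates <- outer(dd, th, function(d, t) lc_activation(d, t, 2, 0.3))
  pk <- arrayInd(which.max(rates), dim(rates))
  expect_equal(dd[pk[1]], 2, tolerance = 0.06)
  expect_equal(th[pk[2]], 0.3, tolerance = 0.03)
  expect_error(lc_activation(1, 0, 1, 0, sigma_d = -1), "positive")
})

test_that("landmark cells ignore absent identities and on-agent landmarks", {
  bank <- lc_bank(c("A", "B"), distances = c(1, 2))
  lmA <- data.frame(x = 1, y = 0, id = "A", stringsAsFactors = FALSE)
  f <- lc_population(0, 0, 0, lmA, bank)
  expect_true(all(f[bank$id == "B"] == 0))
  expect_true(any(f[bank$id == "A"] > 0))
  # a landmark at the agent's own position has no bearing and drives nothing
  lm0 <- data.frame(x = 0, y = 0, id = "A", stringsAsFactors = FALSE)
  expect_true(all(lc_population(0, 0, 0, lm0, bank) == 0))
  expect_true(all(lc_population(0, 0, 0, NULL, bank) == 0))
})

test_that("landmark-cell coding is egocentric", {
  bank <- lc_bank("cue", distances = c(1, 2, 3), sigma_d = 0.8)
  lm <- data.frame(x = 2, y = 1, id = "cue", stringsAsFactors = FALSE)
  f0 <- lc_population(0, 0, 0.4, lm, bank)
  # translating and rotating agent and landmark jointly leaves the code intact
  rot <- 1.1; shift <- c(-3, 2)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  lm2 <- lm
  p <- R %*% c(lm$x, lm$y) + shift
  lm2$x <- p[1]; lm2$y <- p[2]
  a2 <- R %*% c(0, 0) + shift
  f1 <- lc_population(a2[1], a2[2], 0.4 + rot, lm2, bank)
  expect_equal(f1, f0, tolerance = 1e-10)
  # rotating the agent in place permutes which angle-tuned cells respond
  f_rot <- lc_population(0, 0, 0.4 + pi / 4, lm, bank)
  expect_false(isTRUE(all.equal(f_rot, f0)))
  expect_equal(sort(round(f_rot, 8)), sort(round(f0, 8)))  # same rates, relabeled
  # a landmark dead ahead at a preferred distance maximally drives that cell
  lm_ahead <- data.frame(x = 2, y = 0, id = "cue", stringsAsFactors = FALSE)
  f <- lc_population(0, 0, 0, lm_ahead, bank)
  expect_equal(bank$d_star[which.max(f)], 2)
  expect_equal(bank$theta_star[which.max(f)], 0)
  # determinism
  expect_identical(f, lc_population(0, 0, 0, lm_ahead, bank))
})

test_that("boundary-vector cells integrate subtended angle additively", {
  w1 <- rbind(c(-2, 3, 2, 3))      # wall 4 long at distance 3 to the north
  w2 <- rbind(c(5, -1, 5, 1))      # short wall to the east
  r1 <- bvc_activation(0, 0, w1, d_star = 3, phi_star = pi / 2)
  r2 <- bvc_activation(0, 0, w2, d_star = 3, phi_star = pi / 2)
  r12 <- bvc_activation(0, 0, rbind(w1, w2), d_star = 3, phi_star = pi / 2)
  expect_equal(r12, r1 + r2, tolerance = 1e-10)
  expect_equal(bvc_activation(0, 0, NULL, 3, 0), 0)
  # a longer section at the preferred distance subtends a larger angle
  short_w <- rbind(c(-0.5, 3, 0.5, 3))
  expect_gt(r1, bvc_activation(0, 0, short_w, d_star = 3, phi_star = pi / 2))
})

test_that("place cells form localized fields in a square box", {
  hw <- 5.5  # 11 x 11 box walls
  box_walls <- rbind(c(-hw, -hw, hw, -hw), c(hw, -hw, hw, hw),
                     c(hw, hw, -hw, hw), c(-hw, hw, -hw, -hw))
  box <- build_arena("open_field", grid_n = 11, walls = box_walls)
  bank <- place_cell_bank(matrix(c(2, 2), 1, 2), box$boundaries, n_walls = 2)
  map <- place_field_maps(box, bank)
  expect_true(all(map >= 0))
  pk <- which.max(map[, 1])
  expect_lt(sqrt(sum((box$coords[pk, ] - c(2, 2))^2)), 1.6)
  # above-threshold support is spatially restricted (a field, not a stripe)
  expect_lt(mean(map[, 1] > 0), 0.5)
  # threshold above the total drive silences the cell everywhere
  bank_hi <- place_cell_bank(matrix(c(2, 2), 1, 2), box$boundaries,
                             n_walls = 2, threshold_frac = 50)
  expect_true(all(place_field_maps(box, bank_hi) == 0))
})

test_that("removing a reference wall weakens the cells it drives", {
  walls <- rbind(c(-5, -2, -5, 2), c(-2, -5, 2, -5))
  bank <- place_cell_bank(matrix(c(-2, -2), 1, 2), walls, per_wall = TRUE)
  expect_length(bank, 2)
  full <- place_cell_rates(-2, -2, walls, bank, wall_ids = 1:2)
  only2 <- place_cell_rates(-2, -2, walls[2, , drop = FALSE], bank, wall_ids = 2L)
  expect_equal(only2[1], 0)          # the wall-1 cell falls silent
  expect_equal(only2[2], full[2])    # the wall-2 cell is untouched
})

test_that("one-hot encoding is a unit basis", {
  expect_equal(one_hot(2, 5), c(0, 0, 1, 0, 0))
  expect_equal(sum(one_hot(0, 7)), 1)
  expect_equal(sum(one_hot(1, 4) * one_hot(2, 4)), 0)
  expect_error(one_hot(5, 5), "range")
})
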