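# Arenas and task graphs: the environment side of every simulated protocol.
#
# Spatial arenas are uniform square-grid discretizations of a continuous,
# allocentric (x, y) plane with the origin at the arena center; one grid cell
# is the unit of length. The action set is the 8 compass directions. Movement
# into a wall or off the traversable set is clipped (a no-op move).

#' Construct a spatial arena
#'
#' Builds one of four arena kinds used by the simulated protocols:
#' \describe{
#'   \item{`linear_track`}{`n` states in a row; a unique landmark identifies
#'     each state; the terminal state rewards with probability
#'     `reward_prob` (default 0.8).}
#'   \item{`water_maze`}{A `grid_n` x `grid_n` pool with four bounding walls.
#'     A hidden platform (goal circle) and a single intramaze landmark at a
#'     fixed offset from it are placed per session; use
#'     [configure_session()] to move both jointly across sessions.}
#'   \item{`plus_maze`}{Four arms around a central cell. One arm is blocked
#'     during training; a start arm and a baited goal arm are configured.
#'     Use [plus_configure()] to rearrange arms for probe trials.}
#'   \item{`open_field`}{A `grid_n` x `grid_n` field with caller-supplied wall
#'     segments, landmarks and goal; used by the blocking protocols.}
#' }
#'
#' @param kind one of `"linear_track"`, `"water_maze"`, `"plus_maze"`,
#'   `"open_field"`.
#' @param n number of states of the linear track.
#' @param reward_prob goal reward probability.
#' @param grid_n side length (in cells) of the water maze / open field.
#' @param platform_radius radius of the goal circle (cells).
#' @param landmark_offset allocentric (dx, dy) from platform center to the
#'   landmark; held constant across sessions.
#' @param n_sessions number of configured platform/landmark locations.
#' @param session_centers optional `n_sessions` x 2 matrix of platform centers;
#'   a default well-spread set is generated when `NULL`.
#' @param arm_len plus-maze arm length (cells).
#' @param goal_arm,start_arm,blocked_arm plus-maze arm labels among
#'   `"N"`, `"E"`, `"S"`, `"W"`.
#' @param walls open-field wall segments: a matrix with columns
#'   `x1, y1, x2, y2` (or `NULL`).
#' @param landmarks open-field landmarks: `data.frame(x, y, id)` (or `NULL`).
#' @param goal open-field goal: `list(center = c(x, y), radius, reward_prob)`.
#'
#' @return An object of class `"arena"`: a list with the discretized state
#'   space (`coords`, `adj`, `n_states`), `boundaries`, `landmarks`, `goal`,
#'   `start_poses` and kind-specific configuration.
#' @export
#' @examples
#' tr <- build_arena("linear_track", n = 5)
#' tr$n_states
build_arena <- function(kind = c("linear_track", "water_maze", "plus_maze", "open_field"),
                        n = 5, reward_prob = 0.8,
                        grid_n = 20, platform_radius = 1.2,
                        landmark_offset = c(0, 3), n_sessions = 11,
                        session_centers = NULL,
                        arm_len = 4, goal_arm = "E", start_arm = "S", blocked_arm = "N",
                        walls = NULL, landmarks = NULL, goal = NULL) {
  kind <- match.arg(kind)
  arena <- switch(kind,
    linear_track = .build_linear_track(n, reward_prob),
    water_maze = .build_water_maze(grid_n, platform_radius, landmark_offset,
                                   n_sessions, session_centers, reward_prob = 1),
    plus_maze = .build_plus_maze(arm_len, goal_arm, start_arm, blocked_arm),
    open_field = .build_open_field(grid_n, walls, landmarks, goal)
  )
  .validate_arena(arena)
  arena
}

# -- grid machinery -----------------------------------------------------------

.grid_coords <- function(nx, ny, mask) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  keep <- mask[cbind(ix, iy)]
  ix <- ix[keep]; iy <- iy[keep]
  coords <- cbind(x = ix - (nx + 1) / 2, y = iy - (ny + 1) / 2)
  state_grid <- matrix(NA_integer_, nx, ny)
  state_grid[cbind(ix, iy)] <- seq_along(ix)
  list(coords = coords, ix = ix, iy = iy, state_grid = state_grid)
}

# Adjacency over the 8 compass actions; moves leaving `open` cells are no-ops.
.grid_adjacency <- function(g, nx, ny, open = NULL) {
  n <- nrow(g$coords)
  if (is.null(open)) open <- rep(TRUE, n)
  adj <- matrix(seq_len(n), n, 8)
  for (a in 1:8) {
    jx <- g$ix + .dir_dx[a]
    jy <- g$iy + .dir_dy[a]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    tgt <- rep(NA_integer_, n)
    tgt[ok] <- g$state_grid[cbind(jx[ok], jy[ok])]
    ok <- ok & !is.na(tgt) & open[ifelse(is.na(tgt), 1L, tgt)]
    adj[ok, a] <- tgt[ok]
  }
  adj[!open, ] <- matrix(rep(which(!open), 8), sum(!open), 8)  # unreachable cells self-loop
  adj
}

.rect_walls <- function(nx, ny) {
  hx <- nx / 2; hy <- ny / 2
  rbind(c(-hx, -hy, hx, -hy), c(hx, -hy, hx, hy),
        c(hx, hy, -hx, hy), c(-hx, hy, -hx, -hy))
}

.new_arena <- function(kind, nx, ny, g, adj, boundaries, landmarks, goal,
                       start_poses, extra = list()) {
  structure(c(list(
    kind = kind, nx = nx, ny = ny,
    n_states = nrow(g$coords), coords = g$coords,
    state_grid = g$state_grid, ix = g$ix, iy = g$iy,
    adj = adj, boundaries = boundaries,
    landmarks = landmarks, goal = goal,
    start_poses = start_poses, terminal_states = integer(0)
  ), extra), class = "arena")
}

.validate_arena <- function(arena) {
  if (arena$n_states < 1) stop("degenerate arena: no traversable states")
  if (!is.null(arena$landmarks) && nrow(arena$landmarks) &&
      anyDuplicated(arena$landmarks$id)) {
    stop("landmark identities must be unique")
  }
  if (!is.null(arena$goal)) {
    d <- sqrt(colSums((t(arena$coords) - arena$goal$center)^2))
    if (min(d) > max(arena$goal$radius, 1)) {
      stop("goal region lies outside the traversable arena")
    }
  }
  invisible(arena)
}

# -- kinds --------------------------------------------------------------------

.build_linear_track <- function(n, reward_prob) {
  if (n < 2) stop("degenerate arena: linear track needs at least 2 states")
  mask <- matrix(TRUE, n, 1)
  g <- .grid_coords(n, 1, mask)
  adj <- .grid_adjacency(g, n, 1)
  lm <- data.frame(x = g$coords[, 1], y = g$coords[, 2],
                   id = paste0("s", seq_len(n)), stringsAsFactors = FALSE)
  goal <- list(center = g$coords[n, ], radius = 0.45, reward_prob = reward_prob)
  .new_arena("linear_track", n, 1, g, adj, .rect_walls(n, 1), lm, goal,
             list(list(state = 1L, heading = 1L)))
}

.default_session_centers <- function(n_sessions, radius) {
  k <- seq_len(n_sessions)
  ang <- 2 * pi * ((k * 5) %% n_sessions) / n_sessions
  cbind(radius * cos(ang), radius * sin(ang))
}

.build_water_maze <- function(grid_n, platform_radius, landmark_offset,
                              n_sessions, session_centers, reward_prob) {
  mask <- matrix(TRUE, grid_n, grid_n)
  g <- .grid_coords(grid_n, grid_n, mask)
  adj <- .grid_adjacency(g, grid_n, grid_n)
  if (is.null(session_centers)) {
    session_centers <- .default_session_centers(n_sessions, radius = 0.28 * grid_n)
  }
  stopifnot(nrow(session_centers) == n_sessions)
  h <- grid_n / 2 - 1
  starts <- list(
    list(state = g$state_grid[grid_n %/% 2, 1], heading = 3L),      # south edge, facing N
    list(state = g$state_grid[1, grid_n %/% 2], heading = 1L),      # west edge, facing E
    list(state = g$state_grid[grid_n %/% 2, grid_n], heading = 7L), # north edge, facing S
    list(state = g$state_grid[grid_n, grid_n %/% 2], heading = 5L)  # east edge, facing W
  )
  arena <- .new_arena("water_maze", grid_n, grid_n, g, adj,
                      .rect_walls(grid_n, grid_n), NULL, NULL, starts,
                      extra = list(sessions = list(centers = session_centers,
                                                   landmark_offset = landmark_offset,
                                                   reward_prob = reward_prob)))
  configure_session(arena, 1L)
}

.plus_arm_dirs <- c(N = 3L, W = 5L, S = 7L, E = 1L)

.build_plus_maze <- function(arm_len, goal_arm, start_arm, blocked_arm) {
  side <- 2L * arm_len + 1L
  c0 <- arm_len + 1L
  mask <- matrix(FALSE, side, side)
  mask[c0, ] <- TRUE
  mask[, c0] <- TRUE
  g <- .grid_coords(side, side, mask)
  arm_end <- function(arm) {
    switch(arm, N = g$state_grid[c0, side], S = g$state_grid[c0, 1],
           E = g$state_grid[side, c0], W = g$state_grid[1, c0])
  }
  ends <- vapply(c("N", "E", "S", "W"), arm_end, integer(1))
  lm <- data.frame(x = 0, y = 0, id = "ctr", stringsAsFactors = FALSE)
  arena <- .new_arena("plus_maze", side, side, g, NULL, .rect_walls(side, side),
                      lm, NULL, NULL,
                      extra = list(arm_len = arm_len, arm_ends = ends,
                                   goal_arm = goal_arm))
  plus_configure(arena, start_arm = start_arm, blocked_arm = blocked_arm,
                 goal_arm = goal_arm)
}

#' Reconfigure plus-maze arms
#'
#' Sets the start arm, the blocked arm and (for probe trials) which arm ends
#' terminate the trial. The state space is unchanged; only adjacency, start
#' pose and termination rules are rebuilt, so learned state is portable
#' between configurations.
#'
#' @param arena a plus-maze [build_arena()] object.
#' @param start_arm,blocked_arm,goal_arm arm labels (`"N"/"E"/"S"/"W"`);
#'   `blocked_arm = NULL` opens all arms. `goal_arm = NULL` removes the
#'   reward.
#' @param terminal_arms arm labels whose ends end the trial without reward
#'   (probe classification); default none.
#' @return The reconfigured arena.
#' @export
plus_configure <- function(arena, start_arm, blocked_arm = NULL,
                           goal_arm = arena$goal_arm, terminal_arms = character(0)) {
  stopifnot(inherits(arena, "arena"), arena$kind == "plus_maze")
  c0 <- arena$arm_len + 1L
  open <- rep(TRUE, arena$n_states)
  if (!is.null(blocked_arm)) {
    blk <- switch(blocked_arm,
                  N = arena$ix == c0 & arena$iy > c0,
                  S = arena$ix == c0 & arena$iy < c0,
                  E = arena$ix > c0 & arena$iy == c0,
                  W = arena$ix < c0 & arena$iy == c0,
                  stop("unknown arm: ", blocked_arm))
    open[blk] <- FALSE
  }
  arena$adj <- .grid_adjacency(arena, arena$nx, arena$ny, open)
  start_state <- arena$arm_ends[[start_arm]]
  heading <- switch(start_arm, N = 7L, S = 3L, E = 5L, W = 1L)  # face the center
  arena$start_poses <- list(list(state = start_state, heading = heading))
  arena["goal"] <- list(if (is.null(goal_arm)) NULL else {
    list(center = arena$coords[arena$arm_ends[[goal_arm]], ],
         radius = 0.45, reward_prob = 1)
  })
  arena$terminal_states <- unname(arena$arm_ends[terminal_arms])
  arena
}

.build_open_field <- function(grid_n, walls, landmarks, goal) {
  mask <- matrix(TRUE, grid_n, grid_n)
  g <- .grid_coords(grid_n, grid_n, mask)
  adj <- .grid_adjacency(g, grid_n, grid_n)
  h <- grid_n / 2
  starts <- list(
    list(state = g$state_grid[grid_n %/% 2, grid_n], heading = 7L),
    list(state = g$state_grid[grid_n, grid_n %/% 2], heading = 5L)
  )
  .new_arena("open_field", grid_n, grid_n, g, adj, walls, landmarks, goal, starts)
}

#' Move the water-maze platform and landmark to a session's location
#'
#' The platform center and the landmark are translated jointly; the
#' landmark-minus-platform offset is identical across sessions.
#'
#' @param arena a water-maze [build_arena()] object.
#' @param session_index 1-based session number (at most the number of
#'   configured locations).
#' @return The arena with `goal` and `landmarks` set for that session.
#' @export
configure_session <- function(arena, session_index) {
  stopifnot(inherits(arena, "arena"))
  if (arena$kind != "water_maze") stop("configure_session applies to water mazes")
  if (session_index < 1 || session_index > nrow(arena$sessions$centers)) {
    stop("session index exceeds the configured location list")
  }
  ctr <- arena$sessions$centers[session_index, ]
  arena$goal <- list(center = ctr, radius = 1.2,
                     reward_prob = arena$sessions$reward_prob)
  arena$landmarks <- data.frame(x = ctr[1] + arena$sessions$landmark_offset[1],
                                y = ctr[2] + arena$sessions$landmark_offset[2],
                                id = "cue", stringsAsFactors = FALSE)
  arena$session <- session_index
  arena
}

#' Advance the agent one grid step
#'
#' The next pose is the adjacent grid cell in the chosen allocentric
#' direction, clipped at boundaries (a blocked move leaves the position
#' unchanged). Reward is drawn from the goal's Bernoulli rule when the goal
#' region is entered, which also terminates the trial.
#'
#' @param arena an [build_arena()] object.
#' @param state current state index.
#' @param action allocentric action index in 1..8.
#' @return `list(state, next_state, reward, terminal)`.
#' @export
arena_step <- function(arena, state, action) {
  if (state < 1 || state > arena$n_states) stop("pose outside arena")
  if (action < 1 || action > 8) stop("action not in action set")
  ns <- arena$adj[state, action]
  reward <- 0
  terminal <- FALSE
  if (!is.null(arena$goal)) {
    d2 <- sum((arena$coords[ns, ] - arena$goal$center)^2)
    if (d2 <= arena$goal$radius^2) {
      reward <- stats::rbinom(1L, 1L, arena$goal$reward_prob)
      terminal <- TRUE
    }
  }
  if (ns %in% arena$terminal_states) terminal <- TRUE
  list(state = state, next_state = ns, reward = reward, terminal = terminal)
}

#' Uniform random-walk transition matrix of an arena
#'
#' Each of the 8 compass actions is taken with probability 1/8; clipped moves
#' contribute to the self-transition.
#'
#' @param arena an [build_arena()] object.
#' @return An `n_states` x `n_states` row-stochastic matrix.
#' @export
rw_transition_matrix <- function(arena) {
  n <- arena$n_states
  T <- matrix(0, n, n)
  for (a in 1:8) {
    idx <- cbind(seq_len(n), arena$adj[, a])
    T[idx] <- T[idx] + 1 / 8
  }
  T
}

# -- task graphs --------------------------------------------------------------

#' Construct a two-step decision-task graph
#'
#' The `daw_two_step` variant has one start state with two actions leading to
#' one of two second-stage states (common transition with probability
#' `common_prob`, rare with `1 - common_prob`), each second-stage action
#' yielding one of four terminal outcomes whose reward probabilities drift as
#' a bounded Gaussian random walk. The `deterministic_two_step` variant has
#' deterministic first-stage transitions.
#'
#' @param variant `"daw_two_step"` or `"deterministic_two_step"`.
#' @param common_prob probability of the common first-stage transition.
#' @param drift_sd per-trial Gaussian step of the outcome reward
#'   probabilities.
#' @param prob_bounds interval the reward probabilities are kept within.
#' @param reward_probs optional initial outcome reward probabilities (length
#'   4); drawn uniformly inside `prob_bounds` when `NULL` (uses the current
#'   RNG state).
#' @return An object of class `"task_graph"` with states 1 (start), 2-3
#'   (second stage) and 4-7 (terminal outcomes), transition array `P`
#'   (`state` x `action` x `next state`), and the drift configuration.
#' @export
build_task_graph <- function(variant = c("daw_two_step", "deterministic_two_step"),
                             common_prob = 0.7, drift_sd = 0.025,
                             prob_bounds = c(0.25, 0.75), reward_probs = NULL) {
  variant <- match.arg(variant)
  if (variant == "deterministic_two_step") common_prob <- 1
  P <- array(0, dim = c(7, 2, 7))
  P[1, 1, 2] <- common_prob; P[1, 1, 3] <- 1 - common_prob
  P[1, 2, 3] <- common_prob; P[1, 2, 2] <- 1 - common_prob
  P[2, 1, 4] <- 1; P[2, 2, 5] <- 1
  P[3, 1, 6] <- 1; P[3, 2, 7] <- 1
  if (is.null(reward_probs)) {
    reward_probs <- stats::runif(4, prob_bounds[1], prob_bounds[2])
  }
  stopifnot(length(reward_probs) == 4,
            all(reward_probs >= prob_bounds[1] & reward_probs <= prob_bounds[2]))
  structure(list(
    variant = variant, n_states = 7L, n_actions = 2L,
    choice_states = 1:3, outcome_states = 4:7,
    P = P, common_next = c(2L, 3L),  # commonly reached second stage per action
    reward_probs = reward_probs, drift_sd = drift_sd, prob_bounds = prob_bounds
  ), class = "task_graph")
}

#' Advance the task graph one step
#'
#' Samples the next state from the transition distribution and, when a
#' terminal outcome is entered, a Bernoulli reward at that outcome's current
#' probability.
#'
#' @param graph a [build_task_graph()] object.
#' @param state current state (must have actions).
#' @param action action index (1 or 2).
#' @return `list(state, next_state, reward, terminal, common)`; `common` is
#'   `NA` except for first-stage transitions, where it flags a common
#'   transition.
#' @export
graph_step <- function(graph, state, action) {
  if (!state %in% graph$choice_states) stop("invalid state: no actions here")
  if (!action %in% c(1L, 2L)) stop("invalid action")
  p <- graph$P[state, action, ]
  ns <- sample.int(7L, 1L, prob = p)
  reward <- 0
  terminal <- FALSE
  if (ns %in% graph$outcome_states) {
    reward <- stats::rbinom(1L, 1L, graph$reward_probs[ns - 3L])
    terminal <- TRUE
  }
  common <- if (state == 1L) ns == graph$common_next[action] else NA
  list(state = state, next_state = ns, reward = reward,
       terminal = terminal, common = common)
}

#' Advance the outcome reward-probability random walk
#'
#' Adds a Gaussian increment to every outcome probability and clips the
#' result to the configured bounds; call once at the end of each trial.
#'
#' @param graph a [build_task_graph()] object.
#' @return The graph with updated `reward_probs`.
#' @export
advance_reward_probs <- function(graph) {
  p <- graph$reward_probs + stats::rnorm(4, 0, graph$drift_sd)
  graph$reward_probs <- clip(p, graph$prob_bounds[1], graph$prob_bounds[2])
  graph
}

#' @export
print.arena <- function(x, ...) {
  cat("<arena:", x$kind, "> ", x$n_states, " states (", x$nx, "x", x$ny, " grid)\n",
      sep = "")
  if (!is.null(x$goal)) {
    cat("  goal at (", paste(signif(x$goal$center, 3), collapse = ", "),
        "), radius ", x$goal$radius, ", p(reward) = ", x$goal$reward_prob, "\n", sep = "")
  }
  if (!is.null(x$landmarks) && nrow(x$landmarks)) {
    cat("  landmarks:", paste(x$landmarks$id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.task_graph <- function(x, ...) {
  cat("<task_graph:", x$variant, "> reward probs ",
      paste(signif(x$reward_probs, 3), collapse = ", "),
      " in [", x$prob_bounds[1], ", ", x$prob_bounds[2], "]\n", sep = "")
  invisible(x)
}
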