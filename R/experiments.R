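# The five simulated protocols: adapted water maze (landmark + platform
# moved jointly each session), plus-maze place/response probes with outcome
# devaluation, landmark versus boundary blocking, the two-step decision
# task, and the cross-task correlation study.

# -- adapted water maze (landmark moved with the platform) --------------------

.pearce_lc_bank <- function(grid_n) {
  lc_bank("cue",
          distances = seq(1, 0.7 * grid_n, length.out = 6),
          sigma_d = 0.6 * (0.7 * grid_n - 1) / 5)
}

.pearce_one_agent <- function(config, grid_n = 20, n_sessions = 11,
                              trials_per_session = 4, max_steps = 300,
                              lesion_bounds = c(0, 1), snapshots = TRUE) {
  arena <- build_arena("water_maze", grid_n = grid_n, n_sessions = n_sessions)
  ag <- make_spatial_agent(arena, config, hpc = "tabular",
                           lc_bank = .pearce_lc_bank(grid_n))
  set_psr_bounds(ag, lesion_bounds)
  latency <- matrix(NA_real_, n_sessions, trials_per_session)
  mem_dist <- rep(NA_real_, n_sessions)   # value argmax vs previous platform
  # trial-1 occupancy accumulated in a previous-platform-centered frame
  side <- 2L * grid_n - 1L
  rel_occ <- matrix(0, side, side)
  prev_center <- NULL
  for (ses in seq_len(n_sessions)) {
    arena <- configure_session(arena, ses)
    agent_set_arena(ag, arena)
    if (!is.null(prev_center) && snapshots) {
      vm <- value_map(ag)
      mem_dist[ses] <- sqrt(sum((vm$argmax_xy - prev_center)^2))
    }
    for (tr in seq_len(trials_per_session)) {
      start <- arena$start_poses[[((tr - 1L) %% length(arena$start_poses)) + 1L]]
      rec <- run_trial(ag, arena, start = start, max_steps = max_steps)
      latency[ses, tr] <- rec$steps
      if (tr == 1L && !is.null(prev_center)) {
        occ <- tabulate(rec$states, nbins = arena$n_states)
        occ[start$state] <- 0  # the start cell is occupied by construction
        dx <- round(arena$coords[, 1] - prev_center[1]) + grid_n
        dy <- round(arena$coords[, 2] - prev_center[2]) + grid_n
        keep <- dx >= 1 & dx <= side & dy >= 1 & dy <= side
        idx <- cbind(dx[keep], dy[keep])
        rel_occ[idx] <- rel_occ[idx] + occ[keep]
      }
    }
    prev_center <- arena$goal$center
  }
  list(latency = latency, rel_occ = rel_occ, mem_dist = mem_dist,
       final_psr = ag$psr)
}

#' Adapted water-maze protocol
#'
#' Sessions of `trials_per_session` trials; at each session start the hidden
#' platform and the single intramaze landmark move jointly to the next
#' configured location (their offset never changes). Arms: `"none"`
#' (control), `"hpc"` (SR influence clamped to 0) or `"dls"` (clamped to 1).
#'
#' @param n_agents number of independently seeded agents.
#' @param lesion lesion arm, see above.
#' @param config an [agent_config()].
#' @param seed integer seed.
#' @param grid_n,n_sessions,trials_per_session,max_steps protocol geometry
#'   and schedule.
#' @param snapshots record value-map argmax distances at session starts
#'   (needed for [place_memory_score()]).
#' @return A list with `latency` (`agent` x `session` x `trial` array),
#'   `mem_dist` (`agent` x `session` matrix of value-argmax distances to the
#'   previous platform), `rel_occ` (trial-1 occupancy summed over agents and
#'   sessions in a previous-platform-centered frame; the platform sits at
#'   the matrix center), `occ_peak_dist` (distance of the occupancy peak
#'   from the previous platform, in cells), and the lesion arm.
#' @export
run_pearce <- function(n_agents = 10, lesion = c("none", "hpc", "dls"),
                       config = agent_config(), seed = 1, grid_n = 20,
                       n_sessions = 11, trials_per_session = 4,
                       max_steps = 300, snapshots = TRUE) {
  lesion <- match.arg(lesion)
  bounds <- switch(lesion, none = c(0, 1), hpc = c(0, 0), dls = c(1, 1))
  res <- run_agents(n_agents, seed, function(i, s) {
    .pearce_one_agent(config, grid_n, n_sessions, trials_per_session,
                      max_steps, bounds, snapshots)
  })
  latency <- array(NA_real_, c(n_agents, n_sessions, trials_per_session))
  mem <- matrix(NA_real_, n_agents, n_sessions)
  rel_occ <- matrix(0, 2L * grid_n - 1L, 2L * grid_n - 1L)
  for (i in seq_along(res)) {
    latency[i, , ] <- res[[i]]$latency
    mem[i, ] <- res[[i]]$mem_dist
    rel_occ <- rel_occ + res[[i]]$rel_occ
  }
  pk <- arrayInd(which.max(rel_occ), dim(rel_occ))
  occ_peak_dist <- sqrt(sum((pk - grid_n)^2))
  list(latency = latency, mem_dist = mem, rel_occ = rel_occ,
       occ_peak_dist = occ_peak_dist, lesion = lesion, grid_n = grid_n)
}

#' Allocentric place-memory score
#'
#' Mean distance between the previous platform location and the argmax of
#' the agent's net value map at the start of the next session; smaller
#' distances indicate stronger allocentric place memory.
#'
#' @param mem_dist vector (or matrix row) of per-session argmax distances as
#'   returned by [run_pearce()] / the correlation study.
#' @return Scalar mean distance (NA-safe).
#' @export
place_memory_score <- function(mem_dist) {
  mean(mem_dist, na.rm = TRUE)
}

# -- plus maze: place versus response ----------------------------------------

#' Classify a probe trajectory as place or response strategy
#'
#' A probe starts in the arm opposite training. Reaching the trained goal
#' arm's end is a place strategy (same allocentric location); reaching the
#' opposite arm's end is a response strategy (same egocentric turn); a trial
#' that reaches neither within the step cap is unclassified.
#'
#' @param record a [run_trial()] record.
#' @param place_state,response_state arm-end state indices.
#' @return `"place"`, `"response"` or `"unclassified"`.
#' @export
classify_strategy <- function(record, place_state, response_state) {
  final <- record$states[length(record$states)]
  if (final == place_state) "place"
  else if (final == response_state) "response"
  else "unclassified"
}

.opposite_arm <- c(N = "S", S = "N", E = "W", W = "E")

.plus_probe <- function(ag, arena, probe_cfg, bounds, deval_factor = 1) {
  cp <- clone_agent(ag)
  set_psr_bounds(cp, bounds)
  if (deval_factor < 1) cp$Rhat <- devalue(cp$Rhat, deval_factor)
  agent_set_arena(cp, probe_cfg)
  rec <- run_trial(cp, probe_cfg, learn = FALSE, max_steps = 100)
  goal_end <- arena$arm_ends[[arena$goal_arm]]
  resp_end <- arena$arm_ends[[.opposite_arm[[arena$goal_arm]]]]
  classify_strategy(rec, goal_end, resp_end)
}

#' Plus-maze place/response protocol with probe-time inactivations
#'
#' Agents are trained from a fixed start arm to a baited goal arm with the
#' opposite arm blocked. At each probe point a frozen copy of the agent
#' starts from the arm opposite training (training start blocked, both goal
#' arms' ends terminal, no learning) under each inactivation arm: control,
#' `hpc` (SR influence clamped to 0) and `dls` (clamped to 1) -- modeling
#' probe-time lidocaine. Optionally the probe is repeated after devaluing
#' the hippocampal reward representation (prefeeding), which leaves striatal
#' weights untouched.
#'
#' @param n_agents number of agents.
#' @param probe_trials training-trial counts after which probes run.
#' @param n_trials total training trials.
#' @param devaluation also run devalued probes?
#' @param deval_factor reward scaling under devaluation (0 = full).
#' @param config an [agent_config()].
#' @param seed integer seed.
#' @param arm_len plus-maze arm length.
#' @return A `data.frame` with columns `agent`, `probe` (index), `trained`
#'   (trials so far), `arm`, `deval`, `strategy`.
#' @export
run_plus_maze <- function(n_agents = 20, probe_trials = c(28, 60),
                          n_trials = max(probe_trials), devaluation = TRUE,
                          deval_factor = 0, config = agent_config(),
                          seed = 1, arm_len = 4) {
  arms <- c("control", "hpc", "dls")
  res <- run_agents(n_agents, seed, function(i, s) {
    arena <- build_arena("plus_maze", arm_len = arm_len)
    open <- plus_configure(arena, start_arm = "S", blocked_arm = NULL)
    ag <- make_spatial_agent(open, config, hpc = "tabular",
                             lc_bank = lc_bank("ctr", distances = 1:4,
                                               sigma_d = 0.8))
    train_cfg <- plus_configure(arena, start_arm = "S", blocked_arm = "N")
    agent_set_arena(ag, train_cfg)
    probe_cfg <- plus_configure(arena, start_arm = "N", blocked_arm = "S",
                                goal_arm = NULL,
                                terminal_arms = c(arena$goal_arm,
                                                  .opposite_arm[[arena$goal_arm]]))
    out <- list()
    probe_no <- 0L
    for (tr in seq_len(n_trials)) {
      run_trial(ag, train_cfg, max_steps = 100)
      if (tr %in% probe_trials) {
        probe_no <- probe_no + 1L
        for (arm in arms) {
          b <- switch(arm, control = config$psr_bounds, hpc = c(0, 0), dls = c(1, 1))
          out[[length(out) + 1L]] <- data.frame(
            agent = i, probe = probe_no, trained = tr, arm = arm, deval = FALSE,
            strategy = .plus_probe(ag, arena, probe_cfg, b), stringsAsFactors = FALSE)
          if (devaluation) {
            out[[length(out) + 1L]] <- data.frame(
              agent = i, probe = probe_no, trained = tr, arm = arm, deval = TRUE,
              strategy = .plus_probe(ag, arena, probe_cfg, b, deval_factor),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, out)
  })
  do.call(rbind, res)
}

#' Strategy proportions at plus-maze probes
#'
#' @param probes the `data.frame` from [run_plus_maze()].
#' @return A `data.frame` of place/response proportions (over classified
#'   trials) per probe x arm x devaluation cell.
#' @export
strategy_proportions <- function(probes) {
  cl <- probes[probes$strategy != "unclassified", ]
  agg <- stats::aggregate(strategy ~ probe + arm + deval, data = cl,
                   FUN = function(x) mean(x == "place"))
  names(agg)[names(agg) == "strategy"] <- "p_place"
  agg$p_response <- 1 - agg$p_place
  agg[order(agg$probe, agg$arm, agg$deval), ]
}

# -- landmark versus boundary blocking ---------------------------------------

.blocking_geometry <- function(grid_n) {
  hw <- grid_n / 2
  span <- round(grid_n / 4)
  list(
    platform = c(-0.25 * grid_n + 1, -0.25 * grid_n + 1),
    # enclosure walls (always present) then the two removable inner walls
    enclosure = .rect_walls(grid_n, grid_n),
    west = c(-hw + 1, -span, -hw + 1, span),
    south = c(-span, -hw + 1, span, -hw + 1),
    l1_offset = c(1.5, 2.5),
    l2_offset = c(-2.5, 1.5)
  )
}

# Shared, agent-independent pieces of the blocking setup (the place-field
# maps are expensive to integrate and identical across agents).
.blocking_setup <- function(condition, grid_n) {
  geo <- .blocking_geometry(grid_n)
  goal <- list(center = geo$platform, radius = 1.2, reward_prob = 1)
  if (condition == "boundary") {
    full_walls <- rbind(geo$enclosure, geo$west, geo$south)
    wall_sets <- list(c(1:4, 5L), 1:6, c(1:4, 6L))
    arenas <- lapply(wall_sets, function(idx) {
      build_arena("open_field", grid_n = grid_n,
                  walls = full_walls[idx, , drop = FALSE],
                  landmarks = NULL, goal = goal)
    })
    centers <- as.matrix(expand.grid(
      x = seq(-grid_n / 2 + 1.5, grid_n / 2 - 1.5, length.out = 6),
      y = seq(-grid_n / 2 + 1.5, grid_n / 2 - 1.5, length.out = 6)))
    bank <- place_cell_bank(centers, full_walls, per_wall = TRUE,
                            threshold_frac = 0.5)
    pcmaps <- lapply(1:3, function(ph) {
      place_field_maps(arenas[[ph]], bank, wall_ids = wall_sets[[ph]])
    })
    list(geo = geo, goal = goal, arenas = arenas, bank = bank,
         wall_sets = wall_sets, pcmaps = pcmaps)
  } else {
    list(geo = geo, goal = goal)
  }
}

.blocking_one_agent <- function(condition, config, grid_n, trials_per_phase,
                                max_steps, setup) {
  geo <- setup$geo
  goal <- setup$goal
  if (condition == "landmark") {
    lm <- function(ids) {
      offs <- list(L1 = geo$l1_offset, L2 = geo$l2_offset)[ids]
      do.call(rbind, lapply(ids, function(id) {
        data.frame(x = geo$platform[1] + offs[[id]][1],
                   y = geo$platform[2] + offs[[id]][2], id = id,
                   stringsAsFactors = FALSE)
      }))
    }
    arenas <- lapply(list("L1", c("L1", "L2"), "L2"), function(ids) {
      build_arena("open_field", grid_n = grid_n, walls = NULL,
                  landmarks = lm(ids), goal = goal)
    })
    bank <- lc_bank(c("L1", "L2"),
                    distances = seq(1, 0.7 * grid_n, length.out = 5),
                    sigma_d = 0.6 * (0.7 * grid_n - 1) / 4)
    ag <- make_spatial_agent(arenas[[1]], config, hpc = "tabular",
                             lc_bank = bank)
    set_psr_bounds(ag, c(0, 0))  # behavior assumed DLS-controlled
  } else {
    # the pool enclosure always drives place cells; the two inner walls are
    # the trained/compound/removed boundary cues
    arenas <- setup$arenas
    ag <- make_spatial_agent(arenas[[1]], config, hpc = "sf",
                             pc_bank = setup$bank, wall_ids = setup$wall_sets[[1]])
    set_psr_bounds(ag, c(1, 1))  # behavior assumed HPC-controlled
  }
  latency <- numeric(3 * trials_per_phase)
  k <- 0L
  for (ph in 1:3) {
    if (condition == "landmark") {
      agent_set_arena(ag, arenas[[ph]])
    } else {
      ag$arena <- arenas[[ph]]
      ag$pcmap <- setup$pcmaps[[ph]]
    }
    for (tr in seq_len(trials_per_phase)) {
      start <- arenas[[ph]]$start_poses[[((tr - 1L) %% 2L) + 1L]]
      rec <- run_trial(ag, arenas[[ph]], start = start, max_steps = max_steps)
      k <- k + 1L
      latency[k] <- rec$steps
    }
  }
  latency
}

#' Landmark versus boundary blocking protocol
#'
#' Three phases of `trials_per_phase` trials in an open field with a hidden
#' platform: initial learning with one cue (landmark L1, or the west
#' boundary), compound learning with a second cue added (L2, or the south
#' boundary), then removal of the first cue. In the landmark condition no
#' boundaries enter the feature input and behavior is striatally controlled;
#' in the boundary condition there are no landmarks and behavior is
#' hippocampally controlled (successor features over BVC-driven place
#' cells).
#'
#' @param condition `"landmark"` or `"boundary"`.
#' @param n_agents number of agents.
#' @param trials_per_phase trials per phase (10 as in the modeled design).
#' @param config an [agent_config()].
#' @param seed integer seed.
#' @param grid_n field size; `max_steps` trial cap.
#' @param max_steps trial step cap.
#' @return A list with the `latency` matrix (`agent` x trial), per-phase
#'   means, and a one-sided paired test of the phase-3 minus phase-2 escape
#'   time contrast (blocking).
#' @export
run_blocking <- function(condition = c("landmark", "boundary"), n_agents = 20,
                         trials_per_phase = 10, config = agent_config(),
                         seed = 1, grid_n = 15, max_steps = 300) {
  condition <- match.arg(condition)
  setup <- .blocking_setup(condition, grid_n)
  res <- run_agents(n_agents, seed, function(i, s) {
    .blocking_one_agent(condition, config, grid_n, trials_per_phase,
                        max_steps, setup)
  })
  latency <- do.call(rbind, res)
  phase <- rep(1:3, each = trials_per_phase)
  phase_means <- vapply(1:3, function(p) mean(latency[, phase == p]), numeric(1))
  d <- rowMeans(latency[, phase == 3, drop = FALSE]) -
    rowMeans(latency[, phase == 2, drop = FALSE])
  tt <- stats::t.test(d, alternative = "greater")
  list(condition = condition, latency = latency, phase = phase,
       phase_means = phase_means,
       blocking_test = list(statistic = unname(tt$statistic),
                            p_value = tt$p.value, mean_increase = mean(d)))
}
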