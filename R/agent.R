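# Agent runtime: composes the striatal and hippocampal learners with the
# arbitrator and runs trials. Agents are environments (reference semantics)
# so that large learned matrices are updated in place inside the step loop.
# The step loop inlines the module update formulas for speed; the exported
# module functions implement the identical arithmetic and the test suite
# checks the equivalence on small instances.

#' Agent configuration
#'
#' All tunable parameters of the dual-system agent. Units: distances are
#' grid cells; one time step is one environment step.
#'
#' @param gamma discount factor.
#' @param alpha_q striatal Q learning rate.
#' @param lambda striatal eligibility-trace decay.
#' @param alpha_m SR / successor-feature learning rate.
#' @param alpha_r reward-representation learning rate.
#' @param eta learning rate of the SR system's prediction-error average
#'   (updated every step: the state-prediction error is defined densely).
#' @param eta_mf learning rate of the model-free system's prediction-error
#'   average, updated at outcome events (terminal or rewarded steps), where
#'   the reward-prediction error is informative.
#' @param delta_max prediction-error upper bound of the reliability measure.
#' @param A_alpha,B_alpha,A_beta,B_beta arbitration transition-rate
#'   parameters, see [transition_rates()].
#' @param beta_softmax softmax inverse temperature of action selection.
#' @param psr_bounds lesion clamp interval on the SR influence.
#' @param omega_mf0,omega_sr0 initial prediction-error averages: the
#'   model-free system starts maximally unreliable (no reward learning has
#'   occurred), the SR prior starts nearly reliable (preexposure).
#' @param dt arbitration time step per environment step.
#' @param max_steps trial step cap (the trial is flagged, not an error).
#' @return A list of class `"agent_config"`.
#' @export
agent_config <- function(gamma = 0.95, alpha_q = 0.1, lambda = 0.9,
                         alpha_m = 0.3, alpha_r = 0.3, eta = 0.01,
                         eta_mf = 0.015, delta_max = 1, A_alpha = 1, B_alpha = 6,
                         A_beta = 0.3, B_beta = 1, beta_softmax = 20,
                         psr_bounds = c(0, 1), omega_mf0 = 1,
                         omega_sr0 = 0.1, dt = 1, max_steps = 300) {
  stopifnot(gamma >= 0, gamma < 1, beta_softmax > 0,
            psr_bounds[1] >= 0, psr_bounds[2] <= 1,
            psr_bounds[1] <= psr_bounds[2])
  structure(as.list(environment()), class = "agent_config")
}

.init_psr <- function(cfg) {
  chi_mf <- reliability(cfg$omega_mf0, cfg$delta_max)
  chi_sr <- reliability(cfg$omega_sr0, cfg$delta_max)
  rt <- transition_rates(chi_mf, chi_sr, cfg$A_alpha, cfg$B_alpha,
                         cfg$A_beta, cfg$B_beta)
  clip(rt$alpha / (rt$alpha + rt$beta), cfg$psr_bounds[1], cfg$psr_bounds[2])
}

#' Create a dual-system agent for a spatial arena
#'
#' The striatal system reads egocentric landmark-cell features and learns Q
#' values over the 8 egocentric turn actions. The hippocampal system is
#' either a tabular SR over grid states (initialized to the random-walk SR,
#' reflecting reward-free preexposure) or successor features over a
#' BVC-driven place-cell bank (initialized to the identity weight matrix).
#'
#' @param arena an [build_arena()] object.
#' @param config an [agent_config()].
#' @param hpc `"tabular"` or `"sf"`.
#' @param lc_bank an [lc_bank()]; a default bank over the arena's landmark
#'   identities is built when `NULL`.
#' @param pc_bank a [place_cell_bank()] (required when `hpc = "sf"`).
#' @param wall_ids mapping of the arena's current walls to the place-cell
#'   bank's reference walls.
#' @return An environment of class `"dual_agent"`.
#' @export
make_spatial_agent <- function(arena, config = agent_config(),
                               hpc = c("tabular", "sf"), lc_bank = NULL,
                               pc_bank = NULL,
                               wall_ids = seq_len(NROW(arena$boundaries))) {
  hpc <- match.arg(hpc)
  if (is.null(lc_bank)) {
    ids <- if (!is.null(arena$landmarks)) unique(arena$landmarks$id) else character(0)
    lc_bank <- lc_bank(ids, distances = pmax(1, seq(1, max(arena$nx, arena$ny) / 2,
                                                    length.out = 4)))
  }
  ag <- new.env(parent = emptyenv())
  ag$type <- "spatial"
  ag$cfg <- config
  ag$hpc_type <- hpc
  ag$lc_bank <- lc_bank
  ag$n_lc <- nrow(lc_bank)
  ag$w <- matrix(0, ag$n_lc, 8)
  ag$e <- matrix(0, ag$n_lc, 8)
  if (hpc == "tabular") {
    ag$M <- random_walk_sr(arena, config$gamma)
    ag$Rhat <- numeric(arena$n_states)
  } else {
    if (is.null(pc_bank)) stop("hpc = 'sf' requires a place-cell bank")
    ag$pc_bank <- pc_bank
    ag$W <- identity_sr(length(pc_bank))
    ag$u <- numeric(length(pc_bank))
  }
  ag$omega_mf <- config$omega_mf0
  ag$omega_sr <- config$omega_sr0
  ag$bounds <- config$psr_bounds
  ag$psr <- .init_psr(config)
  class(ag) <- "dual_agent"
  agent_set_arena(ag, arena, wall_ids)
  ag
}

#' Bind an agent to a (reconfigured) arena
#'
#' Recomputes the cached feature tables (landmark-cell tables; place-field
#' maps for successor-feature agents); learned weights are untouched.
#'
#' @param ag a `"dual_agent"`.
#' @param arena the arena (same state space as at creation).
#' @param wall_ids wall mapping for the place-cell bank.
#' @return The agent, invisibly.
#' @export
agent_set_arena <- function(ag, arena, wall_ids = seq_len(NROW(arena$boundaries))) {
  stopifnot(inherits(ag, "dual_agent"), ag$type == "spatial")
  ag$arena <- arena
  ag$lc_tabs <- lc_feature_tables(arena, ag$lc_bank)
  if (ag$hpc_type == "sf") {
    ag$pcmap <- place_field_maps(arena, ag$pc_bank, wall_ids)
  }
  invisible(ag)
}

#' Create a dual-system agent for a task graph
#'
#' Both systems operate on one-hot state features; the SR is initialized to
#' the identity (no preexposure to the graph). The hippocampal lookahead
#' uses the graph's true transition probabilities.
#'
#' @param graph a [build_task_graph()] object.
#' @param config an [agent_config()].
#' @return An environment of class `"dual_agent"`.
#' @export
make_graph_agent <- function(graph, config = agent_config()) {
  ag <- new.env(parent = emptyenv())
  ag$type <- "graph"
  ag$cfg <- config
  ag$hpc_type <- "tabular"
  ag$graph <- graph
  n <- graph$n_states
  ag$w <- matrix(0, n, graph$n_actions)
  ag$e <- matrix(0, n, graph$n_actions)
  ag$M <- identity_sr(n)
  ag$Rhat <- numeric(n)
  ag$omega_mf <- config$omega_mf0
  ag$omega_sr <- config$omega_sr0
  ag$bounds <- config$psr_bounds
  ag$psr <- .init_psr(config)
  class(ag) <- "dual_agent"
  ag
}

#' Clamp an agent's SR influence (lesion / inactivation)
#'
#' @param ag a `"dual_agent"`.
#' @param bounds new `[psr_min, psr_max]` interval; the current influence is
#'   clipped into it immediately.
#' @return The agent, invisibly.
#' @export
set_psr_bounds <- function(ag, bounds) {
  ag$bounds <- bounds
  ag$psr <- clip(ag$psr, bounds[1], bounds[2])
  invisible(ag)
}

#' Snapshot an agent
#'
#' Deep copy of the learned state, so probes and counterfactuals can run
#' without disturbing training.
#'
#' @param ag a `"dual_agent"`.
#' @return An independent copy.
#' @export
clone_agent <- function(ag) {
  cp <- new.env(parent = emptyenv())
  for (nm in ls(ag, all.names = TRUE)) assign(nm, get(nm, envir = ag), envir = cp)
  class(cp) <- "dual_agent"
  cp
}

#' Combine the two systems' action values
#'
#' `Q_net = P_SR * Q_HPC + (1 - P_SR) * Q_DLS`: the arbitrator averages the
#' values, not the actions.
#'
#' @param q_hpc,q_dls action-value vectors over the same action set.
#' @param psr proportion of SR influence in `[0, 1]`.
#' @return Combined action-value vector.
#' @export
combined_q <- function(q_hpc, q_dls, psr) {
  if (length(q_hpc) != length(q_dls)) stop("mismatched action sets")
  psr * q_hpc + (1 - psr) * q_dls
}

#' Softmax action selection
#'
#' Draws an action with probability proportional to `exp(beta * Q)`;
#' `beta = Inf` gives a deterministic argmax with uniform tie-breaking.
#'
#' @param q finite action-value vector.
#' @param beta inverse temperature (> 0, possibly `Inf`).
#' @return Chosen action index.
#' @export
select_action <- function(q, beta) {
  if (!length(q)) stop("empty action set")
  if (any(!is.finite(q))) stop("action values must be finite")
  if (is.infinite(beta)) {
    best <- which(q == max(q))
    return(if (length(best) == 1L) best else sample(best, 1L))
  }
  sample.int(length(q), 1L, prob = softmax_probs(q, beta))
}

# -- trial loops --------------------------------------------------------------

#' Run one trial
#'
#' Runs the agent in its environment until a terminal state or the step cap.
#' Every step both systems' action values are combined by the current SR
#' influence, an action is drawn by softmax, and (when `learn = TRUE`) the
#' striatal traces and weights, the SR (or successor features) and reward
#' representation, both prediction-error averages and the influence
#' proportion are updated. Eligibility traces reset at trial start.
#'
#' @param ag a `"dual_agent"`.
#' @param env an `"arena"` (defaults to the agent's bound arena) or, for
#'   graph agents, ignored (the agent carries its drifting graph).
#' @param learn update learned state? Probe trials use `FALSE`.
#' @param start optional start pose `list(state, heading)` overriding the
#'   arena's (cycled) start poses.
#' @param max_steps trial step cap; default from the configuration.
#' @return A `"trial_record"` list: `steps`, `rewarded`, `capped`, and
#'   per-step vectors `states` (visited, including start), `actions`,
#'   `rewards`, `psr`, `abs_dr`, `abs_dm`; graph trials additionally report
#'   `choice1`, `state2`, `common`.
#' @export
run_trial <- function(ag, env = NULL, learn = TRUE, start = NULL,
                      max_steps = ag$cfg$max_steps) {
  if (ag$type == "graph") {
    .run_graph_trial(ag, learn)
  } else {
    if (is.null(env)) env <- ag$arena
    .run_spatial_trial(ag, env, learn, start, max_steps)
  }
}

.run_spatial_trial <- function(ag, arena, learn, start, max_steps) {
  cfg <- ag$cfg
  if (is.null(start)) start <- arena$start_poses[[1]]
  s <- start$state; h <- start$heading
  ag$e[] <- 0
  sf <- ag$hpc_type == "sf"
  gamma <- cfg$gamma
  states <- integer(max_steps + 1L); states[1L] <- s
  actions <- integer(max_steps); rewards <- numeric(max_steps)
  psr_tr <- numeric(max_steps); adr <- numeric(max_steps); adm <- numeric(max_steps)
  n <- 0L; rewarded <- FALSE; terminal <- FALSE
  allo <- 1:8
  while (n < max_steps && !terminal) {
    f <- ag$lc_tabs[[h]][s, ]
    qd_ego <- drop(crossprod(ag$w, f))
    qd_allo <- qd_ego[((allo - h) %% 8L) + 1L]
    ns8 <- arena$adj[s, ]
    if (sf) {
      v_ns <- drop((ag$pcmap[ns8, , drop = FALSE] %*% ag$W) %*% ag$u)
      r_s <- sum(ag$pcmap[s, ] * ag$u)
    } else {
      v_ns <- drop(ag$M[ns8, , drop = FALSE] %*% ag$Rhat)
      r_s <- ag$Rhat[s]
    }
    qh <- r_s + gamma * v_ns
    qnet <- ag$psr * qh + (1 - ag$psr) * qd_allo
    # blocked moves (clipped no-ops) are excluded from selection: leaving
    # them selectable lets the model-free bootstrap inflate their value
    valid <- which(ns8 != s)
    if (!length(valid)) valid <- 1:8
    a <- valid[select_action(qnet[valid], cfg$beta_softmax)]
    tr <- arena_step(arena, s, a)
    s2 <- tr$next_state; r <- tr$reward; terminal <- tr$terminal
    h2 <- a
    n <- n + 1L
    states[n + 1L] <- s2; actions[n] <- a; rewards[n] <- r
    if (learn) {
      # striatal: Q(lambda) over egocentric actions
      eg <- ((a - h) %% 8L) + 1L
      # bootstrap clipped to the attainable value range [0, delta_max]:
      # rewards are episodic Bernoulli(<= delta_max), so true Q lies there;
      # unclipped, off-policy Q(lambda) over overlapping features inflates
      q_next_max <- if (terminal) 0 else {
        q2 <- drop(crossprod(ag$w, ag$lc_tabs[[h2]][s2, ]))
        valid2 <- which(arena$adj[s2, ] != s2)
        if (!length(valid2)) valid2 <- 1:8
        clip(max(q2[((valid2 - h2) %% 8L) + 1L]), 0, cfg$delta_max)
      }
      dr <- r + gamma * q_next_max - qd_ego[eg]
      ag$e <- cfg$lambda * ag$e
      ag$e[, eg] <- ag$e[, eg] + f
      ag$w <- ag$w + cfg$alpha_q * dr * ag$e
      # hippocampal
      if (sf) {
        f_t <- ag$pcmap[s, ]; f_n <- ag$pcmap[s2, ]
        psi_n <- if (terminal) f_n else drop(crossprod(ag$W, f_n))
        dM <- f_t + gamma * psi_n - drop(crossprod(ag$W, f_t))
        ag$W <- ag$W + cfg$alpha_m * outer(f_t, dM) / max(1, sum(f_t^2))
        if (terminal) {
          dterm <- f_n - drop(crossprod(ag$W, f_n))
          ag$W <- ag$W + cfg$alpha_m * outer(f_n, dterm) / max(1, sum(f_n^2))
        }
        ag$u <- feature_reward_update(ag$u, f_n, r, cfg$alpha_r)
      } else {
        target <- if (terminal) {
          v <- numeric(arena$n_states); v[s2] <- 1; v
        } else ag$M[s2, ]
        dM <- gamma * target - ag$M[s, ]
        dM[s] <- dM[s] + 1
        ag$M[s, ] <- ag$M[s, ] + cfg$alpha_m * dM
        if (terminal) {
          one <- numeric(arena$n_states); one[s2] <- 1
          ag$M[s2, ] <- ag$M[s2, ] + cfg$alpha_m * (one - ag$M[s2, ])
        }
        ag$Rhat[s2] <- ag$Rhat[s2] + cfg$alpha_r * (r - ag$Rhat[s2])
      }
      # arbitration: MF reliability tracks outcome-prediction errors
      abs_dr <- clip(abs(dr), 0, cfg$delta_max)
      abs_dm <- clip(max(abs(dM)), 0, cfg$delta_max)
      if (terminal || r != 0) {
        ag$omega_mf <- ag$omega_mf + cfg$eta_mf * (abs_dr - ag$omega_mf)
      }
      ag$omega_sr <- ag$omega_sr + cfg$eta * (abs_dm - ag$omega_sr)
      rt <- transition_rates(reliability(ag$omega_mf, cfg$delta_max),
                             reliability(ag$omega_sr, cfg$delta_max),
                             cfg$A_alpha, cfg$B_alpha, cfg$A_beta, cfg$B_beta)
      ag$psr <- update_psr(ag$psr, rt$alpha, rt$beta, cfg$dt, ag$bounds)
      adr[n] <- abs_dr; adm[n] <- abs_dm
    }
    psr_tr[n] <- ag$psr
    s <- s2; h <- h2
  }
  structure(list(
    steps = n, rewarded = sum(rewards[seq_len(n)]) > 0, capped = !terminal,
    states = states[seq_len(n + 1L)], actions = actions[seq_len(n)],
    rewards = rewards[seq_len(n)], psr = psr_tr[seq_len(n)],
    abs_dr = adr[seq_len(n)], abs_dm = adm[seq_len(n)]
  ), class = "trial_record")
}

.run_graph_trial <- function(ag, learn) {
  cfg <- ag$cfg
  g <- ag$graph
  gamma <- cfg$gamma
  ag$e[] <- 0
  s <- 1L
  choice1 <- NA_integer_; common <- NA; total_r <- 0
  states <- integer(3L); states[1L] <- s
  actions <- integer(2L); rewards <- numeric(2L)
  psr_tr <- numeric(2L); adr <- numeric(2L); adm <- numeric(2L)
  n <- 0L; terminal <- FALSE
  while (!terminal) {
    f <- numeric(g$n_states); f[s] <- 1
    qd <- drop(crossprod(ag$w, f))
    V <- drop(ag$M %*% ag$Rhat)
    qh <- vapply(seq_len(g$n_actions), function(a) {
      ag$Rhat[s] + gamma * sum(g$P[s, a, ] * V)
    }, numeric(1))
    qnet <- ag$psr * qh + (1 - ag$psr) * qd
    a <- select_action(qnet, cfg$beta_softmax)
    tr <- graph_step(g, s, a)
    s2 <- tr$next_state; r <- tr$reward; terminal <- tr$terminal
    if (s == 1L) { choice1 <- a; common <- tr$common }
    n <- n + 1L
    states[n + 1L] <- s2; actions[n] <- a; rewards[n] <- r
    total_r <- total_r + r
    if (learn) {
      q_next_max <- if (terminal) 0 else {
        f2 <- numeric(g$n_states); f2[s2] <- 1
        clip(max(crossprod(ag$w, f2)), 0, cfg$delta_max)
      }
      dr <- r + gamma * q_next_max - qd[a]
      ag$e <- cfg$lambda * ag$e
      ag$e[, a] <- ag$e[, a] + f
      ag$w <- ag$w + cfg$alpha_q * dr * ag$e
      target <- if (terminal) {
        v <- numeric(g$n_states); v[s2] <- 1; v
      } else ag$M[s2, ]
      dM <- gamma * target - ag$M[s, ]
      dM[s] <- dM[s] + 1
      ag$M[s, ] <- ag$M[s, ] + cfg$alpha_m * dM
      if (terminal) {
        one <- numeric(g$n_states); one[s2] <- 1
        ag$M[s2, ] <- ag$M[s2, ] + cfg$alpha_m * (one - ag$M[s2, ])
      }
      ag$Rhat[s2] <- ag$Rhat[s2] + cfg$alpha_r * (r - ag$Rhat[s2])
      abs_dr <- clip(abs(dr), 0, cfg$delta_max)
      abs_dm <- clip(max(abs(dM)), 0, cfg$delta_max)
      if (terminal || r != 0) {
        ag$omega_mf <- ag$omega_mf + cfg$eta_mf * (abs_dr - ag$omega_mf)
      }
      ag$omega_sr <- ag$omega_sr + cfg$eta * (abs_dm - ag$omega_sr)
      rt <- transition_rates(reliability(ag$omega_mf, cfg$delta_max),
                             reliability(ag$omega_sr, cfg$delta_max),
                             cfg$A_alpha, cfg$B_alpha, cfg$A_beta, cfg$B_beta)
      ag$psr <- update_psr(ag$psr, rt$alpha, rt$beta, cfg$dt, ag$bounds)
      adr[n] <- abs_dr; adm[n] <- abs_dm
    }
    psr_tr[n] <- ag$psr
    s <- s2
  }
  if (learn) ag$graph <- advance_reward_probs(g)
  structure(list(
    steps = n, rewarded = total_r > 0, capped = FALSE,
    states = states[seq_len(n + 1L)], actions = actions[seq_len(n)],
    rewards = rewards[seq_len(n)], psr = psr_tr[seq_len(n)],
    abs_dr = adr[seq_len(n)], abs_dm = adm[seq_len(n)],
    choice1 = choice1, state2 = states[2L], common = common
  ), class = "trial_record")
}

#' Net value map of a spatial agent
#'
#' The combined state-value surface `V_net = P_SR * V_HPC + (1 - P_SR) *
#' V_DLS`, where `V_DLS(s)` is the maximum striatal action value over
#' headings and egocentric actions at `s`. Used for the place-memory
#' analysis (argmax location at session start).
#'
#' @param ag a spatial `"dual_agent"`.
#' @return `list(v, argmax, argmax_xy)`.
#' @export
value_map <- function(ag) {
  stopifnot(ag$type == "spatial")
  v_hpc_vec <- if (ag$hpc_type == "sf") {
    drop((ag$pcmap %*% ag$W) %*% ag$u)
  } else {
    drop(ag$M %*% ag$Rhat)
  }
  v_dls <- rep(-Inf, ag$arena$n_states)
  for (h in 1:8) {
    q <- ag$lc_tabs[[h]] %*% ag$w
    v_dls <- pmax(v_dls, apply(q, 1, max))
  }
  v <- ag$psr * v_hpc_vec + (1 - ag$psr) * v_dls
  am <- which.max(v)
  list(v = v, argmax = am, argmax_xy = ag$arena$coords[am, ])
}

#' Run a protocol for several independently seeded agents
#'
#' Thin aggregation wrapper: draws one sub-seed per agent from `seed`, calls
#' `fn(agent_index, agent_seed)` and collects the results in a list.
#'
#' @param n_agents number of agents (0 gives an empty result).
#' @param seed integer base seed.
#' @param fn function of `(i, seed_i)` running one agent.
#' @return List of per-agent results.
#' @export
run_agents <- function(n_agents, seed, fn) {
  if (n_agents == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_agents)
  lapply(seq_len(n_agents), function(i) {
    set.seed(seeds[i])
    fn(i, seeds[i])
  })
}

#' @export
print.dual_agent <- function(x, ...) {
  cat("<dual_agent:", x$type, "/", x$hpc_type, "> P_SR =",
      signif(x$psr, 3), " bounds [", x$bounds[1], ",", x$bounds[2], "]\n")
  invisible(x)
}
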