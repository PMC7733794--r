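# Two-step task protocol, stay-probability and model-based-index analyses,
# and the cross-task correlation study.

#' Two-step decision-task protocol
#'
#' Each agent runs `n_trials` trials of the two-step task. Model arms:
#' `"dls_only"` clamps the SR influence to 0 (pure model-free), `"hpc_only"`
#' to 1 (pure SR), `"full"` leaves arbitration free.
#'
#' @param n_agents number of agents.
#' @param n_trials trials per agent.
#' @param model `"full"`, `"dls_only"` or `"hpc_only"`.
#' @param config an [agent_config()]; the default lowers the softmax inverse
#'   temperature to 8, matched to the discrete task's value scale so that
#'   choice probabilities span the behaviorally observed range rather than
#'   saturating.
#' @param seed integer seed.
#' @param variant task-graph variant, see [build_task_graph()].
#' @return A `data.frame` with one row per trial: `agent`, `trial`,
#'   `choice1`, `common`, `reward`.
#' @export
run_two_step <- function(n_agents = 20, n_trials = 200,
                         model = c("full", "dls_only", "hpc_only"),
                         config = agent_config(beta_softmax = 8), seed = 1,
                         variant = "daw_two_step") {
  model <- match.arg(model)
  bounds <- switch(model, full = config$psr_bounds,
                   dls_only = c(0, 0), hpc_only = c(1, 1))
  res <- run_agents(n_agents, seed, function(i, s) {
    .two_step_one_agent(i, n_trials, config, bounds, variant)
  })
  do.call(rbind, res)
}

.two_step_one_agent <- function(i, n_trials, config, bounds, variant) {
  graph <- build_task_graph(variant)
  ag <- make_graph_agent(graph, config)
  set_psr_bounds(ag, bounds)
  choice1 <- integer(n_trials); common <- logical(n_trials)
  reward <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    rec <- run_trial(ag)
    choice1[t] <- rec$choice1
    common[t] <- rec$common
    reward[t] <- as.integer(rec$rewarded)
  }
  data.frame(agent = i, trial = seq_len(n_trials), choice1 = choice1,
             common = common, reward = reward)
}

#' Stay probabilities by previous reward and transition type
#'
#' For every pair of consecutive trials within an agent, whether the
#' first-stage choice was repeated, stratified by the previous trial's
#' reward (rewarded/unrewarded) and transition type (common/rare).
#'
#' @param records the `data.frame` from [run_two_step()].
#' @return A list of class `"stay_table"`: `prob` (2 x 2 matrix, rows
#'   rewarded/unrewarded, columns common/rare; `NA` where no trials fall in
#'   a cell) and `n` (pair counts).
#' @export
stay_probabilities <- function(records) {
  prob <- matrix(NA_real_, 2, 2,
                 dimnames = list(c("rewarded", "unrewarded"),
                                 c("common", "rare")))
  n <- matrix(0L, 2, 2, dimnames = dimnames(prob))
  stays <- matrix(0L, 2, 2)
  for (a in unique(records$agent)) {
    d <- records[records$agent == a, ]
    if (nrow(d) < 2) next
    idx <- 2:nrow(d)
    stay <- d$choice1[idx] == d$choice1[idx - 1]
    ri <- ifelse(d$reward[idx - 1] == 1, 1L, 2L)
    ci <- ifelse(d$common[idx - 1], 1L, 2L)
    for (k in seq_along(stay)) {
      n[ri[k], ci[k]] <- n[ri[k], ci[k]] + 1L
      stays[ri[k], ci[k]] <- stays[ri[k], ci[k]] + as.integer(stay[k])
    }
  }
  prob[n > 0] <- stays[n > 0] / n[n > 0]
  structure(list(prob = prob, n = n), class = "stay_table")
}

#' @export
print.stay_table <- function(x, ...) {
  cat("Stay probabilities (previous trial):\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' Per-agent model-based planning index
#'
#' Logistic regression of staying with the previous first-stage choice on
#' the previous trial's reward, transition type and their interaction (all
#' coded +/-1). The model-based index is the interaction coefficient:
#' model-free behavior shows a reward main effect only, model-based
#' behavior shows a positive interaction (rewarded rare transitions promote
#' switching). The fit is stabilized against separation by augmenting each
#' design cell with one half-weight stay and one half-weight switch
#' pseudo-observation (a light ridge toward 0), so strongly perseverative
#' agents yield an index near 0 rather than an unbounded estimate.
#'
#' @param records [run_two_step()] records for one or more agents.
#' @param min_trials minimum usable trial pairs per agent.
#' @return A `data.frame` with `agent`, `mb_index` (interaction
#'   coefficient), `reward_effect` (main effect). Agents with too few
#'   trials or degenerate fits get `NA`.
#' @export
mb_index <- function(records, min_trials = 30) {
  cells <- expand.grid(rew = c(-1, 1), trans = c(-1, 1))
  augment <- rbind(cbind(stay = 1, cells), cbind(stay = 0, cells))
  out <- lapply(unique(records$agent), function(a) {
    d <- records[records$agent == a, ]
    res <- data.frame(agent = a, mb_index = NA_real_, reward_effect = NA_real_)
    if (nrow(d) < min_trials + 1) return(res)
    idx <- 2:nrow(d)
    df <- data.frame(
      stay = as.integer(d$choice1[idx] == d$choice1[idx - 1]),
      rew = ifelse(d$reward[idx - 1] == 1, 1, -1),
      trans = ifelse(d$common[idx - 1], 1, -1)
    )
    df <- rbind(df, augment)
    w <- c(rep(1, nrow(df) - nrow(augment)), rep(0.5, nrow(augment)))
    fit <- tryCatch(
      suppressWarnings(stats::glm(stay ~ rew * trans, family = stats::binomial(),
                                  weights = w, data = df)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(res)
    co <- stats::coef(fit)
    if (any(!is.finite(co)) || any(abs(co) > 10)) return(res)
    res$mb_index <- unname(co["rew:trans"])
    res$reward_effect <- unname(co["rew"])
    res
  })
  do.call(rbind, out)
}

# -- correlation study --------------------------------------------------------

#' Fisher z statistic of a correlation
#'
#' `z = atanh(r) * sqrt(n - 3)`, two-sided normal p value.
#'
#' @param r sample correlation (|r| < 1).
#' @param n sample size (>= 4).
#' @return `list(z, p)`.
#' @export
correlation_z <- function(r, n) {
  if (abs(r) >= 1 || n < 4) stop("need |r| < 1 and n >= 4")
  z <- atanh(r) * sqrt(n - 3)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two independent correlations (Fisher z difference)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a normal
#' p value, two-sided or one-sided (`"greater"`: r1 > r2 predicted in
#' advance).
#'
#' @param r1,r2 sample correlations (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return `list(z, p)`.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  list(z = z, p = p)
}

#' Sample heterogeneous arbitration parameters
#'
#' Draws, per agent, the parameters governing the hippocampal-striatal
#' tradeoff from uniform ranges: the amplitude of the transition rate
#' toward the SR system (`A_alpha`, a shared "hippocampal influence" trait
#' expressed in every task), the steepness of both arbitration transition
#' rates, and the softmax inverse temperature. Uses the current RNG state.
#'
#' @param ranges named list of `c(lo, hi)` ranges for `A_alpha`, `B_alpha`,
#'   `B_beta` and `beta_softmax`.
#' @param base an [agent_config()] supplying all other parameters.
#' @param log_scale parameters drawn log-uniformly (scale parameters, so
#'   both strongly hippocampal and strongly striatal regimes are sampled).
#' @return An [agent_config()] with the sampled values.
#' @export
sample_agent_config <- function(ranges = list(A_alpha = c(0.02, 3),
                                              B_alpha = c(2, 5),
                                              B_beta = c(0.25, 3),
                                              beta_softmax = c(7.5, 8.5)),
                                base = agent_config(),
                                log_scale = "A_alpha") {
  for (nm in names(ranges)) {
    base[[nm]] <- if (nm %in% log_scale) {
      exp(stats::runif(1, log(ranges[[nm]][1]), log(ranges[[nm]][2])))
    } else {
      stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
    }
  }
  base
}

#' Cross-task correlation study
#'
#' Samples `n_agents` intact agents with heterogeneous arbitration
#' parameters and `n_agents` agents with a partially lesioned hippocampal
#' component (upper clamp on the SR influence). Each agent performs the
#' two-step task (model-based index from the stay logistic regression) and
#' the adapted water-maze protocol (place-memory score: mean distance from
#' the previous platform to the net value-function argmax at next-session
#' start). Reports, per arm, the correlation between the model-based index
#' and place-memory *strength* (the negated distance score), its Fisher z,
#' and the between-arm comparison.
#'
#' @param n_agents agents per arm.
#' @param seed integer seed.
#' @param n_trials_two_step trials on the two-step task.
#' @param grid_n,n_sessions,max_steps water-maze settings.
#' @param lesion_bounds SR-influence clamp of the lesioned arm.
#' @param ranges parameter ranges, see [sample_agent_config()].
#' @param base an [agent_config()] for the non-sampled parameters.
#' @return A list with the per-agent `scores` data frame, per-arm
#'   correlations `r_intact`, `r_lesioned`, their z/p statistics, the
#'   between-arm comparison `z_diff`/`p_diff`, and the effective ns.
#' @export
run_correlation_study <- function(n_agents = 20, seed = 1,
                                  n_trials_two_step = 1200, grid_n = 15,
                                  n_sessions = 11, max_steps = 250,
                                  lesion_bounds = c(0, 0.02),
                                  ranges = list(A_alpha = c(0.02, 3),
                                                B_alpha = c(2, 5),
                                                B_beta = c(0.25, 3),
                                                beta_softmax = c(7.5, 8.5)),
                                  base = agent_config()) {
  run_arm <- function(arm, arm_seed, bounds) {
    res <- run_agents(n_agents, arm_seed, function(i, s) {
      cfg <- sample_agent_config(ranges, base)
      ts <- .two_step_one_agent(i, n_trials_two_step, cfg, bounds, "daw_two_step")
      mb <- mb_index(ts)$mb_index
      pe <- .pearce_one_agent(cfg, grid_n = grid_n, n_sessions = n_sessions,
                              max_steps = max_steps, lesion_bounds = bounds)
      data.frame(arm = arm, agent = i, mb_index = mb,
                 place_memory_dist = place_memory_score(pe$mem_dist))
    })
    do.call(rbind, res)
  }
  set.seed(seed)
  arm_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  scores <- rbind(run_arm("intact", arm_seeds[1], base$psr_bounds),
                  run_arm("lesioned", arm_seeds[2], lesion_bounds))
  arm_stats <- function(arm) {
    d <- scores[scores$arm == arm & stats::complete.cases(scores), ]
    r <- stats::cor(d$mb_index, -d$place_memory_dist)
    c(list(r = r, n = nrow(d)), correlation_z(r, nrow(d)))
  }
  it <- arm_stats("intact"); le <- arm_stats("lesioned")
  cmp <- compare_correlations(it$r, it$n, le$r, le$n)
  list(scores = scores,
       r_intact = it$r, z_intact = it$z, p_intact = it$p, n_intact = it$n,
       r_lesioned = le$r, z_lesioned = le$z, p_lesioned = le$p, n_lesioned = le$n,
       z_diff = cmp$z, p_diff = cmp$p)
}

#' Run a named protocol
#'
#' Dispatch wrapper over the protocol functions, mainly for the command-line
#' runner.
#'
#' @param protocol one of `"pearce"`, `"plus_maze"`, `"blocking_landmark"`,
#'   `"blocking_boundary"`, `"two_step_daw"`, `"two_step_deterministic"`,
#'   `"correlation_study"`.
#' @param ... passed to the protocol function.
#' @return The protocol function's value.
#' @export
run_experiment <- function(protocol = c("pearce", "plus_maze",
                                        "blocking_landmark", "blocking_boundary",
                                        "two_step_daw", "two_step_deterministic",
                                        "correlation_study"), ...) {
  protocol <- match.arg(protocol)
  switch(protocol,
         pearce = run_pearce(...),
         plus_maze = run_plus_maze(...),
         blocking_landmark = run_blocking("landmark", ...),
         blocking_boundary = run_blocking("boundary", ...),
         two_step_daw = run_two_step(variant = "daw_two_step", ...),
         two_step_deterministic = run_two_step(variant = "deterministic_two_step", ...),
         correlation_study = run_correlation_study(...))
}
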