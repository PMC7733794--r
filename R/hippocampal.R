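# Hippocampal learner: the successor representation (SR), tabular over
# discrete states or as successor features (SF) over place-cell populations,
# plus the learned reward representation that value factorizes over.

#' Random-walk successor representation
#'
#' Closed form `M = (I - gamma * T)^{-1}` for a transition matrix `T`; the
#' prior an agent acquires by freely exploring an arena before the task.
#'
#' @param T row-stochastic transition matrix, or an `"arena"` (the uniform
#'   8-direction random walk is used).
#' @param gamma discount factor in `[0, 1)`.
#' @return The SR matrix `M`.
#' @export
#' @examples
#' T <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
#' random_walk_sr(T, 0.5)
random_walk_sr <- function(T, gamma) {
  if (inherits(T, "arena")) T <- rw_transition_matrix(T)
  stopifnot(gamma >= 0, gamma < 1)
  solve(diag(nrow(T)) - gamma * T)
}

#' Identity successor representation
#'
#' Encodes no knowledge beyond every state predicting itself; the
#' initialization used for task graphs that the agent has not explored.
#'
#' @param n_states number of states.
#' @return The identity matrix.
#' @export
identity_sr <- function(n_states) {
  stopifnot(n_states >= 1)
  diag(n_states)
}

#' Temporal-difference update of the SR
#'
#' Successor prediction error over all states s':
#' `delta_M(s') = I(s = s') + gamma * M(s_next, s') - M(s, s')`, and row `s`
#' moves by `alpha_m * delta_M`. At a terminal transition the successor row
#' is the absorbing state's one-hot (the terminal state predicts only its
#' own occupancy), which preserves the goal state's discounted occupancy in
#' `M`; the absorbing state's own row is additionally relaxed toward that
#' one-hot, since the experienced episode ends there (otherwise a
#' preexposure prior's self-occupancy at the goal is never corrected).
#'
#' @param M SR matrix.
#' @param s,s_next state indices of the transition.
#' @param terminal logical: does the transition end the episode?
#' @param alpha_m learning rate.
#' @param gamma discount factor.
#' @return `list(M, delta)` with the updated matrix and the SPE vector.
#' @export
sr_td_update <- function(M, s, s_next, terminal, alpha_m, gamma) {
  if (terminal) {
    target <- numeric(ncol(M)); target[s_next] <- 1
  } else {
    target <- M[s_next, ]
  }
  delta <- gamma * target - M[s, ]
  delta[s] <- delta[s] + 1
  M[s, ] <- M[s, ] + alpha_m * delta
  if (terminal) {
    one <- numeric(ncol(M)); one[s_next] <- 1
    M[s_next, ] <- M[s_next, ] + alpha_m * (one - M[s_next, ])
  }
  list(M = M, delta = delta)
}

#' Delta-rule update of the reward vector
#'
#' `R(s) <- R(s) + alpha_r * (r - R(s))`; other entries unchanged. Visiting
#' a formerly rewarded state without reward therefore unlearns its entry.
#'
#' @param R reward vector.
#' @param s state where the reward (or its absence) was experienced.
#' @param r observed reward.
#' @param alpha_r learning rate.
#' @return Updated reward vector.
#' @export
reward_update <- function(R, s, r, alpha_r) {
  R[s] <- R[s] + alpha_r * (r - R[s])
  R
}

#' Hippocampal state values
#'
#' `V(s) = sum_s' M(s, s') R(s')`: editing `R` at one state instantly
#' revalues every predecessor state through the SR.
#'
#' @param M SR matrix.
#' @param R reward vector.
#' @return State-value vector.
#' @export
v_hpc <- function(M, R) {
  if (ncol(M) != length(R)) stop("M/R shape mismatch")
  drop(M %*% R)
}

#' Hippocampal action values by one-step lookahead
#'
#' `Q(s, a) = r(s) + gamma * E[V(s') | s, a]` under a one-step model of the
#' environment (deterministic grid adjacency in arenas; the true transition
#' probabilities in task graphs).
#'
#' @param r_s (estimated) reward at the current state.
#' @param next_values for each action, either the successor's value
#'   (deterministic model: a numeric vector) or the expectation
#'   `sum_s' P(s'|s,a) V(s')` already taken.
#' @param gamma discount factor.
#' @return Action-value vector.
#' @export
q_hpc <- function(r_s, next_values, gamma) {
  r_s + gamma * next_values
}

# -- successor features -------------------------------------------------------

#' Estimated successor features
#'
#' Linear function approximation `psi(s) = W^T f(s)`; `W[i, j]` encodes how
#' much feature i predicts the discounted future activity of feature j.
#'
#' @param W SF weight matrix (`n_features` x `n_features`).
#' @param f feature vector.
#' @return Successor-feature vector `psi`.
#' @export
sf_estimate <- function(W, f) {
  if (length(f) != nrow(W)) stop("feature/weight shape mismatch")
  drop(crossprod(W, f))
}

#' Temporal-difference update of the successor-feature weights
#'
#' SF prediction error `delta = f_t + gamma * W^T f_next - W^T f_t`, applied
#' by the normalized outer-product gradient rule
#' `W <- W + alpha_m * f_t delta^T / max(1, f_t^T f_t)` (the normalization
#' keeps the effective step bounded for dense rate vectors). At a terminal
#' transition the bootstrap successor features are the terminal state's own
#' features (`psi(terminal) = f_next`). With one-hot features this reduces
#' exactly to [sr_td_update()].
#'
#' @param W SF weight matrix.
#' @param f_t,f_next feature vectors at the current and successor states.
#' @param terminal logical terminal flag.
#' @param alpha_m learning rate.
#' @param gamma discount factor.
#' @return `list(W, delta)`.
#' @export
sf_td_update <- function(W, f_t, f_next, terminal, alpha_m, gamma) {
  psi_next <- if (terminal) f_next else drop(crossprod(W, f_next))
  delta <- f_t + gamma * psi_next - drop(crossprod(W, f_t))
  W <- W + alpha_m * outer(f_t, delta) / max(1, sum(f_t^2))
  if (terminal) {
    # absorbing state: its own successor features relax toward its features
    dterm <- f_next - drop(crossprod(W, f_next))
    W <- W + alpha_m * outer(f_next, dterm) / max(1, sum(f_next^2))
  }
  list(W = W, delta = delta)
}

#' Delta-rule update of the feature-reward weights
#'
#' Least-mean-squares step moving the predicted reward `f^T u` toward the
#' observed reward under the current features:
#' `u <- u + alpha_r * (r - f^T u) * f / max(1, f^T f)` (the normalization
#' keeps the effective step bounded for dense rate vectors; with one-hot
#' features this reduces exactly to [reward_update()]).
#'
#' @param u feature-reward weight vector.
#' @param f feature vector at the rewarded (or unrewarded) state.
#' @param r observed reward.
#' @param alpha_r learning rate.
#' @return Updated `u`.
#' @export
feature_reward_update <- function(u, f, r, alpha_r) {
  ff <- sum(f^2)
  if (ff < 1e-12) return(u)
  u + alpha_r * (r - sum(f * u)) * f / max(1, ff)
}

#' Value from successor features
#'
#' `V(s) = psi(s)^T u`.
#'
#' @param psi successor-feature vector.
#' @param u feature-reward weights.
#' @return Scalar value.
#' @export
v_sf <- function(psi, u) {
  sum(psi * u)
}

#' Devalue the hippocampal reward representation
#'
#' Scales the reward vector `R` (tabular) or reward weights `u` (successor
#' features) by `factor`; striatal weights are untouched, capturing the
#' model-free system's insensitivity to outcome devaluation.
#'
#' @param R reward vector or feature-reward weights.
#' @param factor scaling in `[0, 1]` (0 = full devaluation).
#' @return The scaled representation.
#' @export
devalue <- function(R, factor) {
  if (factor < 0 || factor > 1) stop("devaluation factor must be in [0, 1]")
  R * factor
}
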