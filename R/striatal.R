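# Dorsolateral-striatal model-free learner: linear Q-learning over sensory
# features with eligibility traces. Weights and traces are n_features x
# n_actions; in spatial tasks the action axis is egocentric (turns relative
# to heading), in graph tasks it coincides with the task actions.

#' Create a striatal learner state
#'
#' @param n_features number of sensory input cells.
#' @param n_actions number of actions.
#' @param alpha_q Q learning rate.
#' @param lambda eligibility-trace decay in `[0, 1]`.
#' @param gamma discount factor in `[0, 1)`.
#' @return A list of class `"striatal_state"` with zero-initialized weights
#'   `w` and traces `e`.
#' @export
striatal_state <- function(n_features, n_actions, alpha_q = 0.1,
                           lambda = 0.9, gamma = 0.9) {
  stopifnot(lambda >= 0, lambda <= 1, gamma >= 0, gamma < 1)
  structure(list(
    w = matrix(0, n_features, n_actions),
    e = matrix(0, n_features, n_actions),
    alpha_q = alpha_q, lambda = lambda, gamma = gamma
  ), class = "striatal_state")
}

#' Striatal action values
#'
#' Linear all-to-all readout: `Q(s, a) = sum_i w[i, a] * f[i]`.
#'
#' @param w weight matrix (`n_features` x `n_actions`) or a
#'   [striatal_state()].
#' @param f feature vector.
#' @return Action-value vector of length `n_actions`.
#' @export
q_dls <- function(w, f) {
  if (inherits(w, "striatal_state")) w <- w$w
  if (length(f) != nrow(w)) stop("feature/weight shape mismatch")
  drop(crossprod(w, f))
}

#' Temporal-difference reward-prediction error
#'
#' `delta_r = r + gamma * max_a' Q(s', a') - Q(s, a)`; pass
#' `q_next_max = 0` at terminal states.
#'
#' @param r reward received on the transition.
#' @param q_sa value of the taken action at the previous state.
#' @param q_next_max maximum action value at the successor state (0 if
#'   terminal).
#' @param gamma discount factor.
#' @return Scalar prediction error.
#' @export
rpe <- function(r, q_sa, q_next_max, gamma) {
  r + gamma * q_next_max - q_sa
}

#' Update eligibility traces
#'
#' All traces decay by `lambda`; the chosen action's traces gain the current
#' feature vector: `e[, a] <- e[, a] + f`. (Only the executed action's
#' synapses are strengthened.)
#'
#' @param e trace matrix.
#' @param f feature vector.
#' @param action index of the chosen action (striatal frame).
#' @param lambda trace decay.
#' @return Updated trace matrix.
#' @export
update_traces <- function(e, f, action, lambda) {
  e <- lambda * e
  e[, action] <- e[, action] + f
  e
}

#' Apply a reward-prediction error to the weights
#'
#' `delta_w[i, a] = alpha_q * delta_r * e[i, a]` for all synapses.
#'
#' @param w weight matrix.
#' @param e trace matrix.
#' @param alpha_q learning rate.
#' @param delta_r scalar reward-prediction error.
#' @return Updated weight matrix.
#' @export
update_weights <- function(w, e, alpha_q, delta_r) {
  w + alpha_q * delta_r * e
}

#' Reset eligibility traces between trials
#'
#' @param state a [striatal_state()].
#' @return The state with zeroed traces; weights untouched.
#' @export
reset_traces <- function(state) {
  state$e[] <- 0
  state
}
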