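# Reliability-based arbitration between the hippocampal (SR) and striatal
# (model-free) systems. Each system's recent average absolute prediction
# error Omega yields a reliability chi; reliabilities set the transition
# rates of a push-pull dynamics on P_SR, the proportion of influence of the
# SR system on the combined action values. Lesions are clamps on P_SR.

#' Update the running average of absolute prediction errors
#'
#' Pearce-Hall-like rule `Omega <- Omega + eta * (|delta| - Omega)`.
#'
#' @param omega current average.
#' @param abs_delta absolute prediction error (>= 0).
#' @param eta learning rate.
#' @return Updated average.
#' @export
update_omega <- function(omega, abs_delta, eta) {
  if (abs_delta < 0) stop("absolute prediction error must be nonnegative")
  omega + eta * (abs_delta - omega)
}

#' Reliability of a system
#'
#' `chi = (delta_max - min(Omega, delta_max)) / delta_max`: 1 when recent
#' prediction errors vanish, 0 when they reach the error bound.
#'
#' @param omega average absolute prediction error.
#' @param delta_max prediction-error upper bound (> 0; 1 by convention).
#' @return Reliability in `[0, 1]`.
#' @export
reliability <- function(omega, delta_max = 1) {
  if (delta_max <= 0) stop("delta_max must be positive")
  (delta_max - pmin(omega, delta_max)) / delta_max
}

#' Arbitration transition rates
#'
#' Logistic functions of the reliabilities:
#' `alpha = A_alpha / (1 + exp(B_alpha * chi_mf))` (model-free to SR) and
#' `beta = A_beta / (1 + exp(B_beta * chi_sr))` (SR to model-free). With the
#' default steep `B_alpha`, transitions toward the SR system are sharply
#' suppressed once the model-free system is reliable, expressing a bias
#' toward the computationally cheaper system.
#'
#' @param chi_mf,chi_sr system reliabilities in `[0, 1]`.
#' @param A_alpha,B_alpha,A_beta,B_beta amplitude and steepness parameters
#'   (`A > 0`).
#' @return `list(alpha, beta)`.
#' @export
transition_rates <- function(chi_mf, chi_sr, A_alpha = 1, B_alpha = 6,
                             A_beta = 0.3, B_beta = 1) {
  if (A_alpha <= 0 || A_beta <= 0) stop("A parameters must be positive")
  list(alpha = A_alpha / (1 + exp(B_alpha * chi_mf)),
       beta = A_beta / (1 + exp(B_beta * chi_sr)))
}

#' Step the influence dynamics
#'
#' `P_SR <- P_SR + dt * (alpha * (1 - P_SR) - beta * P_SR)`, then clamped to
#' the lesion interval. The equilibrium is `alpha / (alpha + beta)`.
#'
#' @param psr current proportion of SR influence.
#' @param alpha,beta transition rates.
#' @param dt time step (1 per environment step).
#' @param bounds lesion clamp interval `[psr_min, psr_max]`.
#' @return Updated `P_SR`.
#' @export
update_psr <- function(psr, alpha, beta, dt = 1, bounds = c(0, 1)) {
  if (dt <= 0) stop("dt must be positive")
  psr <- psr + dt * (alpha * (1 - psr) - beta * psr)
  clip(psr, bounds[1], bounds[2])
}

#' Lesion a system by clamping the influence interval
#'
#' A hippocampal lesion lowers the upper clamp toward 0 (severity 1 pins
#' `P_SR = 0`, purely model-free behavior); a dorsolateral-striatal lesion
#' raises the lower clamp toward 1 symmetrically.
#'
#' @param bounds current clamp interval.
#' @param target `"HPC"` or `"DLS"`.
#' @param severity lesion severity in `[0, 1]`.
#' @return New clamp interval.
#' @export
apply_lesion <- function(bounds = c(0, 1), target = c("HPC", "DLS"),
                         severity = 1) {
  target <- match.arg(target)
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (target == "HPC") {
    bounds[2] <- min(bounds[2], 1 - severity)
    bounds[1] <- min(bounds[1], bounds[2])
  } else {
    bounds[1] <- max(bounds[1], severity)
    bounds[2] <- max(bounds[2], bounds[1])
  }
  bounds
}

#' Scalar magnitude of a successor prediction error
#'
#' Reduces the SPE vector to the bounded scalar that feeds the reliability
#' update: the maximum absolute entry, clipped to `[0, delta_max]`.
#'
#' @param delta SPE vector from [sr_td_update()] or [sf_td_update()].
#' @param delta_max error upper bound.
#' @return Scalar in `[0, delta_max]`.
#' @export
sr_spe_magnitude <- function(delta, delta_max = 1) {
  clip(max(abs(delta)), 0, delta_max)
}
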