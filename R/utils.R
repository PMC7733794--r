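# Small internal helpers shared across modules.

#' Wrap angles to [-pi, pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles wrapped into `[-pi, pi)`.
#' @keywords internal
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

#' Clip values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearer bound.
#' @keywords internal
clip <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

#' Softmax choice probabilities
#'
#' @param q numeric vector of action values (finite).
#' @param beta inverse temperature (> 0).
#' @return Probability vector summing to 1.
#' @keywords internal
softmax_probs <- function(q, beta) {
  z <- beta * (q - max(q))
  p <- exp(z)
  p / sum(p)
}

# Allocentric action conventions: 8 compass directions indexed 1..8,
# direction k has angle (k-1)*pi/4 with index 1 = east, counterclockwise.
.dir_angles <- (0:7) * pi / 4
.dir_dx <- round(cos(.dir_angles))
.dir_dy <- round(sin(.dir_angles))

#' Map between allocentric and egocentric action indices
#'
#' Egocentric actions are turns relative to the current heading: egocentric
#' index 1 is straight ahead, successive indices rotate counterclockwise in
#' 45 degree steps. With heading `h` (allocentric index of the last move),
#' egocentric action `e` executes allocentric direction `(h + e - 2) %% 8 + 1`.
#'
#' @param a allocentric action index in 1..8.
#' @param h heading index in 1..8.
#' @return `ego_from_allo`: the egocentric index of allocentric action `a`
#'   under heading `h`; `allo_from_ego` the inverse.
#' @keywords internal
ego_from_allo <- function(a, h) ((a - h) %% 8L) + 1L

#' @rdname ego_from_allo
#' @param e egocentric action index in 1..8.
#' @keywords internal
allo_from_ego <- function(e, h) ((h + e - 2L) %% 8L) + 1L
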