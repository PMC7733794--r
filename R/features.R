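# Sensory feature models.
#
# The striatal learner sees egocentric landmark-cell (LC) rates; the
# hippocampal learner sees allocentric place-cell rates driven by boundary
# vector cells (BVCs), or one-hot state vectors in nonspatial tasks. All
# rates are nonnegative; LC and BVC peak rates are normalized to 1.

#' Landmark-cell activation
#'
#' An LC is tuned to a landmark of a given identity at a preferred egocentric
#' distance `d_star` and angle `theta_star`; its rate is a bivariate Gaussian
#' (diagonal covariance) in (distance, wrapped angle), normalized to peak 1.
#' A landmark at zero distance has no defined bearing, so the angular factor
#' is 1 there.
#'
#' @param d landmark distance(s) from the agent (>= 0). A landmark at the
#'   agent's own position has no defined bearing and drives no LC (rate 0).
#' @param theta egocentric angle(s) of the landmark, radians
#'   (0 = straight ahead, positive counterclockwise).
#' @param d_star,theta_star preferred distance and egocentric angle.
#' @param sigma_d,sigma_theta tuning widths (> 0).
#' @return Firing rate(s) in `[0, 1]`.
#' @export
#' @examples
#' lc_activation(2, 0, d_star = 2, theta_star = 0)         # peak
#' lc_activation(3, 0, d_star = 2, theta_star = 0, sigma_d = 1)  # exp(-1/2)
lc_activation <- function(d, theta, d_star, theta_star,
                          sigma_d = 1, sigma_theta = 0.6) {
  if (any(sigma_d <= 0) || any(sigma_theta <= 0)) stop("tuning widths must be positive")
  if (any(d < 0)) stop("distance must be nonnegative")
  n <- max(length(d), length(theta), length(d_star), length(theta_star))
  d <- rep_len(d, n); theta <- rep_len(theta, n)
  d_star <- rep_len(d_star, n); theta_star <- rep_len(theta_star, n)
  ang <- wrap_angle(theta - theta_star)
  rate <- exp(-0.5 * (((d - d_star) / rep_len(sigma_d, n))^2 +
                        (ang / rep_len(sigma_theta, n))^2))
  rate[d < 1e-9] <- 0  # no bearing when the agent stands on the landmark
  rate
}

#' Build a landmark-cell bank
#'
#' Per landmark identity, a polar grid of preferred egocentric distances and
#' angles. Cells of one identity respond only to that landmark.
#'
#' @param identities character vector of landmark identities.
#' @param distances preferred distances (arena units = grid cells).
#' @param angles preferred egocentric angles (radians); default 8 directions.
#' @param sigma_d,sigma_theta tuning widths shared by all cells.
#' @return A `data.frame` (class `"lc_bank"`) with one row per cell.
#' @export
lc_bank <- function(identities, distances = c(1, 2.5, 4.5, 7),
                    angles = wrap_angle((0:7) * pi / 4),
                    sigma_d = 1, sigma_theta = 0.6) {
  grid <- expand.grid(theta_star = angles, d_star = distances, id = identities,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sigma_d <- rep(sigma_d, length.out = nrow(grid))
  grid$sigma_theta <- rep(sigma_theta, length.out = nrow(grid))
  structure(grid[, c("id", "d_star", "theta_star", "sigma_d", "sigma_theta")],
            class = c("lc_bank", "data.frame"))
}

#' Landmark-cell population vector at a pose
#'
#' Computes egocentric distance and bearing of every landmark from the
#' agent's position and heading and evaluates the whole LC bank. Cells whose
#' identity is absent from the scene fire 0.
#'
#' @param x,y agent position (allocentric).
#' @param heading_angle agent heading, radians (allocentric).
#' @param landmarks `data.frame(x, y, id)` of landmarks present.
#' @param bank an [lc_bank()].
#' @return Numeric feature vector of length `nrow(bank)`.
#' @export
lc_population <- function(x, y, heading_angle, landmarks, bank) {
  f <- numeric(nrow(bank))
  if (is.null(landmarks) || nrow(landmarks) == 0) return(f)
  for (k in seq_len(nrow(landmarks))) {
    rows <- which(bank$id == landmarks$id[k])
    if (!length(rows)) next
    dx <- landmarks$x[k] - x
    dy <- landmarks$y[k] - y
    d <- sqrt(dx^2 + dy^2)
    theta <- wrap_angle(atan2(dy, dx) - heading_angle)
    f[rows] <- lc_activation(d, theta, bank$d_star[rows], bank$theta_star[rows],
                             bank$sigma_d[rows], bank$sigma_theta[rows])
  }
  f
}

#' Precompute landmark-cell features over an arena
#'
#' LC vectors depend on state and heading; this tabulates them for all 8
#' headings so the agent loop is a lookup. Recompute after
#' [configure_session()] moves the landmark.
#'
#' @param arena an [build_arena()] object.
#' @param bank an [lc_bank()].
#' @return A list of 8 matrices (`n_states` x `n_cells`), one per heading.
#' @export
lc_feature_tables <- function(arena, bank) {
  lapply(1:8, function(h) {
    ha <- .dir_angles[h]
    res <- vapply(seq_len(arena$n_states), function(s) {
      lc_population(arena$coords[s, 1], arena$coords[s, 2], ha,
                    arena$landmarks, bank)
    }, numeric(nrow(bank)))
    if (is.matrix(res)) t(res) else matrix(res, ncol = max(1L, nrow(bank)))
  })
}

# -- boundary vector cells ----------------------------------------------------

#' Boundary-vector-cell activation
#'
#' A BVC is tuned to boundary surface at a preferred allocentric direction
#' `phi_star` and distance `d_star`. Each boundary segment is discretized at
#' arc step `arc_step`; a sample at distance `r` and direction `phi`
#' contributes its subtended angle (`arc_step / r`) weighted by a radial
#' Gaussian (width growing linearly with preferred distance,
#' `sigma_rad = sigma0 * (1 + d_star / beta)`) and an angular Gaussian. The
#' rate is therefore additive over disjoint segments and proportional to the
#' angle a section subtends.
#'
#' @param x,y position at which to evaluate the cell.
#' @param boundaries wall segments, matrix with columns `x1, y1, x2, y2`;
#'   `NULL` or empty gives rate 0.
#' @param d_star,phi_star preferred distance and allocentric direction.
#' @param sigma0 radial width at zero preferred distance.
#' @param beta distance constant of the radial-width growth.
#' @param sigma_ang angular tuning width (radians).
#' @param arc_step discretization step along segments (cells).
#' @return Nonnegative firing rate.
#' @export
bvc_activation <- function(x, y, boundaries, d_star, phi_star,
                           sigma0 = 0.8, beta = 10, sigma_ang = 0.25,
                           arc_step = 0.5) {
  if (is.null(boundaries) || nrow(boundaries) == 0) return(0)
  sigma_rad <- sigma0 * (1 + d_star / beta)
  rate <- 0
  for (k in seq_len(nrow(boundaries))) {
    p1 <- boundaries[k, 1:2]; p2 <- boundaries[k, 3:4]
    len <- sqrt(sum((p2 - p1)^2))
    m <- max(2L, ceiling(len / arc_step) + 1L)
    tt <- seq(0, 1, length.out = m)
    sx <- p1[1] + tt * (p2[1] - p1[1])
    sy <- p1[2] + tt * (p2[2] - p1[2])
    ds <- len / (m - 1)
    r <- pmax(sqrt((sx - x)^2 + (sy - y)^2), 1e-6)
    phi <- atan2(sy - y, sx - x)
    w <- ds / r  # subtended angle of each sample
    g <- exp(-((r - d_star)^2) / (2 * sigma_rad^2)) *
      exp(-(wrap_angle(phi - phi_star)^2) / (2 * sigma_ang^2))
    rate <- rate + sum(w * g)
  }
  rate
}

#' Build a place-cell bank from BVC inputs
#'
#' Each place cell is the thresholded sum of a small set of BVC inputs. For a
#' candidate field center, a BVC is created per reference wall, tuned to the
#' distance and allocentric direction from the center to the nearest point of
#' that wall. With `per_wall = FALSE` (square-box default) each center yields
#' one cell combining the `n_walls` nearest walls, giving a localized,
#' unimodal field. With `per_wall = TRUE` each (center, wall) pair yields a
#' cell driven by that wall alone, the configuration used by the
#' boundary-blocking protocol where walls are added and removed.
#'
#' @param centers matrix of candidate field centers (columns x, y).
#' @param walls wall segments (`x1, y1, x2, y2` columns); the full geometry
#'   the bank should cover (walls may be absent at evaluation time).
#' @param n_walls number of nearest walls combined per cell when
#'   `per_wall = FALSE`.
#' @param per_wall logical, see above.
#' @param threshold_frac threshold as a fraction of the cell's BVC drive at
#'   its own center (with all reference walls present).
#' @param ... tuning parameters passed to [bvc_activation()].
#' @return A list (class `"pc_bank"`) of place cells, each with its BVC
#'   parameter table, threshold and normalization.
#' @export
place_cell_bank <- function(centers, walls, n_walls = 2, per_wall = FALSE,
                            threshold_frac = 0.5, ...) {
  stopifnot(nrow(walls) >= 1)
  dots <- list(...)
  nearest <- function(cx, cy, seg) {
    p1 <- seg[1:2]; p2 <- seg[3:4]
    v <- p2 - p1
    tt <- clip(sum((c(cx, cy) - p1) * v) / sum(v^2), 0, 1)
    q <- p1 + tt * v
    c(d = sqrt(sum((c(cx, cy) - q)^2)), phi = atan2(q[2] - cy, q[1] - cx))
  }
  cells <- list()
  for (i in seq_len(nrow(centers))) {
    cx <- unname(centers[i, 1]); cy <- unname(centers[i, 2])
    np <- t(apply(walls, 1, function(seg) nearest(cx, cy, seg)))
    wall_sets <- if (per_wall) as.list(seq_len(nrow(walls))) else {
      list(order(np[, "d"])[seq_len(min(n_walls, nrow(walls)))]
      )
    }
    for (ws in wall_sets) {
      bvcs <- data.frame(wall = ws, d_star = pmax(np[ws, "d"], 0.5),
                         phi_star = np[ws, "phi"])
      cell <- c(list(center = c(cx, cy), bvcs = bvcs), dots)
      drive <- .pc_drive(cx, cy, walls, cell)
      if (drive <= 1e-8) next
      cell$threshold <- threshold_frac * drive
      cell$norm <- drive - cell$threshold
      cells[[length(cells) + 1L]] <- cell
    }
  }
  structure(cells, class = "pc_bank")
}

# Summed BVC drive of one place cell at (x, y); each BVC reads only its own
# reference wall so that removing a wall silences exactly its inputs.
.pc_drive <- function(x, y, walls, cell) {
  args <- cell[intersect(names(cell),
                         c("sigma0", "beta", "sigma_ang", "arc_step"))]
  drive <- 0
  for (j in seq_len(nrow(cell$bvcs))) {
    w <- cell$bvcs$wall[j]
    if (w > nrow(walls) || is.na(.wall_present(walls, w))) next
    seg <- walls[w, , drop = FALSE]
    drive <- drive + do.call(bvc_activation,
                             c(list(x = x, y = y, boundaries = seg,
                                    d_star = cell$bvcs$d_star[j],
                                    phi_star = cell$bvcs$phi_star[j]),
                               args))
  }
  drive
}

.wall_present <- function(walls, k) if (k <= nrow(walls)) k else NA_integer_

#' Place-cell population rates at a position
#'
#' Each cell's rate is `max(0, drive - threshold)`, normalized so the drive
#' at the cell's own field center (full geometry) maps to rate 1. `walls`
#' holds the boundaries currently present, matched to the bank's reference
#' walls by `wall_ids`: entry j gives the row index in the bank's original
#' geometry of current wall j (so removed walls simply contribute nothing).
#'
#' @param x,y position.
#' @param walls currently present wall segments (may be `NULL`).
#' @param bank a [place_cell_bank()].
#' @param wall_ids integer vector mapping rows of `walls` to the bank's
#'   reference wall indices; defaults to `seq_len(nrow(walls))`.
#' @return Nonnegative rate vector, one entry per place cell.
#' @export
place_cell_rates <- function(x, y, walls, bank,
                             wall_ids = seq_len(NROW(walls))) {
  f <- numeric(length(bank))
  if (is.null(walls) || nrow(walls) == 0) return(f)
  for (i in seq_along(bank)) {
    cell <- bank[[i]]
    args <- cell[intersect(names(cell),
                           c("sigma0", "beta", "sigma_ang", "arc_step"))]
    drive <- 0
    for (j in seq_len(nrow(cell$bvcs))) {
      rows <- which(wall_ids == cell$bvcs$wall[j])
      if (!length(rows)) next
      drive <- drive + do.call(bvc_activation,
                               c(list(x = x, y = y,
                                      boundaries = walls[rows, , drop = FALSE],
                                      d_star = cell$bvcs$d_star[j],
                                      phi_star = cell$bvcs$phi_star[j]),
                                 args))
    }
    f[i] <- max(0, drive - cell$threshold) / cell$norm
  }
  f
}

#' Precompute place-cell rate maps over an arena
#'
#' @param arena an [build_arena()] object whose `boundaries` are the walls
#'   currently present.
#' @param bank a [place_cell_bank()].
#' @param wall_ids mapping of `arena$boundaries` rows to bank reference
#'   walls (see [place_cell_rates()]).
#' @return `n_states` x `n_cells` matrix of rates.
#' @export
place_field_maps <- function(arena, bank, wall_ids = seq_len(NROW(arena$boundaries))) {
  res <- vapply(seq_len(arena$n_states), function(s) {
    place_cell_rates(arena$coords[s, 1], arena$coords[s, 2],
                     arena$boundaries, bank, wall_ids)
  }, numeric(length(bank)))
  if (is.matrix(res)) t(res) else matrix(res, ncol = length(bank))
}

#' One-hot state encoding
#'
#' @param index 0-based state index.
#' @param n_states vector length.
#' @return Unit vector with a 1 at position `index + 1`.
#' @export
#' @examples
#' one_hot(2, 5)
one_hot <- function(index, n_states) {
  if (index < 0 || index >= n_states) stop("index out of range")
  f <- numeric(n_states)
  f[index + 1L] <- 1
  f
}
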