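#' Pentagon body pose
#'
#' The agent's body is a pentagon: five 2D vertices in grid-world coordinate
#' units (one grid cell spans 25 units). Only vertex *differences* enter the
#' free-energy score, so the template shape itself is a free choice.
#'
#' @param vertices A 5 x 2 numeric matrix of (X, Y) coordinates.
#' @param cell Optional `(column, row)` grid cell the pose is anchored to.
#' @return An object of class `pentagon_pose`.
#' @export
pentagon_pose <- function(vertices, cell = NULL) {
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(5L, 2L)))
    stop("a pentagon pose needs exactly five (X, Y) vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  colnames(vertices) <- c("X", "Y")
  structure(list(vertices = vertices, cell = cell), class = "pentagon_pose")
}

# Fixed vertex offsets of the pentagon template within one 25-unit cell,
# tip pointing up (up = decreasing Y).
pentagon_template <- function() {
  matrix(c(12.5, 2.5,
           22.5, 12.5,
           20.0, 22.5,
           5.0, 22.5,
           2.5, 12.5),
         ncol = 2, byrow = TRUE)
}

#' Pentagon pose of an agent occupying a grid cell
#'
#' @param cell Integer `(column, row)` pair, 1-based.
#' @param cell_length Grid cell side length in coordinate units (default 25).
#' @return A [pentagon_pose()] anchored at the cell.
#' @export
pose_from_cell <- function(cell, cell_length = 25) {
  stopifnot(length(cell) == 2L)
  origin <- (as.numeric(cell) - 1) * cell_length
  v <- sweep(pentagon_template(), 2, origin, "+")
  pentagon_pose(v, cell = as.integer(cell))
}

#' Free energy of a body-pose prediction error
#'
#' The sum of squared coordinate differences between the predicted and the
#' actual pentagon pose over all five vertices:
#' \deqn{FE = \sum_{i=1}^{5} (X^{pre}_i - X^{act}_i)^2 +
#'            \sum_{i=1}^{5} (Y^{pre}_i - Y^{act}_i)^2.}
#' Any positive free energy flags the pain (injured) state; zero free energy
#' is the normal state. For recording and plotting, the raw value is clipped
#' at 3125 (the score of a single-cell, 25-unit displacement of all five
#' vertices); the clip never affects the pain flag.
#'
#' @param predicted,actual [pentagon_pose()] objects.
#' @param clip Clipping ceiling for the recorded trace (default 3125).
#' @return An object of class `fe_report`: a list with `fe_raw`,
#'   `fe_clipped` and logical `pain` (`fe_raw > 0`).
#' @examples
#' p <- pose_from_cell(c(2, 2))
#' q <- pose_from_cell(c(4, 2))  # two cells off: 5 * 50^2 = 12500
#' free_energy_grid(p, q)$fe_raw
#' @export
free_energy_grid <- function(predicted, actual, clip = 3125) {
  if (!inherits(predicted, "pentagon_pose") || !inherits(actual, "pentagon_pose"))
    stop("predicted and actual must be pentagon_pose objects")
  d <- predicted$vertices - actual$vertices
  fe <- sum(d^2)
  structure(list(fe_raw = fe, fe_clipped = min(fe, clip), pain = fe > 0),
            class = "fe_report")
}

#' Gaussian free energy of a state estimate (generic and split-sensor forms)
#'
#' Under unit-variance Gaussian generative assumptions, the free energy of a
#' world-state estimate reduces to a half-sum of squared prediction errors.
#' With a single sensory stream it is
#' \deqn{FE = \tfrac12\,[s - g_s(\hat\phi)]^2 + \tfrac12\,[\hat\phi - \mu_\phi]^2,}
#' and with vision/proprioception split plus a forward body-dynamics model it
#' is the three-term form
#' \deqn{FE = \tfrac12[s_v - g_{sv}(\hat\phi)]^2 +
#'       \tfrac12[s_p - g_{sp}(\hat\phi)]^2 +
#'       \tfrac12[\hat\phi - g_\phi(\phi', a')]^2.}
#' Generator functions are supplied by the caller (e.g. learned by motor
#' babbling on a physical system); they must be pure.
#'
#' @param phi_hat Current world/body-state estimate (numeric).
#' @param s Observed sensory value(s) for the single-stream form.
#' @param g_s Sensory generating function `phi_hat -> s` (single-stream form).
#' @param mu_phi Prior mean of the state (single-stream form).
#' @param s_v,s_p Observed vision and proprioception (split form).
#' @param g_sv,g_sp Generating functions for vision and proprioception.
#' @param g_phi Forward dynamics `(phi_prev, a_prev) -> phi` (split form).
#' @param phi_prev,a_prev Previous state and action for `g_phi`.
#' @return The free energy (non-negative scalar).
#' @examples
#' free_energy_general(phi_hat = 2, s = 4, g_s = function(p) 2 * p, mu_phi = 2)
#' @export
free_energy_general <- function(phi_hat, s = NULL, g_s = NULL, mu_phi = NULL,
                                s_v = NULL, s_p = NULL,
                                g_sv = NULL, g_sp = NULL,
                                g_phi = NULL, phi_prev = NULL, a_prev = NULL) {
  split <- !is.null(s_v) || !is.null(s_p) || !is.null(g_phi)
  if (split) {
    if (is.null(s_v) || is.null(s_p) || is.null(g_sv) || is.null(g_sp) ||
        is.null(g_phi) || is.null(phi_prev))
      stop("split-sensor form needs s_v, s_p, g_sv, g_sp, g_phi and phi_prev")
    0.5 * sum((s_v - g_sv(phi_hat))^2) +
      0.5 * sum((s_p - g_sp(phi_hat))^2) +
      0.5 * sum((phi_hat - g_phi(phi_prev, a_prev))^2)
  } else {
    if (is.null(s) || is.null(g_s) || is.null(mu_phi))
      stop("single-stream form needs s, g_s and mu_phi")
    0.5 * sum((s - g_s(phi_hat))^2) + 0.5 * sum((phi_hat - mu_phi)^2)
  }
}

#' Predict the next body pose under the healthy movement rule
#'
#' The agent knows its own (undamaged) movement rule, including walls and
#' grid bounds, and uses it to predict the pose after a motor command: one
#' cell length in the commanded direction, or no movement when the move is
#' blocked. `up` decreases Y; `right` increases X. Damage-induced movement
#' inversion is *not* part of the predictor — that mismatch is exactly what
#' the free-energy score detects.
#'
#' @param current A [pentagon_pose()] anchored to a grid cell.
#' @param command One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @param world A [grid_world()].
#' @return The predicted [pentagon_pose()].
#' @export
predict_next_pose <- function(current, command, world) {
  if (!inherits(current, "pentagon_pose")) stop("current must be a pentagon_pose")
  cell <- current$cell
  if (is.null(cell))
    stop("pose is not anchored to a grid cell")
  if (any(cell < 1) || cell[1] > world$width || cell[2] > world$height)
    stop("pose cell lies outside the grid")
  target <- cell + command_delta(command)
  if (cell_blocked(world, target)) target <- cell
  pose_from_cell(target, world$cell_length)
}

#' Write a free-energy trace to CSV
#'
#' @param trace Data frame with columns `step`, `fe_raw`, `fe_clipped`, `pain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fe_trace <- function(trace, path) {
  utils::write.csv(trace[, c("step", "fe_raw", "fe_clipped", "pain")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
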