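#' Two-zone grid world with a dangerous object, a switch, and a passage
#'
#' A rectangular grid of cells split by a one-cell wall column into a danger
#' zone (left) and a safety zone (right). The wall contains passage cells
#' that are closed until an agent touches the switch, after which they stay
#' open for the rest of the episode. A dangerous object sits in the danger
#' zone; colliding with it impairs an agent's motor system (movement
#' inversion). Entering the safety zone restores a damaged agent.
#'
#' @param width,height Grid dimensions in cells (default 11 x 7).
#' @param cell_length Cell side length in coordinate units (default 25).
#' @param wall_col Column occupied by the wall (default the middle column).
#' @param danger_cell `(column, row)` of the dangerous object (danger zone).
#' @param switch_cell `(column, row)` of the switch; must not sit on a wall
#'   or on the dangerous object. Danger-side for the solo exploration phase,
#'   safety-side for the two-agent rescue task.
#' @param passage_cells Matrix (or single pair) of wall cells opened by the
#'   switch; default the middle cell of the wall column.
#' @return An object of class `grid_world` (with `passage_open = FALSE`).
#' @export
grid_world <- function(width = 11, height = 7, cell_length = 25,
                       wall_col = (width + 1) %/% 2,
                       danger_cell = c(2, 4),
                       switch_cell = c(width - 1, height - 1),
                       passage_cells = c(wall_col, (height + 1) %/% 2)) {
  stopifnot(width >= 3, height >= 1, wall_col > 1, wall_col < width)
  if (is.null(dim(passage_cells))) passage_cells <- matrix(passage_cells, ncol = 2)
  danger_cell <- as.integer(danger_cell)
  switch_cell <- as.integer(switch_cell)
  world <- structure(list(width = as.integer(width), height = as.integer(height),
                          cell_length = cell_length, wall_col = as.integer(wall_col),
                          danger_cell = danger_cell, switch_cell = switch_cell,
                          passage_cells = passage_cells, passage_open = FALSE),
                     class = "grid_world")
  if (cell_zone(world, danger_cell) != "danger")
    stop("danger_cell must lie in the danger zone")
  if (switch_cell[1] == wall_col) stop("switch_cell must not sit on the wall")
  if (all(switch_cell == danger_cell)) stop("switch_cell must differ from danger_cell")
  world
}

command_delta <- function(command) {
  switch(match.arg(command, c("up", "down", "left", "right")),
         up = c(0L, -1L), down = c(0L, 1L),
         left = c(-1L, 0L), right = c(1L, 0L))
}

# TRUE if the cell cannot be entered (out of bounds, or a closed wall cell).
cell_blocked <- function(world, cell) {
  if (cell[1] < 1 || cell[1] > world$width ||
      cell[2] < 1 || cell[2] > world$height) return(TRUE)
  if (cell[1] == world$wall_col) {
    on_passage <- any(world$passage_cells[, 1] == cell[1] &
                        world$passage_cells[, 2] == cell[2])
    return(!(on_passage && world$passage_open))
  }
  FALSE
}

cell_zone <- function(world, cell) {
  if (cell[1] < world$wall_col) "danger"
  else if (cell[1] > world$wall_col) "safety"
  else "wall"
}

#' Create an agent in a grid world
#'
#' @param id Agent identifier (character).
#' @param cell Starting `(column, row)` cell.
#' @param world A [grid_world()].
#' @return An object of class `agent_state` with the agent's cell, pentagon
#'   pose, heading, motor-damage flag, overt color (`"green"` = normal,
#'   `"red"` = pain) and zone.
#' @export
agent_state <- function(id, cell, world) {
  cell <- as.integer(cell)
  if (cell_blocked(world, cell)) stop("agent cannot start on a blocked cell")
  structure(list(id = id, cell = cell,
                 pose = pose_from_cell(cell, world$cell_length),
                 heading = "up", damaged = FALSE, color = "green",
                 zone = cell_zone(world, cell)),
            class = "agent_state")
}

#' Advance an agent by one motor command
#'
#' An undamaged agent moves one cell in the commanded direction; a damaged
#' agent moves in the *inverted* direction (right becomes left, up becomes
#' down). Blocked moves leave the agent in place. Moving onto the dangerous
#' object sets the damage flag; touching the switch opens the passage for
#' the rest of the episode; entering the safety zone clears damage.
#'
#' @param world A [grid_world()].
#' @param agent An [agent_state()].
#' @param command One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return A list with the updated `world`, `agent`, and a character vector
#'   `events` drawn from `"collision"`, `"switch"`, `"recovery"`.
#' @export
step_agent <- function(world, agent, command) {
  if (any(agent$cell < 1) || agent$cell[1] > world$width ||
      agent$cell[2] > world$height)
    stop("agent cell outside the grid: state corrupted")
  delta <- command_delta(command)
  if (agent$damaged) delta <- -delta
  target <- agent$cell + delta
  if (cell_blocked(world, target)) target <- agent$cell
  events <- character()
  moved <- !all(target == agent$cell)
  agent$heading <- command
  agent$cell <- target
  agent$pose <- pose_from_cell(target, world$cell_length)
  if (moved && all(target == world$danger_cell)) {
    if (!agent$damaged) events <- c(events, "collision")
    agent$damaged <- TRUE
  }
  if (all(target == world$switch_cell) && !world$passage_open) {
    world$passage_open <- TRUE
    events <- c(events, "switch")
  }
  agent$zone <- cell_zone(world, agent$cell)
  if (agent$zone == "safety" && agent$damaged) {
    agent$damaged <- FALSE
    agent$color <- "green"
    events <- c(events, "recovery")
  }
  list(world = world, agent = agent, events = events)
}

#' Detect the agent's internal state after a step
#'
#' Compares the pose predicted from the pre-step pose and the issued command
#' (healthy movement rule, walls included) against the actual post-step pose
#' via [free_energy_grid()]. Positive free energy flags pain; the agent's
#' overt color is updated accordingly (red in pain, green otherwise).
#'
#' @param world A [grid_world()].
#' @param agent_before The [agent_state()] before the step.
#' @param command The command that was issued.
#' @param agent_after The [agent_state()] returned by [step_agent()].
#' @return A list with `report` (the [free_energy_grid()] `fe_report`) and
#'   `agent` (`agent_after` with its color updated).
#' @export
sense_self <- function(world, agent_before, command, agent_after) {
  predicted <- predict_next_pose(agent_before$pose, command, world)
  report <- free_energy_grid(predicted, agent_after$pose)
  agent_after$color <- if (report$pain) "red" else "green"
  list(report = report, agent = agent_after)
}

#' Perceive another agent's overt action
#'
#' Maps the target's color to the percept label consumed by
#' [observe_other()]. Perceiving one's own color yields the same label as
#' perceiving the identical color on another agent.
#'
#' @param observer,target [agent_state()] objects (the observer may equal
#'   the target for self-perception).
#' @return `"perceive-red"` or `"perceive-green"`.
#' @export
perceive_other <- function(observer, target) {
  paste0("perceive-", target$color)
}

#' Uniform random-walk policy
#'
#' Draws one of the four cardinal commands uniformly, using R's global RNG
#' (seed upstream with `set.seed()` for reproducibility).
#'
#' @return A command string.
#' @export
random_walk_policy <- function() {
  sample(c("up", "down", "left", "right"), 1L)
}

# Breadth-first-search distances from a source cell over currently
# unblocked cells. Returns a width x height matrix of step counts (Inf =
# unreachable). Used for agentB's escape routing; tests cross-check against
# an independent graph library.
bfs_distances <- function(world, from) {
  dist <- matrix(Inf, world$width, world$height)
  dist[from[1], from[2]] <- 0
  queue <- list(as.integer(from))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (cmd in c("up", "down", "left", "right")) {
      nxt <- cur + command_delta(cmd)
      if (!cell_blocked(world, nxt) && dist[nxt[1], nxt[2]] == Inf) {
        dist[nxt[1], nxt[2]] <- dist[cur[1], cur[2]] + 1
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  dist
}

# One escape command for a damaged/trapped agent heading for the safety
# zone once the passage is open: follow the BFS gradient toward the nearest
# safety cell, compensating for movement inversion if damaged.
escape_command <- function(world, agent) {
  targets <- which(matrix(seq_len(world$width) > world$wall_col,
                          world$width, world$height), arr.ind = TRUE)
  dist <- bfs_distances(world, agent$cell)
  reach <- targets[is.finite(dist[targets]), , drop = FALSE]
  if (nrow(reach) == 0L) return(random_walk_policy())
  goal <- reach[which.min(dist[reach]), ]
  back <- bfs_distances(world, goal)
  best <- NULL; best_d <- back[agent$cell[1], agent$cell[2]]
  for (cmd in c("up", "down", "left", "right")) {
    nxt <- agent$cell + command_delta(cmd)
    if (!cell_blocked(world, nxt) && back[nxt[1], nxt[2]] < best_d) {
      best <- cmd; best_d <- back[nxt[1], nxt[2]]
    }
  }
  if (is.null(best)) return(random_walk_policy())
  if (agent$damaged) best <- invert_command(best)
  best
}

invert_command <- function(command) {
  switch(command, up = "down", down = "up", left = "right", right = "left")
}
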