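# Bounded 2D arena, point agent, ray-trace vision, collision
# somatosensation, and motor decoding closing the brain-environment loop.

#' Construct a rectangular arena
#'
#' @param width,height Positive extents in world units (default 20 x 20; the
#'   10-unit far-vision range then covers half the arena).
#' @return An `arena` object; the walls are the four bounding segments of
#'   `[0, width] x [0, height]`.
#' @export
arena <- function(width = 20, height = 20) {
  if (width <= 0 || height <= 0) stop("arena extents must be positive",
                                      call. = FALSE)
  structure(list(width = width, height = height), class = "arena")
}

#' Construct an agent state
#'
#' @param x,y Position in world units.
#' @param heading Heading in radians, wrapped to `[0, 2*pi)`;
#'   counterclockwise-positive, 0 along +x.
#' @param move_command Smoothed forward command v (world units per epoch,
#'   non-negative).
#' @param turn_command Turn command h (radians per epoch).
#' @return An `agent_state` object.
#' @export
agent_state <- function(x, y, heading = 0, move_command = 0,
                        turn_command = 0) {
  if (move_command < 0) stop("move_command must be non-negative",
                             call. = FALSE)
  structure(list(x = x, y = y, heading = wrap_angle(heading),
                 move_command = move_command, turn_command = turn_command),
            class = "agent_state")
}

# alias so function arguments named `arena` can default to a fresh arena
default_arena <- function() arena()

wrap_angle <- function(a) a %% (2 * pi)

inside_arena <- function(x, y, arena) {
  x >= 0 && x <= arena$width && y >= 0 && y <= arena$height
}

# Distance from (x, y) along direction `angle` to the first bounding wall.
# Exact ray/axis-aligned-segment geometry.
ray_wall_distance <- function(x, y, angle, arena) {
  dx <- cos(angle); dy <- sin(angle)
  ts <- c(
    if (dx > 0) (arena$width - x) / dx else Inf,
    if (dx < 0) (0 - x) / dx else Inf,
    if (dy > 0) (arena$height - y) / dy else Inf,
    if (dy < 0) (0 - y) / dy else Inf
  )
  ts <- ts[ts >= 0]
  if (!length(ts)) return(Inf)
  min(ts)
}

#' Cast the two visual rays
#'
#' One ray per eye, offset 10 degrees to either side of the agent's heading
#' (left ray at heading + 10 degrees, right ray at heading - 10 degrees);
#' the reading is the distance to the first intersection with a bounding
#' wall. Collision flags are carried by [move_agent()], so they are FALSE
#' here.
#'
#' @param agent An [agent_state()] strictly inside the arena.
#' @param arena An [arena()].
#' @return A `sensor_reading` list: `left_ray_distance`,
#'   `right_ray_distance`, `collided_left`, `collided_right`.
#' @export
cast_rays <- function(agent, arena) {
  if (!inside_arena(agent$x, agent$y, arena)) {
    stop("agent is outside the arena", call. = FALSE)
  }
  off <- 10 * pi / 180
  structure(list(
    left_ray_distance = ray_wall_distance(agent$x, agent$y,
                                          agent$heading + off, arena),
    right_ray_distance = ray_wall_distance(agent$x, agent$y,
                                           agent$heading - off, arena),
    collided_left = FALSE, collided_right = FALSE
  ), class = "sensor_reading")
}

#' Map sensor readings to forced task-positive nodes
#'
#' Per side: a wall closer than `near_range` forces that side's near-visual
#' node; a wall between `near_range` and `far_range` forces the far-visual
#' node (near and far are mutually exclusive per side); a collision forces
#' the somatosensory node.
#'
#' @param reading A `sensor_reading`.
#' @param roles A [node_roles()].
#' @param near_range,far_range Distance thresholds in world units
#'   (defaults 2 and 10).
#' @return Integer vector of task-positive node indices to force excited.
#' @export
sensors_to_forcing <- function(reading, roles, near_range = 2,
                               far_range = 10) {
  forced <- integer(0)
  d <- c(reading$left_ray_distance, reading$right_ray_distance)
  coll <- c(reading$collided_left, reading$collided_right)
  for (s in 1:2) {
    if (d[s] < near_range) {
      forced <- c(forced, roles$near_visual[s])
    } else if (d[s] <= far_range) {
      forced <- c(forced, roles$far_visual[s])
    }
    if (coll[s]) forced <- c(forced, roles$somatosensory[s])
  }
  forced
}

#' Decode motor commands from the network state
#'
#' Turn: +30 degrees when only the left rotate node is excited, -30 degrees
#' when only the right one is, 0 when both or neither (opposing rotations
#' cancel). Move: raw command 0 / 0.5 / 2 world units for zero / one / both
#' forward nodes excited, temporally smoothed as
#' `v = 7/8 * raw + 1/8 * previous v`. The turn command is not smoothed
#' unless `smooth_turn` is set.
#'
#' @param state A [gh_state()].
#' @param roles A [node_roles()].
#' @param prev The previous [agent_state()] (supplies the smoothing memory).
#' @param smooth_turn Apply the same 7/8-1/8 smoothing to the turn command.
#' @return List with `v` (world units/epoch) and `h` (radians/epoch).
#' @export
decode_motors <- function(state, roles, prev, smooth_turn = FALSE) {
  act <- function(i) state$states[i] == 1L
  rl <- act(roles$rotate_left); rr <- act(roles$rotate_right)
  raw_turn <- if (rl && !rr) pi / 6 else if (rr && !rl) -pi / 6 else 0
  nf <- act(roles$forward_left) + act(roles$forward_right)
  raw_move <- c(0, 0.5, 2)[nf + 1]
  v <- 7 / 8 * raw_move + 1 / 8 * prev$move_command
  h <- if (smooth_turn) 7 / 8 * raw_turn + 1 / 8 * prev$turn_command
       else raw_turn
  list(v = v, h = h)
}

#' Move the agent and resolve wall collisions
#'
#' The heading is rotated by `h` (wrapped), then the agent advances `v`
#' world units along the new heading. If the displacement segment crosses a
#' bounding wall, the position is clipped to 1e-3 world units inside the
#' first wall hit and a collision is flagged. The collision side is left
#' when the wall lies counterclockwise of the heading (signed angle from the
#' heading to the into-wall normal > 0), right otherwise; a head-on hit
#' (|signed angle| < 1 degree) flags both sides.
#'
#' @param agent An [agent_state()].
#' @param v Non-negative forward displacement (world units).
#' @param h Turn (radians).
#' @param arena An [arena()].
#' @return List: `agent` (updated state), `collided_left`, `collided_right`.
#' @export
move_agent <- function(agent, v, h, arena) {
  if (v < 0) stop("v must be non-negative", call. = FALSE)
  heading <- wrap_angle(agent$heading + h)
  dx <- v * cos(heading); dy <- v * sin(heading)
  x0 <- agent$x; y0 <- agent$y
  x1 <- x0 + dx; y1 <- y0 + dy
  eps <- 1e-3
  collided_left <- FALSE; collided_right <- FALSE

  if (!inside_arena(x1, y1, arena)) {
    # parametric first crossing along the displacement segment
    tx <- if (dx > 0) (arena$width - x0) / dx
          else if (dx < 0) -x0 / dx else Inf
    ty <- if (dy > 0) (arena$height - y0) / dy
          else if (dy < 0) -y0 / dy else Inf
    t_hit <- min(tx, ty)
    # wall normal oriented into the wall (direction of penetration), so a
    # head-on hit gives signed angle 0
    if (tx <= ty) {                       # vertical wall hit first
      normal <- if (dx > 0) 0 else pi
    } else {                              # horizontal wall hit first
      normal <- if (dy > 0) pi / 2 else -pi / 2
    }
    # stop at the wall, then push 1e-3 inside along any violated axis
    x1 <- min(max(x0 + t_hit * dx, eps), arena$width - eps)
    y1 <- min(max(y0 + t_hit * dy, eps), arena$height - eps)
    sa <- signed_angle(heading, normal)
    if (abs(sa) < pi / 180) {
      collided_left <- TRUE; collided_right <- TRUE
    } else if (sa > 0) collided_left <- TRUE else collided_right <- TRUE
  }
  out <- agent
  out$x <- x1; out$y <- y1; out$heading <- heading
  out$move_command <- v; out$turn_command <- h
  list(agent = out, collided_left = collided_left,
       collided_right = collided_right)
}

# signed angle from direction a to direction b, in (-pi, pi]
signed_angle <- function(a, b) {
  d <- (b - a) %% (2 * pi)
  if (d > pi) d - 2 * pi else d
}

#' Run the embodied closed-loop simulation
#'
#' Executes `config$epochs` iterations of the sensorimotor loop. Each epoch:
#' (1) visual rays are cast from the current pose and combined with the
#' previous epoch's collision flags into sensory forcing; (2) under the
#' `"macro"`/`"combined"` variants, task-negative nodes are forced in
#' complement ([macro_balance()]); (3) the network takes one synchronous GH
#' step with both forcing sets; (4) under `"local"`/`"combined"`,
#' thresholds are updated ([update_thresholds()]); (5) motor commands are
#' decoded and the agent moves ([move_agent()]). The initial network state
#' is all-quiescent with uniform thresholds; the initial pose is the arena
#' center with a heading drawn uniformly from the seeded stream. The whole
#' run is a pure function of the configuration and seed.
#'
#' @param c A [connectome()].
#' @param roles A [node_roles()] (default [default_node_roles()]).
#' @param config A [model_config()].
#' @param arena An [arena()].
#' @return A `gh_run` object: `states` and `thresholds` (epoch-by-node
#'   matrices, rows = state after each epoch), `trajectory` (data frame
#'   with epoch, x, y, heading, v, h, wall_distance, collided_left,
#'   collided_right, n_tp_forced, n_tn_forced_E), `forced_E` (epoch-by-node
#'   logical), plus the config, roles and arena.
#' @export
run_simulation <- function(c, roles = default_node_roles(c),
                           config = model_config(), arena = default_arena()) {
  stopifnot(inherits(c, "connectome"), inherits(roles, "node_roles"),
            inherits(config, "model_config"), inherits(arena, "arena"))
  if (roles$n_nodes != c$n_nodes) {
    stop("roles were built for a different network size", call. = FALSE)
  }
  n <- c$n_nodes
  epochs <- config$epochs
  set.seed(config$seed)

  w <- normalized_weights(c, config$coupling)
  states <- integer(n)                       # all quiescent
  thresholds <- rep(config$initial_threshold, n)
  ag <- agent_state(arena$width / 2, arena$height / 2,
                    heading = stats::runif(1, 0, 2 * pi))
  macro_on <- config$variant %in% c("macro", "combined")
  local_on <- config$variant %in% c("local", "combined")
  # NULL = default: the exogenously forced (task-positive + task-negative)
  # nodes are not subject to threshold plasticity
  excl <- config$homeostasis_exclude
  if (is.null(excl)) excl <- c(roles$task_positive, roles$task_negative)

  S <- matrix(0L, epochs, n)
  TH <- matrix(0, epochs, n)
  FE <- matrix(FALSE, epochs, n)
  traj <- data.frame(epoch = seq_len(epochs), x = 0, y = 0, heading = 0,
                     v = 0, h = 0, wall_distance = 0,
                     ray_left = 0, ray_right = 0,
                     collided_left = FALSE, collided_right = FALSE,
                     n_tp_forced = 0L, n_tn_forced_E = 0L)
  coll_l <- FALSE; coll_r <- FALSE

  for (t in seq_len(epochs)) {
    # (1) sense from the pose the agent currently occupies
    reading <- cast_rays(ag, arena)
    reading$collided_left <- coll_l
    reading$collided_right <- coll_r
    tp_forced <- sensors_to_forcing(reading, roles)

    # (2) macroscopic balancing
    if (macro_on) {
      bal <- macro_balance(tp_forced, roles)
      forced_E <- c(tp_forced, bal$forced_E_tn)
      forced_Q <- bal$forced_Q_tn
      n_tn_E <- length(bal$forced_E_tn)
    } else {
      forced_E <- tp_forced
      forced_Q <- integer(0)
      n_tn_E <- 0L
    }

    # (3) synchronous network update
    states <- gh_step_core(states, thresholds, w, config$p_spont,
                           forced_E, forced_Q)

    # (4) local homeostasis
    if (local_on) {
      delta <- config$alpha * (as.numeric(states == 1L) - config$rho)
      if (length(excl)) delta[excl] <- 0
      thresholds <- thresholds + delta
    }

    # (5) act
    mot <- decode_motors(list(states = states), roles, ag,
                         smooth_turn = config$smooth_turn)
    mv <- move_agent(ag, mot$v, mot$h, arena)
    ag <- mv$agent
    coll_l <- mv$collided_left; coll_r <- mv$collided_right

    S[t, ] <- states
    TH[t, ] <- thresholds
    FE[t, forced_E] <- TRUE
    traj$x[t] <- ag$x; traj$y[t] <- ag$y; traj$heading[t] <- ag$heading
    traj$v[t] <- mot$v; traj$h[t] <- mot$h
    # ray distances as sensed at the start of this epoch (pre-move pose)
    traj$ray_left[t] <- reading$left_ray_distance
    traj$ray_right[t] <- reading$right_ray_distance
    traj$wall_distance[t] <- min(ag$x, arena$width - ag$x,
                                 ag$y, arena$height - ag$y)
    traj$collided_left[t] <- coll_l; traj$collided_right[t] <- coll_r
    traj$n_tp_forced[t] <- length(tp_forced)
    traj$n_tn_forced_E[t] <- n_tn_E
  }

  structure(list(states = S, thresholds = TH, forced_E = FE,
                 trajectory = traj, config = config, roles = roles,
                 arena = arena, connectome_labels = c$labels),
            class = "gh_run")
}

#' @export
print.gh_run <- function(x, ...) {
  cat("gh_run:", nrow(x$states), "epochs x", ncol(x$states), "nodes,",
      "variant =", x$config$variant, "\n")
  cat(sprintf("  mean activity %.4f | collisions %d | net displacement %.2f\n",
              mean(x$states == 1L),
              sum(x$trajectory$collided_left | x$trajectory$collided_right),
              sqrt((x$trajectory$x[nrow(x$trajectory)] - x$arena$width / 2)^2 +
                   (x$trajectory$y[nrow(x$trajectory)] - x$arena$height / 2)^2)))
  invisible(x)
}

#' Run the network at rest (no environmental embedding)
#'
#' Executes the GH dynamics without sensory forcing, motor decoding or an
#' arena: the network is driven by spontaneous firing and recurrent
#' propagation only, with local threshold plasticity under the
#' `"local"`/`"combined"` variants. This is the resting-state mode used to
#' study the dynamics and the homeostatic rule in isolation.
#'
#' @param c A [connectome()].
#' @param config A [model_config()]. `homeostasis_exclude = NULL` resolves
#'   to no exclusions here (there are no forced nodes at rest).
#' @return A `gh_rest_run`: `states` and `thresholds` epoch-by-node
#'   matrices plus the config.
#' @export
run_network <- function(c, config = model_config()) {
  stopifnot(inherits(c, "connectome"), inherits(config, "model_config"))
  n <- c$n_nodes
  epochs <- config$epochs
  set.seed(config$seed)
  w <- normalized_weights(c, config$coupling)
  states <- integer(n)
  thresholds <- rep(config$initial_threshold, n)
  local_on <- config$variant %in% c("local", "combined")
  excl <- config$homeostasis_exclude
  S <- matrix(0L, epochs, n)
  TH <- matrix(0, epochs, n)
  for (t in seq_len(epochs)) {
    states <- gh_step_core(states, thresholds, w, config$p_spont)
    if (local_on) {
      delta <- config$alpha * (as.numeric(states == 1L) - config$rho)
      if (length(excl)) delta[excl] <- 0
      thresholds <- thresholds + delta
    }
    S[t, ] <- states
    TH[t, ] <- thresholds
  }
  structure(list(states = S, thresholds = TH, config = config,
                 connectome_labels = c$labels),
            class = "gh_rest_run")
}

#' Binarized activity raster of a run
#'
#' @param run A `gh_run` or `gh_rest_run`.
#' @return Epoch-by-node 0/1 integer matrix (1 = excited).
#' @export
activity_raster <- function(run) {
  matrix(as.integer(run$states == 1L), nrow(run$states), ncol(run$states))
}
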