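# State-dependent forces and torques, motion integration, reflective walls
# and the proximity-based collision override.

#' Wrap an angle to (-pi, pi]
#'
#' Used for all angular differences, so turns always take the short way round.
#'
#' @param a angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  ifelse(a > pi, a - 2 * pi, a)
}

#' Exploration kinetics: persistent random walk
#'
#' Speed relaxes toward the exploration cruise speed and the heading receives
#' a fresh uniform random turn from `[-theta_exp_max, theta_exp_max]` every
#' step. Draws from the current R random stream.
#'
#' @param v current speed (px/ts).
#' @param v_exp cruise speed.
#' @param theta_exp_max maximal turning angle (rad).
#' @return List with `F_v` and `T_theta`.
#' @export
exploration_kinetics <- function(v, v_exp = 3, theta_exp_max = 0.5) {
  list(F_v = v_exp - v,
       T_theta = runif(1, -theta_exp_max, theta_exp_max))
}

#' Exploitation kinetics: stop and centre on the patch
#'
#' The agent brakes at rate `r_stop` and turns toward the patch centre at rate
#' `r_turn`, with the goal-angle difference wrapped to (-pi, pi].
#'
#' @param agent list with `x`, `y`, `theta`, `v`.
#' @param patch_center numeric `c(x, y)` of the patch being exploited.
#' @param r_stop stopping rate.
#' @param r_turn turning rate.
#' @return List with `F_v` and `T_theta`.
#' @examples
#' a <- list(x = 0, y = 0, theta = 0, v = 3)
#' exploitation_kinetics(a, c(10, 0))  # F_v = -0.525, no turn needed
#' @export
exploitation_kinetics <- function(agent, patch_center, r_stop = 0.175,
                                  r_turn = 0.02) {
  theta_goal <- atan2(patch_center[2] - agent$y, patch_center[1] - agent$x)
  list(F_v = -r_stop * agent$v,
       T_theta = r_turn * wrap_angle(theta_goal - agent$theta))
}

#' Social relocation kinetics: left-right steering
#'
#' Speed relaxes toward the relocation cruise speed; the turn is the maximal
#' social turning angle scaled by the hemisphere difference D of the social
#' projection field (positive D steers left).
#'
#' @param v current speed.
#' @param D hemisphere difference (see [hemisphere_difference()]).
#' @param v_soc relocation cruise speed.
#' @param theta_soc_max maximal relocation turn (rad).
#' @return List with `F_v` and `T_theta`.
#' @export
relocation_kinetics <- function(v, D, v_soc = 3, theta_soc_max = 1.8) {
  list(F_v = v_soc - v, T_theta = theta_soc_max * D)
}

#' Collision override from the proximity field
#'
#' If any proximity bin is set and the central 10% of the field (centred on
#' the heading) is not clear, the agent halts forward progress and turns
#' toward the hemisphere with the lower mean proximity until the central
#' window clears. At exact left/right symmetry the agent turns left. The turn
#' magnitude is capped at `theta_soc_max`.
#'
#' @param prox_field binary proximity field (full 360 degrees).
#' @param theta_soc_max turning-rate cap (rad/ts).
#' @return List with `active` (logical), `direction` (+1 left / -1 right / 0)
#'   and `T_theta`.
#' @export
collision_override <- function(prox_field, theta_soc_max = 1.8) {
  k <- length(prox_field)
  phi <- -pi + (seq_len(k) - 0.5) * (2 * pi / k)
  central <- abs(phi) <= 0.1 * pi
  if (!any(prox_field > 0) || !any(prox_field[central] > 0)) {
    return(list(active = FALSE, direction = 0, T_theta = 0))
  }
  s_left <- sum(prox_field[phi > 0])
  s_right <- sum(prox_field[phi < 0])
  dir <- if (s_left <= s_right) 1 else -1
  list(active = TRUE, direction = dir, T_theta = dir * theta_soc_max)
}

#' One Euler step of the motion equations
#'
#' Heading updates before displacement: `theta <- wrap(theta + T_theta)`,
#' `v <- max(v + F_v, 0)`, then `x <- x + v cos(theta)`,
#' `y <- y + v sin(theta)` (dt = 1 timestep).
#'
#' @param agent list with `x`, `y`, `theta`, `v`.
#' @param F_v speed force.
#' @param T_theta torque (rad).
#' @return The updated agent list.
#' @export
integrate_motion <- function(agent, F_v, T_theta) {
  agent$theta <- (agent$theta + T_theta) %% (2 * pi)
  agent$v <- max(agent$v + F_v, 0)
  agent$x <- agent$x + agent$v * cos(agent$theta)
  agent$y <- agent$y + agent$v * sin(agent$theta)
  agent
}

#' Reflective arena boundaries
#'
#' If the body would cross a wall, the position is mirrored back inside and
#' the corresponding heading component is reflected (`theta -> pi - theta` at
#' vertical walls, `theta -> -theta` at horizontal walls). Applied after each
#' displacement; the agent centre always ends inside
#' `[R_A, W - R_A] x [R_A, H - R_A]`.
#'
#' @param agent list with `x`, `y`, `theta`.
#' @param width,height arena dimensions.
#' @param radius agent body radius.
#' @return The updated agent list.
#' @export
reflect_boundaries <- function(agent, width, height, radius) {
  for (guard in 1:8) {
    bounced <- FALSE
    if (agent$x < radius) {
      agent$x <- 2 * radius - agent$x
      agent$theta <- (pi - agent$theta) %% (2 * pi)
      bounced <- TRUE
    } else if (agent$x > width - radius) {
      agent$x <- 2 * (width - radius) - agent$x
      agent$theta <- (pi - agent$theta) %% (2 * pi)
      bounced <- TRUE
    }
    if (agent$y < radius) {
      agent$y <- 2 * radius - agent$y
      agent$theta <- (-agent$theta) %% (2 * pi)
      bounced <- TRUE
    } else if (agent$y > height - radius) {
      agent$y <- 2 * (height - radius) - agent$y
      agent$theta <- (-agent$theta) %% (2 * pi)
      bounced <- TRUE
    }
    if (!bounced) break
  }
  agent$x <- min(max(agent$x, radius), width - radius)
  agent$y <- min(max(agent$y, radius), height - radius)
  agent
}
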