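# Visual projection fields: the social field (exploiting agents only,
# optics-true, optional occlusion and limited field of view) and the
# short-range proximity field used for collision avoidance.

#' Angular interval subtended by another agent's body
#'
#' On the focal agent's 1D retina, a disk of radius `agent_radius` at centre
#' distance d subtends the interval `[bearing - alpha, bearing + alpha]` with
#' half-width `alpha = asin(agent_radius / d)` (tangent-line optics). For
#' overlapping bodies (d < agent_radius) the half-width is clamped to pi/2.
#' The bearing is measured relative to the focal heading, wrapped to
#' (-pi, pi].
#'
#' @param focal list or one-row data.frame with `x`, `y`, `theta`.
#' @param other list or one-row data.frame with `x`, `y`.
#' @param agent_radius body radius in pixels.
#' @return List with `bearing`, `half_width`, `lo`, `hi` (lo/hi unwrapped, may
#'   exceed the (-pi, pi] domain for intervals straddling the rear).
#' @examples
#' angular_interval(list(x = 0, y = 0, theta = 0), list(x = 20, y = 0), 10)
#' @export
angular_interval <- function(focal, other, agent_radius) {
  dx <- other$x - focal$x
  dy <- other$y - focal$y
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("degenerate geometry: coincident agent centers")
  bearing <- wrap_angle(atan2(dy, dx) - focal$theta)
  half <- if (d >= agent_radius) asin(agent_radius / d) else pi / 2
  list(bearing = bearing, half_width = half,
       lo = bearing - half, hi = bearing + half)
}

#' Social visual projection field
#'
#' Binary field over K angular bins on `[-pi, pi)` relative to the focal
#' heading. Bins covered by visible exploiting agents are 1; agents exploiting
#' the same patch as the focal agent are never targets, and bins outside the
#' symmetric field-of-view window `[-fov_half_angle, fov_half_angle]` stay 0.
#' With `occlusion = TRUE`, every other agent body (exploiting or not,
#' including same-patch co-exploiters) blocks farther exploiting agents along
#' each bin's ray; the nearest hit wins. Perception range is unlimited.
#'
#' @param focal list with `x`, `y`, `theta` and optionally `patch` (id of the
#'   patch the focal agent is on, `NA` if none).
#' @param agents data.frame of the other agents with columns `x`, `y`,
#'   `exploiting` (logical) and optionally `patch` (id, `NA` when off-patch).
#' @param agent_radius body radius in pixels.
#' @param fov_half_angle field-of-view half-angle in `[0, pi]`.
#' @param occlusion logical.
#' @param resolution number of bins K.
#' @return Integer 0/1 vector of length `resolution`.
#' @examples
#' focal <- list(x = 100, y = 100, theta = 0)
#' others <- data.frame(x = 200, y = 100, exploiting = TRUE, patch = 1)
#' sum(project_social(focal, others))
#' @export
project_social <- function(focal, agents, agent_radius = 10,
                           fov_half_angle = pi, occlusion = FALSE,
                           resolution = 2000L) {
  stopifnot(resolution >= 1, fov_half_angle >= 0, fov_half_angle <= pi)
  if (is.null(agents) || nrow(agents) == 0) {
    return(integer(resolution))
  }
  patch <- if ("patch" %in% names(agents)) as.integer(agents$patch) else
    rep(NA_integer_, nrow(agents))
  fpatch <- if (!is.null(focal$patch) && !is.na(focal$patch))
    as.integer(focal$patch) else NA_integer_
  cpp_project_social(focal$x, focal$y, focal$theta, fpatch,
                     as.numeric(agents$x), as.numeric(agents$y),
                     as.logical(agents$exploiting), patch,
                     agent_radius, fov_half_angle, isTRUE(occlusion),
                     as.integer(resolution))
}

#' Left-right hemisphere difference of a visual field
#'
#' Mean over the left hemisphere bins (relative angle in (0, pi)) minus the
#' mean over the right hemisphere bins ((-pi, 0)); positive values steer the
#' agent left. Bin centres sit at `-pi + (k + 0.5) * 2*pi/K`.
#'
#' @param field binary vector as returned by [project_social()].
#' @return Scalar in `[-1, 1]`.
#' @export
hemisphere_difference <- function(field) {
  k <- length(field)
  stopifnot(k >= 2)
  phi <- -pi + (seq_len(k) - 0.5) * (2 * pi / k)
  mean(field[phi > 0]) - mean(field[phi < 0])
}

#' Short-range proximity field
#'
#' Binary 360-degree field (the field of view does not apply) marking the
#' angular extent of any agent whose body surface comes within `sense_range`
#' pixels of the focal body surface — a minimal stand-in for a LiDAR-like
#' proximity sensor.
#'
#' @param focal list with `x`, `y`, `theta`.
#' @param agents data.frame with columns `x`, `y` for the other agents.
#' @param agent_radius body radius in pixels.
#' @param sense_range maximal surface-to-surface gap in pixels (default 2).
#' @param resolution number of bins.
#' @return Integer 0/1 vector of length `resolution`.
#' @export
proximity_field <- function(focal, agents, agent_radius = 10,
                            sense_range = 2, resolution = 2000L) {
  stopifnot(sense_range > 0, resolution >= 1)
  if (is.null(agents) || nrow(agents) == 0) {
    return(integer(resolution))
  }
  cpp_proximity_field(focal$x, focal$y, focal$theta,
                      as.numeric(agents$x), as.numeric(agents$y),
                      agent_radius, sense_range, as.integer(resolution))
}

#' Dump a visual field to CSV for inspection
#'
#' @param field binary vector.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, path) {
  k <- length(field)
  phi <- -pi + (seq_len(k) - 0.5) * (2 * pi / k)
  utils::write.csv(data.frame(bin = seq_len(k) - 1L, phi = phi,
                              value = as.integer(field)),
                   path, row.names = FALSE)
  invisible(path)
}
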