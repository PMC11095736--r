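#' Simulation configuration
#'
#' Build the full parameter set of the foraging model. Defaults are the
#' fixed reference values of the model: a 500 x 500 px arena, disk agents of
#' radius 10 px moving at 3 px per timestep, resource patches of radius 15 px
#' holding an equal share of `total_units = 2400` resource units consumed at
#' quality `quality = 0.25` units per timestep, and two leaky integrators with
#' decay 0.085, thresholds 0.5 and saturation 1.
#'
#' @param n_agents number of agents \eqn{N_A}.
#' @param n_patches number of resource patches \eqn{N_R} (0 is allowed, giving
#'   an empty arena for testing).
#' @param eps_w social excitability: gain on the mean of the social projection
#'   field entering the social integrator. 0 makes agents fully asocial.
#' @param n_steps run length \eqn{T} in timesteps.
#' @param arena_width,arena_height arena size \eqn{W}, \eqn{H} in pixels.
#' @param agent_radius agent body radius \eqn{R_A} in pixels.
#' @param patch_radius patch radius \eqn{R_P} in pixels.
#' @param total_units total resource units in the arena (split equally over
#'   patches).
#' @param quality patch quality \eqn{Q_j}: units one agent can consume from a
#'   patch per timestep.
#' @param v_exp,v_soc cruise speeds (px/ts) in exploration and relocation.
#' @param theta_exp_max half-width (rad) of the uniform random turn during
#'   exploration.
#' @param theta_soc_max maximal relocation turning rate (rad/ts); also reused
#'   as the turning rate cap during collision avoidance.
#' @param r_stop,r_turn exploitation stopping and turning rates.
#' @param novelty_length novelty window \eqn{T_n} in timesteps.
#' @param baseline_u,baseline_w integrator baselines \eqn{B_u}, \eqn{B_w}.
#' @param u_max,w_max integrator saturation values.
#' @param g_u,g_w integrator decay rates.
#' @param threshold_u,threshold_w decision thresholds \eqn{T_u}, \eqn{T_w}.
#' @param eps_u personal information integration rate.
#' @param s_uw,s_wu cross-inhibition weights (0 by default: independent race).
#' @param fov_half_angle half-angle \eqn{L} of the symmetric field of view in
#'   radians; `pi` is panoramic vision, 0 a blind agent.
#' @param occlusion if `TRUE`, nearer agent bodies block farther exploiting
#'   agents in the visual field.
#' @param collisions if `TRUE`, agents use proximity-based collision avoidance
#'   instead of freely overlapping.
#' @param resolution number of angular bins K of the social projection field.
#' @param prox_resolution number of angular bins of the proximity field.
#' @param prox_range surface-to-surface gap (px) at which the proximity sensor
#'   detects another body.
#' @param max_place_attempts rejection-sampling cap per patch placement.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_agents = 5, n_patches = 3, eps_w = 1, n_steps = 200)
#' cfg$eps_w
#' @export
sim_config <- function(n_agents = 10,
                       n_patches = 3,
                       eps_w = 1,
                       n_steps = 25000,
                       arena_width = 500,
                       arena_height = 500,
                       agent_radius = 10,
                       patch_radius = 15,
                       total_units = 2400,
                       quality = 0.25,
                       v_exp = 3,
                       v_soc = 3,
                       theta_exp_max = 0.5,
                       theta_soc_max = 1.8,
                       r_stop = 0.175,
                       r_turn = 0.02,
                       novelty_length = 10L,
                       baseline_u = 0,
                       baseline_w = 0,
                       u_max = 1,
                       w_max = 1,
                       g_u = 0.085,
                       g_w = 0.085,
                       threshold_u = 0.5,
                       threshold_w = 0.5,
                       eps_u = 1,
                       s_uw = 0,
                       s_wu = 0,
                       fov_half_angle = pi,
                       occlusion = FALSE,
                       collisions = FALSE,
                       resolution = 2000L,
                       prox_resolution = 2000L,
                       prox_range = 2,
                       max_place_attempts = 10000L) {
  cfg <- list(
    n_agents = as.integer(n_agents), n_patches = as.integer(n_patches),
    eps_w = eps_w, n_steps = as.integer(n_steps),
    arena_width = arena_width, arena_height = arena_height,
    agent_radius = agent_radius, patch_radius = patch_radius,
    total_units = total_units, quality = quality,
    v_exp = v_exp, v_soc = v_soc,
    theta_exp_max = theta_exp_max, theta_soc_max = theta_soc_max,
    r_stop = r_stop, r_turn = r_turn,
    novelty_length = as.integer(novelty_length),
    baseline_u = baseline_u, baseline_w = baseline_w,
    u_max = u_max, w_max = w_max, g_u = g_u, g_w = g_w,
    threshold_u = threshold_u, threshold_w = threshold_w,
    eps_u = eps_u, s_uw = s_uw, s_wu = s_wu,
    fov_half_angle = fov_half_angle,
    occlusion = isTRUE(occlusion), collisions = isTRUE(collisions),
    resolution = as.integer(resolution),
    prox_resolution = as.integer(prox_resolution),
    prox_range = prox_range,
    max_place_attempts = as.integer(max_place_attempts)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks positivity/range constraints of all parameters and the geometric
#' feasibility of patch placement. Called by [sim_config()]; exported so that
#' externally modified configurations can be re-checked.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("arena_width", "arena_height", "agent_radius", "patch_radius",
           "total_units", "quality", "v_exp", "v_soc", "u_max", "w_max")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0) {
      stop("invalid configuration: `", p, "` must be a positive scalar")
    }
  }
  nonneg <- c("eps_w", "eps_u", "g_u", "g_w", "r_stop", "r_turn",
              "theta_exp_max", "theta_soc_max", "s_uw", "s_wu", "prox_range")
  for (p in nonneg) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] < 0) {
      stop("invalid configuration: `", p, "` must be a non-negative scalar")
    }
  }
  if (cfg$n_agents < 1) stop("invalid configuration: need at least one agent")
  if (cfg$n_patches < 0) stop("invalid configuration: negative patch count")
  if (cfg$n_steps < 1) stop("invalid configuration: `n_steps` must be >= 1")
  if (cfg$fov_half_angle < 0 || cfg$fov_half_angle > pi) {
    stop("invalid configuration: `fov_half_angle` must lie in [0, pi]")
  }
  if (cfg$resolution < 2 || cfg$resolution %% 2L != 0L) {
    stop("invalid configuration: `resolution` must be an even integer >= 2")
  }
  if (cfg$prox_resolution < 2 || cfg$prox_resolution %% 2L != 0L) {
    stop("invalid configuration: `prox_resolution` must be even and >= 2")
  }
  if (cfg$n_patches > 0 &&
      (2 * cfg$patch_radius > cfg$arena_width ||
       2 * cfg$patch_radius > cfg$arena_height)) {
    stop("invalid configuration: patch does not fit inside the arena")
  }
  if (2 * cfg$agent_radius > cfg$arena_width ||
      2 * cfg$agent_radius > cfg$arena_height) {
    stop("invalid configuration: agent does not fit inside the arena")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  agents: %d (R_A = %g px), patches: %d (R_P = %g px)\n",
              x$n_agents, x$agent_radius, x$n_patches, x$patch_radius))
  cat(sprintf("  arena: %g x %g px, total units: %g, quality: %g R/ts\n",
              x$arena_width, x$arena_height, x$total_units, x$quality))
  cat(sprintf("  eps_w: %g, fov: %.3f rad, occlusion: %s, collisions: %s\n",
              x$eps_w, x$fov_half_angle, x$occlusion, x$collisions))
  cat(sprintf("  n_steps: %d\n", x$n_steps))
  invisible(x)
}
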