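# Evidence accumulation: two independent leaky integrators (personal u,
# social w) racing toward their thresholds, plus the novelty bookkeeping.

#' Personal information signal
#'
#' The personal evidence entering the personal integrator is the average of a
#' binary novelty component N (1 during the novelty window after first
#' discovery of a patch) and the resource units Q consumed in the current
#' step: `(N + Q) / 2`.
#'
#' @param consumed resource units consumed this step (>= 0).
#' @param novelty_active logical; is the novelty window running?
#' @return Scalar personal information.
#' @examples
#' personal_information(0, TRUE)      # fresh discovery: 0.5
#' personal_information(0.25, FALSE)  # steady consumption: 0.125
#' @export
personal_information <- function(consumed, novelty_active) {
  if (!is.numeric(consumed) || any(consumed < 0)) {
    stop("`consumed` must be non-negative")
  }
  (as.numeric(novelty_active) + consumed) / 2
}

#' One Euler step of the two leaky integrators
#'
#' Updates the personal integrator u and social integrator w by one timestep
#' (dt = 1):
#' `u <- u + eps_u * I_per - g_u * (u - B_u) - S_wu * max(w, 0)` and
#' `w <- w + eps_w * mean(V_soc) - g_w * (w - B_w) - S_uw * max(u, 0)`,
#' then both are clamped into `[0, max]` (saturating clamp: decay stays active
#' at the ceiling, so integrators can leave saturation when input stops). The
#' social drive is the mean of the binary projection field over the full
#' angular domain, so a narrower field of view strictly reduces input.
#'
#' @param state list with numeric `u` and `w`.
#' @param I_per personal information (see [personal_information()]).
#' @param social_field binary projection field, or a single number already
#'   equal to its mean.
#' @param config a [sim_config()] (only the integrator parameters are used).
#' @return List with updated `u` and `w`.
#' @examples
#' cfg <- sim_config()
#' s <- update_integrators(list(u = 0, w = 0), 0.5, 0, cfg)
#' s$u  # 0.5 after one novelty step
#' update_integrators(s, 0.5, 0, cfg)$u  # 0.9575 after two
#' @export
update_integrators <- function(state, I_per, social_field, config) {
  v_soc_mean <- if (length(social_field) > 1) mean(social_field)
                else as.numeric(social_field)
  up <- max(state$u, 0)
  wp <- max(state$w, 0)
  u <- state$u + config$eps_u * I_per - config$g_u * (state$u -
         config$baseline_u) - config$s_wu * wp
  w <- state$w + config$eps_w * v_soc_mean - config$g_w * (state$w -
         config$baseline_w) - config$s_uw * up
  list(u = min(max(u, 0), config$u_max), w = min(max(w, 0), config$w_max))
}

#' Behavioral state from integrator activities
#'
#' Threshold logic with strict comparisons: exploitation whenever
#' `u > threshold_u` (exploitation has priority over relocation), social
#' relocation when only `w > threshold_w`, exploration otherwise. Exactly one
#' state is active for any (u, w).
#'
#' @param u,w integrator activities.
#' @param threshold_u,threshold_w decision thresholds (default 0.5).
#' @return One of `"exploitation"`, `"social_relocation"`, `"exploration"`.
#' @examples
#' select_state(0.9, 0.9)  # exploitation wins
#' select_state(0.1, 0.9)  # social relocation
#' select_state(0.5, 0.5)  # strict: still exploration
#' @export
select_state <- function(u, w, threshold_u = 0.5, threshold_w = 0.5) {
  if (u > threshold_u) "exploitation"
  else if (w > threshold_w) "social_relocation"
  else "exploration"
}

#' Indicator triple of a behavioral state
#'
#' @param state a state name as returned by [select_state()].
#' @return Named 0/1 vector `c(a_exp, a_soc, a_ind)` summing to 1.
#' @export
behavior_indicators <- function(state) {
  state <- match.arg(state,
                     c("exploration", "social_relocation", "exploitation"))
  c(a_exp = as.integer(state == "exploration"),
    a_soc = as.integer(state == "social_relocation"),
    a_ind = as.integer(state == "exploitation"))
}

#' Fire the novelty signal on first patch discovery
#'
#' Discovery of a patch whose id has not been seen by this agent during the
#' patch's lifetime starts the novelty window (`novelty_timer = novelty
#' length`) and records the id, so re-entering the same live patch never
#' refires. A regenerated patch carries a fresh id and fires again.
#'
#' @param integrator list with `novelty_timer` (integer) and
#'   `discovered` (integer vector of patch ids).
#' @param patch_id id of the patch just entered.
#' @param novelty_length window length in timesteps (default 10).
#' @return The updated integrator list.
#' @examples
#' s <- list(novelty_timer = 0L, discovered = integer(0))
#' s <- fire_novelty(s, 7)
#' s$novelty_timer
#' fire_novelty(s, 7)$novelty_timer  # no refire on the same lifetime
#' @export
fire_novelty <- function(integrator, patch_id, novelty_length = 10L) {
  if (!(patch_id %in% integrator$discovered)) {
    integrator$novelty_timer <- as.integer(novelty_length)
    integrator$discovered <- c(integrator$discovered, as.integer(patch_id))
  }
  integrator
}
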