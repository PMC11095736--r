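# The per-timestep simulation loop and the three global metrics.

#' Run one foraging simulation
#'
#' Executes `config$n_steps` synchronous timesteps: every agent perceives the
#' same start-of-step snapshot, updates its two integrators, selects a
#' behavioral state and moves; consumption is then resolved sequentially in
#' ascending agent id, depleted patches regenerate at fresh random locations,
#' and per-step ledgers are recorded. Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the run.
#' @param record_traces if `TRUE`, per-agent per-step trajectories and
#'   integrator traces are kept (memory ~ `7 * n_steps * n_agents` doubles).
#' @param arena optional pre-built `forage_arena` overriding the random
#'   initialization (useful for controlled experiments and tests).
#' @param agents optional data.frame with columns `x`, `y`, `theta`, `v`
#'   overriding random agent initialization.
#' @return An object of class `forage_run`: a list with the scalar metrics
#'   `E` (collective search efficiency, units per agent per timestep),
#'   `D_hat` (run-mean inter-individual distance, px), `T_soc` (fraction of
#'   agent-timesteps in social relocation), `n_regen`, per-agent consumption
#'   totals, a per-step `ledger` data.frame (`consumed`, `units_left`,
#'   `regenerations`, state counts, `d_hat`), final `agents` and `patches`
#'   tables, and (optionally) `traces`.
#' @examples
#' run <- sim_run(sim_config(n_agents = 3, n_patches = 3, n_steps = 200),
#'                seed = 1)
#' run$E
#' @export
sim_run <- function(config, seed, record_traces = FALSE,
                    arena = NULL, agents = NULL) {
  validate_sim_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  if (is.null(arena)) arena <- init_environment(config)
  if (is.null(agents)) {
    r <- config$agent_radius
    agents <- data.frame(
      x = runif(config$n_agents, r, config$arena_width - r),
      y = runif(config$n_agents, r, config$arena_height - r),
      theta = runif(config$n_agents, 0, 2 * pi),
      v = rep(config$v_exp, config$n_agents)
    )
  }
  stopifnot(nrow(agents) == config$n_agents)
  p <- arena$patches
  pm <- cbind(p$x, p$y, p$radius, p$units_total, p$units_left, p$quality,
              p$id)
  if (nrow(p) == 0) pm <- matrix(numeric(0), 0, 7)
  am <- cbind(agents$x, agents$y, agents$theta, agents$v)
  raw <- cpp_run_sim(config, pm, am, config$n_steps, isTRUE(record_traces))

  ledger <- data.frame(
    step = seq_len(config$n_steps),
    consumed = raw$led_consumed,
    units_left = raw$led_units,
    regenerations = raw$led_regen,
    n_explore = raw$led_nexp,
    n_social = raw$led_nsoc,
    n_exploit = raw$led_nind,
    d_hat = raw$led_dhat
  )
  patches <- data.frame(
    id = as.integer(raw$patches[, 7]), x = raw$patches[, 1],
    y = raw$patches[, 2], radius = raw$patches[, 3],
    units_total = raw$patches[, 4], units_left = raw$patches[, 5],
    quality = raw$patches[, 6]
  )
  agents_out <- data.frame(
    id = seq_len(config$n_agents), x = raw$agents[, 1], y = raw$agents[, 2],
    theta = raw$agents[, 3], v = raw$agents[, 4], u = raw$agents[, 5],
    w = raw$agents[, 6],
    state = c("exploration", "social_relocation",
              "exploitation")[raw$agents[, 7] + 1]
  )
  out <- list(
    E = raw$E, D_hat = raw$D_hat, T_soc = raw$T_soc,
    total_consumed = raw$total_consumed, n_regen = raw$n_regen,
    consumed_agent = raw$consumed_agent,
    ledger = ledger, agents = agents_out, patches = patches,
    config = config, seed = as.integer(seed)
  )
  if (isTRUE(record_traces)) {
    out$traces <- list(
      x = raw$trace_x, y = raw$trace_y, v = raw$trace_v,
      theta = raw$trace_theta, u = raw$trace_u, w = raw$trace_w,
      state = raw$trace_state
    )
  }
  class(out) <- "forage_run"
  out
}

#' @export
print.forage_run <- function(x, ...) {
  cat("<forage_run>\n")
  cat(sprintf("  N_A = %d, N_R = %d, eps_w = %g, T = %d, seed = %d\n",
              x$config$n_agents, x$config$n_patches, x$config$eps_w,
              x$config$n_steps, x$seed))
  cat(sprintf("  E = %.5f R/agent/ts, D_hat = %s px, T_soc = %.4f\n",
              x$E, ifelse(is.na(x$D_hat), "NA", sprintf("%.1f", x$D_hat)),
              x$T_soc))
  cat(sprintf("  consumed = %.2f units, regenerations = %d\n",
              x$total_consumed, x$n_regen))
  invisible(x)
}

#' Collective search efficiency
#'
#' Resource units collected by the whole group, normalized by group size and
#' run length: `E = sum(consumed) / (n_agents * n_steps)`.
#'
#' @param consumed vector of consumed units (any partition of the total:
#'   per-step, per-agent, or a single total).
#' @param n_agents group size.
#' @param n_steps run length.
#' @return Efficiency in units per agent per timestep.
#' @examples
#' efficiency(5, n_agents = 2, n_steps = 10)
#' @export
efficiency <- function(consumed, n_agents, n_steps) {
  if (n_agents <= 0 || n_steps <= 0) {
    stop("invalid input: `n_agents` and `n_steps` must be positive")
  }
  sum(consumed) / (n_agents * n_steps)
}

#' Mean inter-individual distance at one timestep
#'
#' `2 * sum_{i<j} dist(i, j) / (N_A * (N_A - 1))`; the run-level statistic is
#' this quantity averaged over recorded timesteps.
#'
#' @param positions numeric matrix with one row per agent, columns x and y.
#' @return Mean pairwise Euclidean distance.
#' @examples
#' mean_pairwise_distance(rbind(c(0, 0), c(3, 4)))
#' @export
mean_pairwise_distance <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("undefined metric: need at least two agents")
  d <- stats::dist(positions[, 1:2, drop = FALSE])
  2 * sum(d) / (n * (n - 1))
}

#' Fraction of agent-timesteps spent in social relocation
#'
#' @param states character or integer matrix (timesteps x agents) of
#'   behavioral states, or a `forage_run` ledger data.frame with an
#'   `n_social` column.
#' @param n_agents group size (required for the ledger form).
#' @return Scalar in `[0, 1]`.
#' @export
relocation_time_fraction <- function(states, n_agents = NULL) {
  if (is.data.frame(states)) {
    stopifnot(!is.null(n_agents), "n_social" %in% names(states))
    return(sum(states$n_social) / (n_agents * nrow(states)))
  }
  states <- as.matrix(states)
  soc <- if (is.character(states)) states == "social_relocation"
         else states == 1L
  mean(soc)
}

#' Write the per-run trajectory store to CSV
#'
#' Long-format per-timestep, per-agent table (position, speed, heading,
#' integrators, state) from a run recorded with `record_traces = TRUE`.
#'
#' @param run a `forage_run` with traces.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_traces_csv <- function(run, path) {
  if (is.null(run$traces)) stop("run was not recorded with traces")
  tr <- run$traces
  nT <- nrow(tr$x)
  nA <- ncol(tr$x)
  df <- data.frame(
    step = rep(seq_len(nT), nA),
    agent = rep(seq_len(nA), each = nT),
    x = as.vector(tr$x), y = as.vector(tr$y), v = as.vector(tr$v),
    theta = as.vector(tr$theta), u = as.vector(tr$u), w = as.vector(tr$w),
    state = c("exploration", "social_relocation",
              "exploitation")[as.vector(tr$state) + 1]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
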