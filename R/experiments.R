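# Parameter sweeps across social excitability, environment and group size,
# with replicate aggregation, per-environment normalization and paired
# condition contrasts.

#' Define a sweep grid
#'
#' Builds the full factorial grid over the supplied parameter axes. Every
#' cell is run `replicates` times with seeds
#' `base_seed + (cell - 1) * replicates + (replicate - 1)`, which are disjoint
#' across cells by construction.
#'
#' @param eps_w,n_patches,n_agents,fov_half_angle,patch_radius numeric axes
#'   (any may be a single value).
#' @param occlusion,collisions logical axes.
#' @param replicates runs per cell.
#' @param n_steps timesteps per run.
#' @param base_seed first seed of the grid.
#' @return A `sweep_grid`: a tibble of cells with attributes `replicates`,
#'   `n_steps`, `base_seed`.
#' @examples
#' g <- sweep_grid(eps_w = c(0, 1), n_patches = c(3, 50), replicates = 2,
#'                 n_steps = 200)
#' nrow(g)
#' @export
sweep_grid <- function(eps_w = c(0, 0.25, 0.5, 1, 2, 5),
                       n_patches = c(3, 8, 20, 50),
                       n_agents = 10,
                       fov_half_angle = pi,
                       occlusion = FALSE,
                       collisions = FALSE,
                       patch_radius = 15,
                       replicates = 10,
                       n_steps = 5000,
                       base_seed = 1) {
  grid <- expand.grid(
    eps_w = eps_w, n_patches = n_patches, n_agents = n_agents,
    fov_half_angle = fov_half_angle, occlusion = occlusion,
    collisions = collisions, patch_radius = patch_radius,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- tibble::as_tibble(grid)
  grid$cell <- seq_len(nrow(grid))
  stopifnot(base_seed + nrow(grid) * replicates < 2^31)
  structure(grid, replicates = as.integer(replicates),
            n_steps = as.integer(n_steps),
            base_seed = as.integer(base_seed), class = c("sweep_grid",
                                                         class(grid)))
}

#' Seeds of one sweep cell
#'
#' @param grid a `sweep_grid`.
#' @param cell cell index.
#' @return Integer vector of `replicates` seeds.
#' @export
cell_seeds <- function(grid, cell) {
  reps <- attr(grid, "replicates")
  base <- attr(grid, "base_seed")
  base + (cell - 1L) * reps + seq_len(reps) - 1L
}

#' Run a parameter sweep
#'
#' Executes every cell of the grid `replicates` times and aggregates the
#' global metrics. Cells whose environment cannot be placed (too dense) are
#' reported with `status = "environment_too_dense"` and `NA` metrics instead
#' of aborting the sweep. Results are independent of execution order.
#'
#' @param grid a [sweep_grid()].
#' @param base_config a [sim_config()] supplying all parameters not on a grid
#'   axis.
#' @param progress print one line per cell.
#' @return A `sweep_result` list: `replicates` (one row per run: cell
#'   parameters, seed, E, D_hat, T_soc, status) and `summary` (per-cell n,
#'   mean and sd of each metric).
#' @export
run_sweep <- function(grid, base_config = sim_config(), progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  reps <- attr(grid, "replicates")
  n_steps <- attr(grid, "n_steps")
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cellpar <- grid[ci, ]
    cfg <- base_config
    cfg$eps_w <- cellpar$eps_w
    cfg$n_patches <- as.integer(cellpar$n_patches)
    cfg$n_agents <- as.integer(cellpar$n_agents)
    cfg$fov_half_angle <- cellpar$fov_half_angle
    cfg$occlusion <- isTRUE(cellpar$occlusion)
    cfg$collisions <- isTRUE(cellpar$collisions)
    cfg$patch_radius <- cellpar$patch_radius
    cfg$n_steps <- n_steps
    validate_sim_config(cfg)
    seeds <- cell_seeds(grid, ci)
    if (progress) {
      message(sprintf("cell %d/%d: eps_w=%g N_R=%d N_A=%d", ci, nrow(grid),
                      cfg$eps_w, cfg$n_patches, cfg$n_agents))
    }
    for (ri in seq_along(seeds)) {
      res <- tryCatch(sim_run(cfg, seed = seeds[ri]), error = function(e) e)
      if (inherits(res, "error")) {
        if (!grepl("environment too dense", conditionMessage(res))) {
          stop(res)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell = ci, replicate = ri, seed = seeds[ri],
          cellpar[, setdiff(names(cellpar), "cell")],
          E = NA_real_, D_hat = NA_real_, T_soc = NA_real_,
          status = "environment_too_dense"
        )
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell = ci, replicate = ri, seed = seeds[ri],
          cellpar[, setdiff(names(cellpar), "cell")],
          E = res$E, D_hat = res$D_hat, T_soc = res$T_soc, status = "ok"
        )
      }
    }
  }
  replicates <- dplyr::bind_rows(rows)
  pars <- setdiff(names(grid), "cell")
  per_cell <- split(replicates, replicates$cell)
  summary <- dplyr::bind_rows(lapply(per_cell, function(d) {
    tibble::tibble(
      d[1, c("cell", pars)],
      n = nrow(d),
      E_mean = mean(d$E), E_sd = sd(d$E),
      D_hat_mean = mean(d$D_hat), D_hat_sd = sd(d$D_hat),
      T_soc_mean = mean(d$T_soc), T_soc_sd = sd(d$T_soc)
    )
  }))
  structure(list(replicates = replicates, summary = summary,
                 grid = grid), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  cat(sprintf("  %d cells x %d replicates\n", nrow(x$summary),
              attr(x$grid, "replicates")))
  print(x$summary, n = 10)
  invisible(x)
}

#' Normalize efficiencies per environment
#'
#' Within each environment (each combination of the grouping columns, by
#' default everything except `eps_w` and the metric columns), mean search
#' efficiency is min-max rescaled to `[0, 1]`, so the least efficient social
#' excitability level maps to 0 and the most efficient to 1. A constant
#' column is set to 0 with a warning.
#'
#' @param result a `sweep_result` or its `summary` tibble.
#' @param value column to rescale (default `"E_mean"`).
#' @param within grouping columns defining one environment column; default:
#'   all cell parameters except `eps_w`.
#' @return The summary tibble with an added `<value>_rel` column.
#' @export
normalize_per_environment <- function(result, value = "E_mean",
                                      within = NULL) {
  summary <- if (inherits(result, "sweep_result")) result$summary else result
  stopifnot(value %in% names(summary))
  metric_cols <- c("cell", "n", grep("_(mean|sd|rel)$", names(summary),
                                     value = TRUE))
  if (is.null(within)) {
    within <- setdiff(names(summary), c(metric_cols, "eps_w"))
  }
  groups <- if (length(within) == 0) rep(1L, nrow(summary)) else
    interaction(summary[within], drop = TRUE)
  rel <- numeric(nrow(summary))
  constant <- FALSE
  for (g in split(seq_len(nrow(summary)), groups)) {
    v <- summary[[value]][g]
    rng <- range(v)
    if (diff(rng) == 0) {
      constant <- TRUE
      rel[g] <- 0
    } else {
      rel[g] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (constant) {
    warning("constant environment column; normalized values set to 0",
            call. = FALSE)
  }
  summary[[paste0(value, "_rel")]] <- rel
  summary
}

#' Contrast two sweep conditions cell by cell
#'
#' Pairs the cells of two sweeps that share all axes except the toggled
#' condition (for example occlusion on vs off) and reports the difference in
#' mean metric with its pooled standard error
#' `sqrt(sd_a^2 / n_a + sd_b^2 / n_b)`.
#'
#' @param result_a,result_b `sweep_result` objects over matching grids.
#' @param metric one of `"E"`, `"D_hat"`, `"T_soc"`.
#' @return Tibble with the shared cell parameters, the two means, `delta`
#'   (a minus b) and `pooled_se`.
#' @export
compare_conditions <- function(result_a, result_b, metric = "E") {
  metric <- match.arg(metric, c("E", "D_hat", "T_soc"))
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  a <- result_a$summary
  b <- result_b$summary
  keys <- intersect(names(a), c("eps_w", "n_patches", "n_agents",
                                "fov_half_angle", "patch_radius"))
  keys <- keys[vapply(keys, function(k) {
    length(unique(c(a[[k]], b[[k]]))) > 0
  }, logical(1))]
  if (nrow(a) != nrow(b)) stop("invalid comparison: grids do not match")
  j <- dplyr::inner_join(
    a[, c(keys, "n", mcol, scol)],
    b[, c(keys, "n", mcol, scol)],
    by = keys, suffix = c("_a", "_b")
  )
  if (nrow(j) != nrow(a)) stop("invalid comparison: grids do not match")
  j$delta <- j[[paste0(mcol, "_a")]] - j[[paste0(mcol, "_b")]]
  j$pooled_se <- sqrt(j[[paste0(scol, "_a")]]^2 / j$n_a +
                      j[[paste0(scol, "_b")]]^2 / j$n_b)
  j
}

#' Tidy replicate table of a sweep
#'
#' @param result a `sweep_result`.
#' @param path optional CSV path; written when supplied.
#' @return The replicate tibble (invisibly when `path` is given).
#' @export
sweep_results_csv <- function(result, path = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  if (!is.null(path)) {
    utils::write.csv(result$replicates, path, row.names = FALSE)
    return(invisible(result$replicates))
  }
  result$replicates
}
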