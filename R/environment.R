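# Arena and resource patches: placement, depletion, regeneration.

#' Resource units per patch
#'
#' The total resource budget of the arena is divided equally among patches, so
#' patchy environments (few patches) hold rich patches and uniform environments
#' (many patches) hold poor ones: 2400 units over 3 patches gives 800 units
#' each, over 50 patches 48 units each.
#'
#' @param total_units total resource units in the arena.
#' @param n_patches number of patches (>= 1).
#' @return Units per patch, `total_units / n_patches`.
#' @examples
#' units_per_patch(2400, 3)
#' units_per_patch(2400, 50)
#' @export
units_per_patch <- function(total_units, n_patches) {
  if (!is.numeric(n_patches) || length(n_patches) != 1 || n_patches < 1) {
    stop("invalid configuration: `n_patches` must be >= 1")
  }
  if (!is.numeric(total_units) || length(total_units) != 1 ||
      total_units <= 0) {
    stop("invalid configuration: `total_units` must be positive")
  }
  total_units / n_patches
}

#' Packing fraction of disks in the arena
#'
#' Proportion of the arena surface covered by `n` non-overlapping disks:
#' \eqn{n \pi r^2 / (W H)}.
#'
#' @param n number of disks (>= 0).
#' @param radius disk radius in pixels.
#' @param width,height arena dimensions in pixels.
#' @return Dimensionless fraction.
#' @examples
#' packing_fraction(100, 10, 500, 500) # ~0.126
#' packing_fraction(3, 15, 500, 500)   # ~0.008
#' @export
packing_fraction <- function(n, radius, width, height) {
  if (!is.numeric(radius) || radius <= 0 || !is.numeric(width) ||
      width <= 0 || !is.numeric(height) || height <= 0) {
    stop("invalid configuration: geometry must be positive")
  }
  if (!is.numeric(n) || any(n < 0)) {
    stop("invalid configuration: `n` must be non-negative")
  }
  n * pi * radius^2 / (width * height)
}

# uniform draw of a patch centre fully inside the arena, rejecting overlap
# with the patches in `others` (data.frame with x, y, radius)
draw_patch_center <- function(radius, width, height, others, max_attempts) {
  for (att in seq_len(max_attempts)) {
    cx <- runif(1, radius, width - radius)
    cy <- runif(1, radius, height - radius)
    if (nrow(others) == 0) return(c(cx, cy))
    d2 <- (others$x - cx)^2 + (others$y - cy)^2
    if (all(d2 >= (others$radius + radius)^2)) return(c(cx, cy))
  }
  stop("environment too dense: could not place patch without overlap")
}

#' Initialize the foraging arena
#'
#' Places `n_patches` non-overlapping circular patches uniformly at random,
#' fully inside the arena (centres at least one patch radius from every wall).
#' Each patch starts full with an equal share of the total resource budget.
#' Uses the current R random stream; call `set.seed()` for reproducibility.
#'
#' @param config a [sim_config()].
#' @return A list of class `forage_arena` with elements `width`, `height` and
#'   `patches` (data.frame: `id`, `x`, `y`, `radius`, `units_total`,
#'   `units_left`, `quality`).
#' @examples
#' set.seed(1)
#' arena <- init_environment(sim_config(n_patches = 3))
#' arena$patches$units_left
#' @export
init_environment <- function(config) {
  validate_sim_config(config)
  n <- config$n_patches
  per <- if (n > 0) units_per_patch(config$total_units, n) else numeric(0)
  patches <- data.frame(
    id = integer(0), x = numeric(0), y = numeric(0), radius = numeric(0),
    units_total = numeric(0), units_left = numeric(0), quality = numeric(0)
  )
  for (j in seq_len(n)) {
    ctr <- draw_patch_center(config$patch_radius, config$arena_width,
                             config$arena_height, patches,
                             config$max_place_attempts)
    patches <- rbind(patches, data.frame(
      id = j, x = ctr[1], y = ctr[2], radius = config$patch_radius,
      units_total = per, units_left = per, quality = config$quality
    ))
  }
  structure(list(width = config$arena_width, height = config$arena_height,
                 patches = patches, max_place_attempts =
                   config$max_place_attempts),
            class = "forage_arena")
}

#' Replace a depleted patch at a fresh random location
#'
#' The depleted patch is removed and a full patch of the same size and budget
#' appears at a uniform random location that does not overlap any surviving
#' patch, so the number of live patches is conserved. The replacement gets a
#' fresh id: agents treat it as a new discovery.
#'
#' @param arena a `forage_arena`.
#' @param patch_id id of the depleted patch (`units_left` must be 0).
#' @return The updated arena.
#' @export
regenerate_patch <- function(arena, patch_id) {
  stopifnot(inherits(arena, "forage_arena"))
  idx <- match(patch_id, arena$patches$id)
  if (is.na(idx)) stop("no patch with id ", patch_id)
  if (arena$patches$units_left[idx] != 0) {
    stop("contract violation: patch ", patch_id, " is not depleted")
  }
  old <- arena$patches[idx, ]
  survivors <- arena$patches[-idx, ]
  ctr <- draw_patch_center(old$radius, arena$width, arena$height, survivors,
                           arena$max_place_attempts)
  fresh <- old
  fresh$id <- max(arena$patches$id) + 1L
  fresh$x <- ctr[1]
  fresh$y <- ctr[2]
  fresh$units_left <- fresh$units_total
  arena$patches[idx, ] <- fresh
  arena
}

#' Resolve one timestep of consumption
#'
#' Each exploiting agent consumes up to the patch quality \eqn{Q_j} from the
#' patch it overlaps; when fewer units remain than the demand, the remainder is
#' consumed. With several agents on one patch, consumption is sequential in
#' ascending agent id, so late ids may receive less (or nothing) on the final
#' units of a patch.
#'
#' @param arena a `forage_arena`.
#' @param exploiting data.frame with columns `agent` (id, used for ordering)
#'   and `patch` (patch id the agent overlaps). May have zero rows.
#' @return List with `arena` (units decremented) and `consumed`, a numeric
#'   vector of per-agent consumed units named by agent id.
#' @examples
#' set.seed(1)
#' arena <- init_environment(sim_config(n_patches = 1))
#' out <- consume_step(arena, data.frame(agent = 1, patch = 1))
#' out$consumed
#' @export
consume_step <- function(arena, exploiting) {
  stopifnot(inherits(arena, "forage_arena"))
  if (is.null(exploiting) || nrow(exploiting) == 0) {
    return(list(arena = arena, consumed = setNames(numeric(0), character(0))))
  }
  stopifnot(all(c("agent", "patch") %in% names(exploiting)))
  ord <- order(exploiting$agent)
  exploiting <- exploiting[ord, , drop = FALSE]
  consumed <- setNames(numeric(nrow(exploiting)),
                       as.character(exploiting$agent))
  for (r in seq_len(nrow(exploiting))) {
    idx <- match(exploiting$patch[r], arena$patches$id)
    if (is.na(idx)) stop("contract violation: unknown patch id")
    q <- min(arena$patches$quality[idx], arena$patches$units_left[idx])
    arena$patches$units_left[idx] <- arena$patches$units_left[idx] - q
    consumed[r] <- q
  }
  list(arena = arena, consumed = consumed)
}

#' Write per-patch state to a data.frame row set
#'
#' Small helper mirroring the per-timestep patch table recorded by the engine;
#' convenient for CSV export of arena snapshots.
#'
#' @param arena a `forage_arena`.
#' @param step integer timestep label attached to each row.
#' @return data.frame with `step`, `id`, `x`, `y`, `radius`, `units_left`.
#' @export
arena_snapshot <- function(arena, step = 0L) {
  p <- arena$patches
  data.frame(step = as.integer(step), id = p$id, x = p$x, y = p$y,
             radius = p$radius, units_left = p$units_left)
}
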