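# Independent per-bin ray-casting oracle for the visual projection fields.
# For every bin, a ray is cast at the bin's centre angle; each agent disk is
# tested for intersection and the nearest hit wins. This enumerates the optics
# directly, without the interval arithmetic of the implementation.

oracle_project_social <- function(focal, agents, agent_radius = 10,
                                  fov_half_angle = pi, occlusion = FALSE,
                                  resolution = 2000L) {
  K <- as.integer(resolution)
  binw <- 2 * pi / K
  phi <- -pi + (seq_len(K) - 0.5) * binw
  a <- focal$theta + phi
  rx <- cos(a)
  ry <- sin(a)
  n <- nrow(agents)
  fpatch <- if (!is.null(focal$patch)) focal$patch else NA
  depth <- matrix(Inf, K, max(n, 1))
  hit <- matrix(FALSE, K, max(n, 1))
  tgt <- logical(n)
  for (j in seq_len(n)) {
    dx <- agents$x[j] - focal$x
    dy <- agents$y[j] - focal$y
    proj <- dx * rx + dy * ry
    perp <- dx * ry - dy * rx
    rem <- agent_radius^2 - perp^2
    h <- proj > 0 & rem >= 0
    tt <- proj - sqrt(pmax(rem, 0))
    depth[h, j] <- tt[h]
    hit[, j] <- h
    pj <- if ("patch" %in% names(agents)) agents$patch[j] else NA
    tgt[j] <- isTRUE(as.logical(agents$exploiting[j])) &&
      !(!is.na(fpatch) && !is.na(pj) && pj == fpatch)
  }
  field <- integer(K)
  if (n > 0) {
    if (occlusion) {
      anyh <- rowSums(hit) > 0
      jmin <- max.col(-depth, ties.method = "first")  # row-wise which.min
      field[anyh & tgt[jmin]] <- 1L
    } else if (any(tgt)) {
      field[rowSums(hit[, tgt, drop = FALSE]) > 0] <- 1L
    }
  }
  field[abs(phi) > fov_half_angle] <- 0L
  field
}

oracle_proximity <- function(focal, agents, agent_radius = 10,
                             sense_range = 2, resolution = 2000L) {
  d <- sqrt((agents$x - focal$x)^2 + (agents$y - focal$y)^2)
  sub <- agents[d <= 2 * agent_radius + sense_range, , drop = FALSE]
  if (nrow(sub) == 0) return(integer(resolution))
  sub$exploiting <- TRUE
  sub$patch <- NA
  oracle_project_social(list(x = focal$x, y = focal$y, theta = focal$theta),
                        sub, agent_radius, pi, FALSE, resolution)
}

# random scene of n agents in mixed behavioral states; first agent is focal
random_scene <- function(seed, n = 10, width = 500, height = 500,
                         p_exploit = 0.4) {
  set.seed(seed)
  data.frame(
    x = runif(n, 0, width),
    y = runif(n, 0, height),
    theta = runif(n, 0, 2 * pi),
    exploiting = runif(n) < p_exploit,
    patch = sample(c(NA, 1L, 2L, 3L), n, replace = TRUE)
  )
}

# small fast configuration for engine tests
quick_config <- function(...) {
  sim_config(n_agents = 5, n_patches = 3, eps_w = 1, n_steps = 300, ...)
}

# hand-built arena for environment unit tests
make_arena <- function(patches, width = 500, height = 500) {
  structure(list(width = width, height = height, patches = patches,
                 max_place_attempts = 10000L),
            class = "forage_arena")
}
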