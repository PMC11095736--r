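test_that("a disk subtends the tangent-line half-angle asin(R/d)", {
  focal <- list(x = 0, y = 0, theta = 0)
  iv <- angular_interval(focal, list(x = 20, y = 0), agent_radius = 10)
  expect_equal(iv$half_width, pi / 6)          # full width pi/3 at d = 2R
  expect_equal(iv$bearing, 0)

  expect_equal(angular_interval(focal, list(x = 10, y = 0), 10)$half_width,
               pi / 2)                          # touching body: asin(1)
  far <- angular_interval(focal, list(x = 1e6 * 10, y = 0), 10)
  expect_lt(far$half_width, 2 * pi / 2000)      # at most one bin at K = 2000
  expect_error(angular_interval(focal, list(x = 0, y = 0), 10),
               "degenerate")
})

test_that("social field marks exploiting agents and honours exclusions", {
  focal <- list(x = 250, y = 250, theta = 0)
  none <- data.frame(x = c(300, 200), y = c(250, 250),
                     exploiting = c(FALSE, FALSE), patch = c(NA, NA))
  expect_equal(sum(project_social(focal, none)), 0)

  one <- data.frame(x = 350, y = 250, exploiting = TRUE, patch = 1)
  f <- project_social(focal, one)
  expect_gt(sum(f), 0)
  expect_true(all(f %in% 0:1))

  # same-patch co-exploiters are ignored as targets
  focal_on1 <- list(x = 250, y = 250, theta = 0, patch = 1)
  expect_equal(sum(project_social(focal_on1, one)), 0)

  # empty agent set allowed
  expect_equal(project_social(focal, one[0, ]), integer(2000))
})

test_that("a nearer body occludes a collinear exploiter; without occlusion it
           shines through", {
  focal <- list(x = 0, y = 250, theta = 0)
  scene <- data.frame(x = c(50, 100), y = c(250, 250),
                      exploiting = c(FALSE, TRUE), patch = c(NA, 1))
  blocked <- project_social(focal, scene, occlusion = TRUE)
  open <- project_social(focal, scene, occlusion = FALSE)
  expect_equal(sum(blocked), 0)
  expect_gt(sum(open), 0)
})

test_that("the field of view window blinds the rear", {
  focal <- list(x = 250, y = 250, theta = 0)
  behind <- data.frame(x = 150, y = 250, exploiting = TRUE, patch = 1)
  expect_equal(sum(project_social(focal, behind, fov_half_angle = pi / 2)), 0)
  expect_gt(sum(project_social(focal, behind, fov_half_angle = pi)), 0)
  # fov 0 means fully blind
  ahead <- data.frame(x = 350, y = 250, exploiting = TRUE, patch = 1)
  expect_equal(sum(project_social(focal, ahead, fov_half_angle = 0)), 0)
})

test_that("hemisphere difference is the left mean minus the right mean", {
  K <- 2000
  phi <- -pi + (seq_len(K) - 0.5) * (2 * pi / K)
  expect_equal(hemisphere_difference(integer(K)), 0)
  expect_equal(hemisphere_difference(as.integer(phi > 0)), 1)
  expect_equal(hemisphere_difference(as.integer(phi < 0)), -1)
  set.seed(99)
  f <- as.integer(runif(K) < 0.3)
  expect_equal(hemisphere_difference(f),
               mean(f[phi > 0]) - mean(f[phi < 0]))
  # mirror-symmetric field cancels
  sym <- as.integer(abs(phi) < 0.5)
  expect_equal(hemisphere_difference(sym), 0)
})

test_that("proximity field sees only bodies within the sensing gap", {
  focal <- list(x = 250, y = 250, theta = 0)
  far <- data.frame(x = 250 + 23.1, y = 250)  # gap 3.1 px > 2 px
  expect_equal(sum(proximity_field(focal, far)), 0)

  near <- data.frame(x = 250 + 21, y = 250)   # gap 1 px, dead ahead
  f <- proximity_field(focal, near)
  K <- length(f)
  phi <- -pi + (seq_len(K) - 0.5) * (2 * pi / K)
  expect_gt(sum(f), 0)
  expect_true(all(abs(phi[f == 1]) < pi / 2))
  # symmetric about the heading (up to one-bin quantization)
  expect_lte(sum(f != rev(f)), 2)
})

test_that("occlusion and field-of-view narrowing only remove bins", {
  for (s in 1:25) {
    sc <- random_scene(s)
    focal <- list(x = sc$x[1], y = sc$y[1], theta = sc$theta[1],
                  patch = sc$patch[1])
    others <- sc[-1, ]
    f_occ <- project_social(focal, others, occlusion = TRUE)
    f_open <- project_social(focal, others, occlusion = FALSE)
    expect_true(all(f_occ <= f_open))
    L <- runif(1, 0, pi)
    f_nar <- project_social(focal, others, fov_half_angle = L / 2)
    f_wid <- project_social(focal, others, fov_half_angle = L)
    expect_true(all(f_nar <= f_wid))
  }
})

test_that("projection width shrinks with distance and rotates with the
           scene", {
  focal <- list(x = 0, y = 0, theta = 0)
  widths <- sapply(c(25, 50, 100, 200, 400), function(d) {
    sum(project_social(focal,
                       data.frame(x = d, y = 0, exploiting = TRUE,
                                  patch = 1)))
  })
  expect_true(all(diff(widths) < 0))

  # rotating agent positions about the focal point shifts the field
  # circularly by the same number of bins
  K <- 2000L
  binw <- 2 * pi / K
  sc <- random_scene(7)
  focal <- list(x = sc$x[1], y = sc$y[1], theta = sc$theta[1])
  others <- sc[-1, ]
  f0 <- project_social(focal, others, resolution = K)
  m <- 137L
  delta <- m * binw
  rot <- others
  rot$x <- focal$x + cos(delta) * (others$x - focal$x) -
    sin(delta) * (others$y - focal$y)
  rot$y <- focal$y + sin(delta) * (others$x - focal$x) +
    cos(delta) * (others$y - focal$y)
  f1 <- project_social(focal, rot, resolution = K)
  shifted <- c(tail(f0, -(K - m)), head(f0, K - m))  # circular shift by +m
  expect_lte(sum(f1 != shifted), 4)  # one-bin quantization slack per edge
})

test_that("projection fields match the per-bin ray-casting oracle exactly", {
  for (s in 1:100) {
    sc <- random_scene(s, n = 10)
    focal <- list(x = sc$x[1], y = sc$y[1], theta = sc$theta[1],
                  patch = sc$patch[1])
    others <- sc[-1, ]
    L <- if (s %% 3 == 0) pi else runif(1, 0, pi)
    for (occ in c(FALSE, TRUE)) {
      impl <- project_social(focal, others, fov_half_angle = L,
                             occlusion = occ, resolution = 500L)
      orc <- oracle_project_social(focal, others, fov_half_angle = L,
                                   occlusion = occ, resolution = 500L)
      expect_identical(impl, orc)
    }
  }
  # proximity field against the same oracle restricted to the sensing range
  for (s in 1:50) {
    set.seed(s)
    n <- 10
    sc <- data.frame(x = runif(n, 0, 80), y = runif(n, 0, 80))
    focal <- list(x = sc$x[1], y = sc$y[1], theta = runif(1, 0, 2 * pi))
    others <- sc[-1, ]
    impl <- proximity_field(focal, others, resolution = 500L)
    orc <- oracle_proximity(focal, others, resolution = 500L)
    expect_identical(impl, orc)
  }
})
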