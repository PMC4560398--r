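test_that("arena configuration validates its geometry", {
  cfg <- arena_config()
  expect_equal(cfg$zone_centers, matrix(c(27.5, 55, 82.5, 55), 2, 2,
                                        byrow = TRUE))
  expect_error(arena_config(zone_centers = matrix(c(5, 5, 50, 50), 2, 2,
                                                  byrow = TRUE)),
               "inside the arena")
  expect_error(arena_config(robot_diameter = 30), NULL)
  # default zones are disjoint: no point can be inside both
  d <- sqrt(sum((cfg$zone_centers[1, ] - cfg$zone_centers[2, ])^2))
  expect_gt(d, cfg$zone_diameter)
})

test_that("initial placement is deterministic, non-overlapping and in-bounds", {
  cfg <- arena_config()
  w1 <- init_world(cfg, 7)
  w2 <- init_world(cfg, 7)
  expect_identical(w1, w2)
  expect_false(identical(w1, init_world(cfg, 8)))
  for (s in 1:50) {
    w <- init_world(cfg, s)
    d <- as.matrix(dist(w$poses[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] >= cfg$robot_diameter))
    r <- cfg$robot_diameter / 2
    expect_true(all(w$poses$x >= r & w$poses$x <= cfg$side_length - r))
    expect_true(all(w$poses$y >= r & w$poses$y <= cfg$side_length - r))
    expect_true(all(w$poses$heading >= 0 & w$poses$heading < 2 * pi))
  }
})

test_that("initial positions are uniform over the arena (chi-square)", {
  cfg <- arena_config()
  n <- 2500
  xs <- ys <- numeric(n * 4)
  for (s in seq_len(n)) {
    w <- init_world(cfg, s)
    xs[(s - 1) * 4 + 1:4] <- w$poses$x
    ys[(s - 1) * 4 + 1:4] <- w$poses$y
  }
  # 4 x 4 grid over the reachable band [r, L - r]
  r <- cfg$robot_diameter / 2
  cut4 <- function(v) findInterval(v, seq(r, cfg$side_length - r,
                                          length.out = 5),
                                   all.inside = TRUE)
  counts <- table(factor(cut4(xs), 1:4), factor(cut4(ys), 1:4))
  p <- suppressWarnings(chisq.test(counts)$p.value)
  # independence test is a proxy; also test marginal uniformity directly
  pu <- chisq.test(as.vector(counts), p = rep(1 / 16, 16))$p.value
  expect_gt(pu, 0.01)
})

test_that("straight motion and spin-in-place are exact", {
  cfg <- arena_config()
  p <- step_kinematics(c(10, 20, pi / 6), 1.0, 1.0, cfg)
  expect_equal(unname(p), c(10 + cos(pi / 6), 20 + sin(pi / 6), pi / 6))
  p <- step_kinematics(c(10, 20, 1.0), -0.7, 0.7, cfg)
  expect_equal(unname(p[1:2]), c(10, 20))
  expect_equal(unname(p[3]), 1.0 + 2 * 0.7 / 5.5)
})

test_that("closed-form arcs match a fine-step Euler oracle", {
  cfg <- arena_config()
  euler <- function(pose, vl, vr, n_sub = 1000) {
    v <- (vl + vr) / 2
    w <- (vr - vl) / cfg$robot_diameter
    for (k in seq_len(n_sub)) {
      pose[1] <- pose[1] + (v / n_sub) * cos(pose[3])
      pose[2] <- pose[2] + (v / n_sub) * sin(pose[3])
      pose[3] <- pose[3] + w / n_sub
    }
    pose
  }
  # canonical case: one wheel driven, 100 steps
  pa <- pe <- c(0, 0, 0)
  for (t in 1:100) {
    pa <- step_kinematics(pa, 0, 1, cfg)
    pe <- euler(pe, 0, 1)
  }
  expect_lt(max(abs(pa[1:2] - pe[1:2])), 1e-3)
  # random control sequences
  set.seed(42)
  for (rep in 1:20) {
    pa <- pe <- c(runif(2, 10, 100), runif(1, 0, 2 * pi))
    for (t in 1:100) {
      v <- runif(2, -1.3, 1.3)
      pa <- step_kinematics(pa, v[1], v[2], cfg)
      pe <- euler(pe, v[1], v[2])
    }
    expect_lt(max(abs(pa[1:2] - pe[1:2])), 1e-3)
  }
})

test_that("collision resolution separates robots and leaves legal states alone", {
  cfg <- arena_config()
  w <- init_world(cfg, 3)
  # no overlaps: untouched
  expect_identical(resolve_collisions(w, cfg, 99)$poses, w$poses)
  # two robots 3 cm apart
  w$poses$x <- c(50, 53, 20, 90)
  w$poses$y <- c(50, 50, 20, 90)
  out <- resolve_collisions(w, cfg, 99)
  d <- as.matrix(dist(out$poses[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= cfg$robot_diameter))
  # robot centered 1 cm from the wall: chassis fully inside afterwards
  w$poses$x <- c(1, 40, 60, 90)
  out <- resolve_collisions(w, cfg, 5)
  r <- cfg$robot_diameter / 2
  expect_true(all(out$poses$x >= r & out$poses$x <= cfg$side_length - r))
  expect_true(all(out$poses$y >= r & out$poses$y <= cfg$side_length - r))
  # deterministic given the seed
  expect_identical(resolve_collisions(w, cfg, 5), out)
})

test_that("poses stay in bounds over long random-control runs", {
  cfg <- short_config(2000)
  set.seed(5)
  team <- genotype_team(random_genotype(4))
  res <- simulate_trial(team, cfg, seed = 11, keep_log = TRUE)
  r <- cfg$robot_diameter / 2
  xs <- res$log$pose[, 1:4]
  ys <- res$log$pose[, 5:8]
  expect_true(all(xs >= r - 1e-9 & xs <= cfg$side_length - r + 1e-9))
  expect_true(all(ys >= r - 1e-9 & ys <= cfg$side_length - r + 1e-9))
})

test_that("zone membership uses the half-open robot-center convention", {
  cfg <- arena_config()
  expect_equal(in_zone(cfg$zone_centers[1, ], cfg), 1L)
  expect_equal(in_zone(cfg$zone_centers[2, ], cfg), 2L)
  expect_equal(in_zone(c(55, 55), cfg), NA_integer_)
  # 11.01 cm from a center: outside
  expect_equal(in_zone(cfg$zone_centers[1, ] + c(11.01, 0), cfg), NA_integer_)
  expect_equal(in_zone(cfg$zone_centers[1, ] + c(11, 0), cfg), NA_integer_)
  expect_equal(in_zone(cfg$zone_centers[1, ] + c(10.99, 0), cfg), 1L)
})
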