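test_that("barycenter and euclidean distance match hand arithmetic", {
  expect_equal(unname(barycenter(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))),
               c(1, 1))
  expect_equal(unname(barycenter(c(3.2, -1))), c(3.2, -1))
  expect_equal(unname(barycenter(rbind(c(1, 0), c(0, 1), c(2, 5), c(5, 2)))),
               c(2, 2))
  expect_error(barycenter(matrix(numeric(0), 0, 2)), "empty")
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(7, 7), c(7, 7)), 0)
  expect_equal(euclidean_distance(c(1, 1), c(4, 5)), 5)
  # barycenter lies in the convex hull (bounding box suffices for axis checks)
  set.seed(12)
  for (i in 1:200) {
    pts <- matrix(runif(8, 0, 110), 4, 2)
    b <- barycenter(pts)
    expect_true(b[1] >= min(pts[, 1]) && b[1] <= max(pts[, 1]))
    expect_true(b[2] >= min(pts[, 2]) && b[2] <= max(pts[, 2]))
  }
})

test_that("leadership measure is the population sd of the quadruple", {
  expect_equal(leadership_measure(c(5, 5, 5, 5)), 0)
  expect_equal(leadership_measure(c(2, 6, 6, 6)), sqrt(3))
  q <- c(3, 9, 14, 22)
  expect_equal(leadership_measure(3 * q), 3 * leadership_measure(q))
  expect_equal(leadership_measure(q + 100), leadership_measure(q))
})

test_that("pinned-robot barycenter distance has its closed form on orbits", {
  cfg <- arena_config(steps_per_trial = 200)
  ctr <- c(55, 55)
  steps <- 200
  phi <- seq(0, 4 * pi, length.out = steps + 1)
  orbit_path <- function(offset, radius = 10)
    cbind(ctr[1] + radius * cos(phi + offset), ctr[2] + radius * sin(phi + offset))
  # three followers equally spaced on the orbit: their centroid is the
  # center, so the 4-point barycenter sits exactly on the pinned robot
  log_sym <- log_from_paths(list(path_at(ctr, steps),
                                 orbit_path(0), orbit_path(2 * pi / 3),
                                 orbit_path(4 * pi / 3)),
                            cfg, pinned = 1)
  expect_equal(trial_stats(log_sym)$mean_dist_barycenter[1], 0,
               tolerance = 1e-9)
  # three followers clustered at one orbit angle: barycenter at 3/4 of the
  # orbit radius from the pinned robot
  log_clu <- log_from_paths(list(path_at(ctr, steps), orbit_path(0),
                                 orbit_path(0), orbit_path(0)),
                            cfg, pinned = 1)
  expect_equal(trial_stats(log_clu)$mean_dist_barycenter[1], 7.5,
               tolerance = 1e-9)
  # free robots parked in a far corner: pinned value at least half the
  # corner distance
  corner <- c(100, 100)
  log_far <- log_from_paths(list(path_at(ctr, steps), path_at(corner, steps),
                                 path_at(corner + c(-6, 0), steps),
                                 path_at(corner + c(0, -6), steps)),
                            cfg, pinned = 1)
  d_corner <- euclidean_distance(ctr, corner)
  expect_gt(trial_stats(log_far)$mean_dist_barycenter[1], d_corner / 2)
})

test_that("the barycenter test finds the constructed leader on fixtures", {
  cfg <- short_config(500)
  fx <- make_fixture("passive_leader_group", cfg, seed = 1)
  bq <- barycenter_test(fx$replication, cfg, n_generations = 1, n_trials = 3,
                        seed = 5)
  expect_s3_class(bq, "barycenter_quadruple")
  expect_equal(identify_leader(bq), "green")
  expect_equal(which.min(as.numeric(bq)), 1L)
})

test_that("leaderless groups score lower leadership than led groups", {
  cfg <- short_config(500)
  led <- make_fixture("passive_leader_group", cfg, seed = 2)
  none <- make_fixture("leaderless_group", cfg, seed = 2)
  lm_led <- leadership_measure(
    barycenter_test(led$replication, cfg, 1, n_trials = 3, seed = 7))
  lm_none <- leadership_measure(
    barycenter_test(none$replication, cfg, 1, n_trials = 3, seed = 7))
  expect_lt(lm_none, lm_led)
})

test_that("individual fitness counts zone steps with the expected extremes", {
  cfg <- arena_config(steps_per_trial = 120)
  z1 <- cfg$zone_centers[1, ]
  log <- log_from_paths(list(path_at(z1, 120), path_at(c(55, 10), 120),
                             path_at(c(5, 5), 120), path_at(z1 + c(3, 0), 120)),
                        cfg)
  st <- trial_stats(log, fitness_mode = "individual")
  expect_equal(st$fitness, c(120, 0, 0, 120))
  expect_equal(st$steps_in_zone, c(120, 0, 0, 120))
})

test_that("collective fitness indicator averages the last generations", {
  fake <- structure(list(group_fitness = rep(250, 40), generations = 40L),
                    class = "replication_result")
  expect_equal(collective_fitness_indicator(fake), 250)
  fake$group_fitness <- c(rep(0, 20), 100 * (1:20))
  expect_equal(collective_fitness_indicator(fake), 1050)
  mono <- structure(list(group_fitness = seq(0, 390, by = 10),
                         generations = 40L), class = "replication_result")
  expect_gte(collective_fitness_indicator(mono),
             mean(mono$group_fitness[1:20]))
  expect_error(collective_fitness_indicator(
    structure(list(group_fitness = 1:5), class = "replication_result")),
    "fewer")
})

test_that("follower reaching time matches its kinematic closed form", {
  cfg <- arena_config(steps_per_trial = 300, wheel_speed_max = 1.1)
  ctr <- c(55, 55)
  # follower starts 55 cm away driving straight at the pinned leader
  team <- scripted_team(list(
    scripted_controller("stationary"),
    scripted_controller("goto_point", target = ctr),
    scripted_controller("stationary"),
    scripted_controller("stationary")))
  # follower placed 55 cm from the center along the diagonal, facing it
  init <- pose_matrix(c(55, 55, 0),
                      c(55 + 55 / sqrt(2), 55 + 55 / sqrt(2), 5 * pi / 4),
                      c(10, 10, 0), c(100, 10, 0))
  res <- simulate_trial(team, cfg, seed = 1, pinned = 1, init_poses = init)
  # (55 - 11) / 1.1 = 40 steps
  expect_lte(abs(res$first_reach_step[2] - 40), 2)
  # stationary followers never reach: censored at the trial length
  expect_equal(res$first_reach_step[3], 300)
  expect_equal(res$first_reach_step[4], 300)
  # a follower already within reach reports 0
  init0 <- init
  init0[3, ] <- c(60, 55, 0)
  res0 <- simulate_trial(team, cfg, seed = 1, pinned = 1, init_poses = init0)
  expect_equal(res0$first_reach_step[3], 0)
})

test_that("capability of followers averages reach times over trials", {
  cfg <- short_config(400)
  fx <- make_fixture("follower_only", cfg, seed = 3)
  cap <- capability_of_followers(fx$replication, "green", cfg, n_trials = 3,
                                 seed = 11)
  expect_true(cap > 0 && cap < 400)
})

test_that("mobility counts distinct grid cells", {
  cfg <- arena_config(steps_per_trial = 220)
  # stationary robot: one cell
  log1 <- log_from_paths(list(path_at(c(30, 30), 220), path_at(c(80, 80), 220),
                              path_at(c(20, 80), 220), path_at(c(80, 20), 220)),
                         cfg)
  expect_equal(mobility_of_leaders(list(log1), "green"), 1)
  # a robot traversing one full row of the arena: 110 / 5.5 = 20 cells
  xs <- seq(0.5, 109.5, length.out = 221)
  row_path <- cbind(xs, rep(30, 221))
  log2 <- log_from_paths(list(row_path, path_at(c(80, 80), 220),
                              path_at(c(20, 80), 220), path_at(c(80, 20), 220)),
                         cfg)
  expect_equal(mobility_of_leaders(list(log2), "green"), 20)
  expect_lte(max(trial_stats(log2)$cells_visited, na.rm = TRUE), 400)
})

test_that("vision counts exactly the constructed exposure", {
  cfg <- arena_config(steps_per_trial = 2000)
  steps <- 2000
  sens <- matrix(0, steps, 72)
  sens[1:1500, 2] <- 1  # green channel of photoreceptor 0, robot 1
  paths <- lapply(list(c(30, 30), c(80, 80), c(20, 80), c(80, 20)), path_at,
                  steps = steps)
  log <- log_from_paths(paths, cfg)
  log$sensors <- sens
  expect_equal(vision_of_leaders(list(log), "green"), 1500)
  # a leader alone in the arena sees nothing
  log$sensors <- matrix(0, steps, 72)
  expect_equal(vision_of_leaders(list(log), "green"), 0)
})

test_that("an orbiting leader is more mobile than a zone-parking leader", {
  cfg <- short_config(700)
  mob <- function(scenario, s) {
    fx <- make_fixture(scenario, cfg, seed = s)
    trial_stats(fx$log)$cells_visited[1]
  }
  passive <- vapply(1:3, function(s) mob("passive_leader_group", s), numeric(1))
  strong <- vapply(1:3, function(s) mob("strong_active_group", s), numeric(1))
  expect_gt(mean(strong), mean(passive))
})

test_that("removing nobody reproduces the baseline; removal drops a robot", {
  cfg <- short_config(300)
  fx <- make_fixture("passive_leader_group", cfg, seed = 6)
  rt <- removal_test(fx$replication, removed = NULL, config = cfg,
                     n_trials = 2, seed = 13)
  expect_equal(rt$fitness_removed, rt$fitness_baseline)
  rt2 <- removal_test(fx$replication, removed = "blue", config = cfg,
                      n_trials = 2, seed = 13)
  expect_identical(rt2$removed, "blue")
  expect_true(is.finite(rt2$fitness_removed))
  expect_error(removal_test(fx$replication, removed = c("blue", "yellow",
                                                        "green"),
                            config = cfg, n_trials = 1, seed = 1),
               "unsupported")
})

test_that("measure suite ties the pieces together on a fixture", {
  cfg <- short_config(400)
  fx <- make_fixture("passive_leader_group", cfg, seed = 8)
  ms <- measure_suite(fx$replication, cfg, n_generations = 1, n_trials = 2,
                      seed = 21)
  expect_s3_class(ms, "measure_suite_result")
  expect_equal(ms$leader, "green")
  expect_equal(ms$leadership_measure,
               leadership_measure(ms$barycenter_quadruple))
  row <- as.data.frame(ms)
  expect_equal(nrow(row), 1L)
  expect_true(all(c("leadership_measure", "leader",
                    "collective_fitness_indicator",
                    "capability_of_followers", "mobility_of_leaders",
                    "vision_of_leaders") %in% names(row)))
})

test_that("removing the leader collapses a leader-centered group", {
  cfg <- short_config(600)
  fx <- make_fixture("passive_leader_group", cfg, seed = 10)
  base <- removal_test(fx$replication, removed = NULL, config = cfg,
                       n_trials = 3, seed = 17)$fitness_baseline
  expect_gt(base, 0)
  # followers only track the green leader; without it they never forage
  no_leader <- removal_test(fx$replication, removed = "green", config = cfg,
                            n_trials = 3, seed = 17)$fitness_removed
  expect_equal(no_leader, 0)
  # removing one follower leaves the leader-centered group functional
  no_follower <- removal_test(fx$replication, removed = "blue", config = cfg,
                              n_trials = 3, seed = 17)$fitness_removed
  expect_gt(no_follower, 0.5 * base)
})
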