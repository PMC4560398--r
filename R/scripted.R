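# Scripted controllers and fixture scenarios. These bypass the neural
# controllers and drive robots with hand-written policies that mimic the
# behaviours an evolved team exhibits (a leader heading straight to a zone,
# colour-following followers, an orbiting leader, random walkers), so every
# leadership measure can be exercised against known ground truth.

# proportional steering toward a target point; v in cm/step
drive_to <- function(pose, target, config, stop_radius = 0) {
  vmax <- config$wheel_speed_max
  d <- config$robot_diameter
  dist <- sqrt(sum((target - pose[1:2])^2))
  if (dist <= stop_radius) return(c(0, 0))
  err <- wrap_pi(atan2(target[2] - pose[2], target[1] - pose[1]) - pose[3])
  wmax <- 2 * vmax / d
  w <- min(max(err, -wmax), wmax)
  v <- min(vmax * max(0, cos(err)), dist)
  vl <- v - w * d / 2
  vr <- v + w * d / 2
  m <- max(abs(vl), abs(vr), vmax)
  c(vl, vr) * (vmax / m)
}

#' Construct a scripted controller
#'
#' Available policies:
#' \describe{
#'   \item{stationary}{never moves.}
#'   \item{goto_point}{drives to \code{target = c(x, y)}; optional
#'     \code{stop_radius}.}
#'   \item{goto_zone}{drives to the center of zone \code{k} and parks there.}
#'   \item{goto_nearest_zone}{drives to whichever zone center is nearer.}
#'   \item{follow_colour}{pursues the robot with chassis colour
#'     \code{colour}, stopping just outside collision range.}
#'   \item{orbit}{circles counter-clockwise around \code{center} at
#'     \code{radius}, advancing \code{omega} radians per step.}
#'   \item{random_walk}{drives forward at 80\% speed with random steering
#'     noise (uses the R RNG).}
#'   \item{wiggle_goto_zone}{like goto_zone but pauses to spin in place for
#'     \code{turn_steps} steps every \code{period} steps (a weak-active
#'     leader caricature).}
#' }
#'
#' @param policy Policy name.
#' @param ... Policy parameters, see above.
#' @return A \code{scripted_controller}; its \code{fn(poses, i, config, t)}
#'   returns \code{c(v_left, v_right)}.
#' @export
scripted_controller <- function(policy, ...) {
  pars <- list(...)
  fn <- switch(policy,
    stationary = function(poses, i, config, t) c(0, 0),
    goto_point = function(poses, i, config, t)
      drive_to(poses[i, ], pars$target, config,
               if (is.null(pars$stop_radius)) 0 else pars$stop_radius),
    goto_zone = function(poses, i, config, t)
      drive_to(poses[i, ], config$zone_centers[pars$k, ], config,
               stop_radius = config$zone_diameter / 8),
    goto_nearest_zone = function(poses, i, config, t) {
      d2 <- (config$zone_centers[, 1] - poses[i, 1])^2 +
            (config$zone_centers[, 2] - poses[i, 2])^2
      drive_to(poses[i, ], config$zone_centers[which.min(d2), ], config,
               stop_radius = config$zone_diameter / 8)
    },
    follow_colour = function(poses, i, config, t) {
      j <- match(pars$colour, robot_colours())
      if (is.na(poses[j, 1])) return(c(0, 0))
      drive_to(poses[i, ], poses[j, 1:2], config,
               stop_radius = 1.5 * config$robot_diameter)
    },
    orbit = function(poses, i, config, t) {
      omega <- if (is.null(pars$omega)) 0.2 else pars$omega
      phi <- atan2(poses[i, 2] - pars$center[2], poses[i, 1] - pars$center[1])
      target <- pars$center + pars$radius * c(cos(phi + omega), sin(phi + omega))
      drive_to(poses[i, ], target, config)
    },
    random_walk = function(poses, i, config, t) {
      v <- 0.8 * config$wheel_speed_max
      eps <- stats::runif(1, -0.2, 0.2) * config$wheel_speed_max
      pmin(pmax(c(v - eps, v + eps), -config$wheel_speed_max),
           config$wheel_speed_max)
    },
    wiggle_goto_zone = function(poses, i, config, t) {
      period <- if (is.null(pars$period)) 200 else pars$period
      turn_steps <- if (is.null(pars$turn_steps)) 25 else pars$turn_steps
      if (t %% period < turn_steps) {
        v <- 0.5 * config$wheel_speed_max
        return(c(-v, v))  # spin on the spot
      }
      drive_to(poses[i, ], config$zone_centers[pars$k, ], config,
               stop_radius = config$zone_diameter / 8)
    },
    stop("unknown scripted policy '", policy, "'")
  )
  structure(list(policy = policy, pars = pars, fn = fn),
            class = "scripted_controller")
}

#' Bundle four scripted controllers into a team
#'
#' @param controllers List of four [scripted_controller()] objects in robot
#'   index order.
#' @return A \code{scripted_team}, usable wherever a [genotype_team()] is.
#' @export
scripted_team <- function(controllers) {
  stopifnot(length(controllers) == 4,
            all(vapply(controllers, inherits, TRUE, "scripted_controller")))
  structure(list(controllers = controllers), class = "scripted_team")
}

# random non-overlapping placement for the scripted path (R RNG)
place_robots_r <- function(config, active, pinned) {
  r <- config$robot_diameter / 2
  L <- config$side_length
  D <- config$robot_diameter
  poses <- matrix(NA_real_, 4, 3)
  if (!is.null(pinned)) poses[pinned, ] <- c(L / 2, L / 2, 0)
  for (i in which(active)) {
    if (!is.null(pinned) && i == pinned) next
    for (attempt in 1:10000) {
      p <- stats::runif(2, r, L - r)
      if (config$exclude_zones_at_init &&
          !is.na(in_zone(p, config))) next
      placed <- which(!is.na(poses[, 1]))
      if (length(placed) &&
          any((poses[placed, 1] - p[1])^2 + (poses[placed, 2] - p[2])^2 < D^2))
        next
      poses[i, ] <- c(p, stats::runif(1, 0, 2 * pi))
      break
    }
    if (is.na(poses[i, 1])) stop("could not place robots (arena too small?)")
  }
  poses
}

# displace colliding robots (R RNG); returns poses and per-robot moved flags
resolve_poses_r <- function(poses, active, pinned, config) {
  r <- config$robot_diameter / 2
  L <- config$side_length
  D <- config$robot_diameter
  moved <- rep(FALSE, 4)
  for (i in which(active)) {
    if (!is.null(pinned) && i == pinned) next
    others <- setdiff(which(active), i)
    colliding <- function(p) {
      p[1] < r || p[1] > L - r || p[2] < r || p[2] > L - r ||
        (length(others) > 0 &&
         any((poses[others, 1] - p[1])^2 + (poses[others, 2] - p[2])^2 < D^2))
    }
    if (!colliding(poses[i, 1:2])) next
    ok <- FALSE
    for (attempt in 1:10000) {
      disp <- config$collision_displacement * 2^((attempt - 1) %/% 1000)
      a <- stats::runif(1, 0, 2 * pi)
      p <- poses[i, 1:2] + disp * c(cos(a), sin(a))
      if (colliding(p)) next
      poses[i, ] <- c(p, stats::runif(1, 0, 2 * pi))
      moved[i] <- TRUE
      ok <- TRUE
      break
    }
    if (!ok) stop("resolve_collisions: no legal reposition found")
  }
  list(poses = poses, moved = moved)
}

#' @export
simulate_trial.scripted_team <- function(team, config, seed,
                                         fitness_mode = "collective",
                                         pinned = NULL, removed = NULL,
                                         reach_radius = 11,
                                         bary_exclude_pinned = FALSE,
                                         keep_log = TRUE, log_sensors = FALSE,
                                         init_poses = NULL) {
  mask <- removed_mask(removed)
  active <- !mask
  steps <- config$steps_per_trial
  ucfg <- unclass(config)

  pose_log <- matrix(NA_real_, steps + 1, 12)
  ctrl_log <- matrix(NA_real_, steps, 8)
  zone_log <- matrix(NA_integer_, steps, 4)
  coll_log <- matrix(0L, steps, 4)
  sens_log <- if (log_sensors) matrix(NA_real_, steps, 72) else NULL

  with_seed(derive_seed(seed, "scripted"), {
    poses <- place_robots_r(config, active, pinned)
    if (!is.null(init_poses)) poses[] <- init_poses
    pose_log[1, ] <- c(poses[, 1], poses[, 2], poses[, 3])
    for (t in seq_len(steps)) {
      vlr <- matrix(0, 4, 2)
      for (i in which(active)) {
        if (log_sensors) {
          ret <- .read_retina_cpp(poses, i - 1L, ucfg)
          sm <- read_smell(poses[i, ], config)
          sens_log[t, (i - 1) * 18 + (1:18)] <-
            c(ret, as.numeric(sm), read_ground(poses[i, ], config))
        }
        if (is.null(pinned) || i != pinned)
          vlr[i, ] <- team$controllers[[i]]$fn(poses, i, config, t)
      }
      vmax <- config$wheel_speed_max
      vlr <- pmin(pmax(vlr, -vmax), vmax)
      for (i in which(active)) {
        if (!is.null(pinned) && i == pinned) next
        poses[i, ] <- step_kinematics(poses[i, ], vlr[i, 1], vlr[i, 2], config)
      }
      res <- resolve_poses_r(poses, active, pinned, config)
      poses <- res$poses
      coll_log[t, ] <- as.integer(res$moved)
      pose_log[t + 1, ] <- c(poses[, 1], poses[, 2], poses[, 3])
      ctrl_log[t, ] <- as.vector(t(vlr))
      for (i in which(active)) zone_log[t, i] <- in_zone(poses[i, ], config)
    }
  })

  log <- new_trial_log(seed = seed, config = config, pinned = pinned,
                       removed = removed, pose = pose_log, control = ctrl_log,
                       zone = zone_log, collided = coll_log,
                       sensors = sens_log)
  stats <- trial_stats(log, fitness_mode = fitness_mode,
                       reach_radius = reach_radius,
                       bary_exclude_pinned = bary_exclude_pinned)
  stats$log <- if (keep_log) log else NULL
  stats
}

#' Generate a named fixture scenario
#'
#' Produces a scripted team with known ground truth, one logged trial, and a
#' pseudo-replication wrapper usable by the measure battery:
#' \describe{
#'   \item{passive_leader_group}{robot 1 (green) drives straight to zone 1
#'     and parks; robots 2-4 follow green.}
#'   \item{weak_active_group}{as above, but the leader periodically spins in
#'     place before resuming course.}
#'   \item{strong_active_group}{the leader orbits the arena center at 20 cm
#'     while robots 2-4 follow it.}
#'   \item{leaderless_group}{four independent random walkers.}
#'   \item{follower_only}{robot 1 stands still; robots 2-4 follow green.}
#' }
#'
#' @param scenario Scenario name (see above).
#' @param config An [arena_config()].
#' @param seed Integer seed for the logged trial.
#' @param log_sensors Log per-step sensor values in the trial log.
#' @return List with \code{team} (scripted_team), \code{log} (one
#'   \code{trial_log}), and \code{replication} (a \code{scripted_replication}
#'   accepted by [barycenter_test()] and friends).
#' @export
make_fixture <- function(scenario, config = arena_config(), seed = 1,
                         log_sensors = FALSE) {
  follow1 <- function() scripted_controller("follow_colour", colour = "green")
  team <- switch(scenario,
    passive_leader_group = scripted_team(list(
      scripted_controller("goto_zone", k = 1),
      follow1(), follow1(), follow1())),
    weak_active_group = scripted_team(list(
      scripted_controller("wiggle_goto_zone", k = 1),
      follow1(), follow1(), follow1())),
    strong_active_group = scripted_team(list(
      scripted_controller("orbit",
                          center = c(config$side_length / 2,
                                     config$side_length / 2),
                          radius = 20),
      follow1(), follow1(), follow1())),
    leaderless_group = scripted_team(lapply(1:4, function(i)
      scripted_controller("random_walk"))),
    follower_only = scripted_team(list(
      scripted_controller("stationary"),
      follow1(), follow1(), follow1())),
    stop("unknown scenario '", scenario, "'")
  )
  res <- simulate_trial(team, config, seed, keep_log = TRUE,
                        log_sensors = log_sensors)
  list(team = team, log = res$log, scenario = scenario,
       replication = scripted_replication(team))
}

#' Wrap a scripted team as a pseudo-replication
#'
#' The measure battery asks a replication for its team at each of the last
#' generations; a scripted replication answers with the same fixed team at
#' every generation, which makes all measures runnable on fixtures.
#'
#' @param team A [scripted_team()].
#' @param generations Nominal generation count.
#' @param group_fitness Optional per-generation group fitness series.
#' @param teams Optional list of per-generation [scripted_team()]s (length
#'   \code{generations}), for fixtures whose behaviour changes over
#'   generations; overrides \code{team}.
#' @return A \code{scripted_replication}.
#' @export
scripted_replication <- function(team, generations = 20,
                                 group_fitness = rep(0, generations),
                                 teams = NULL) {
  if (!is.null(teams)) stopifnot(length(teams) == generations)
  structure(list(team = team, generations = generations,
                 group_fitness = group_fitness, teams = teams),
            class = "scripted_replication")
}
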