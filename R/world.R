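#' @useDynLib swarmlead, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Chassis colours of the four robots
#'
#' Fixed identity colours (green, blue, light-blue, yellow) with the RGB
#' triples used by the retina model. Robot index i always carries colour
#' \code{robot_colours()[i]}.
#'
#' @return Character vector of the four colour ids, in robot-index order.
#' @export
robot_colours <- function() c("green", "blue", "light_blue", "yellow")

#' RGB triples (0-255) of the chassis colours, one row per robot index.
#' @return 4 x 3 integer matrix with rownames from [robot_colours()].
#' @export
colour_rgb <- function() {
  m <- matrix(c(0L, 255L, 0L,
                0L, 0L, 255L,
                0L, 255L, 255L,
                255L, 255L, 0L), 4, 3, byrow = TRUE)
  dimnames(m) <- list(robot_colours(), c("R", "G", "B"))
  m
}

#' Arena configuration
#'
#' Geometry and physics constants of the simulated world: a square arena
#' bounded by walls, two circular grey food zones on a white floor, and four
#' circular differential-drive robots.
#'
#' @param side_length Wall length of the square arena (cm).
#' @param zone_diameter Diameter of each circular food zone (cm).
#' @param zone_centers 2 x 2 matrix of zone center coordinates (cm); defaults
#'   to two positions symmetric about the arena center on the horizontal
#'   midline.
#' @param robot_diameter Chassis diameter (cm); also the wheel separation
#'   used by the kinematics.
#' @param steps_per_trial Lifetime of one trial in time steps.
#' @param wheel_speed_max Maximum wheel speed (cm per time step).
#' @param collision_displacement Distance a robot is teleported when it
#'   impacts a wall or another robot (cm).
#' @param exclude_zones_at_init If TRUE, initial random placement rejects
#'   positions inside a food zone.
#' @return An object of class \code{arena_config} (a validated list).
#' @examples
#' cfg <- arena_config()
#' cfg$side_length
#' @export
arena_config <- function(side_length = 110,
                         zone_diameter = 22,
                         zone_centers = NULL,
                         robot_diameter = 5.5,
                         steps_per_trial = 3000,
                         wheel_speed_max = 1.3,
                         collision_displacement = 5.5,
                         exclude_zones_at_init = FALSE) {
  if (is.null(zone_centers)) {
    zone_centers <- matrix(c(side_length / 4, side_length / 2,
                             3 * side_length / 4, side_length / 2),
                           2, 2, byrow = TRUE)
  }
  zone_centers <- matrix(as.numeric(zone_centers), 2, 2)
  cfg <- structure(list(
    side_length = as.numeric(side_length),
    zone_diameter = as.numeric(zone_diameter),
    zone_centers = zone_centers,
    robot_diameter = as.numeric(robot_diameter),
    steps_per_trial = as.integer(steps_per_trial),
    wheel_speed_max = as.numeric(wheel_speed_max),
    collision_displacement = as.numeric(collision_displacement),
    exclude_zones_at_init = isTRUE(exclude_zones_at_init)
  ), class = "arena_config")
  validate_arena_config(cfg)
  cfg
}

validate_arena_config <- function(cfg) {
  stopifnot(cfg$side_length > 0,
            cfg$zone_diameter > 0,
            cfg$robot_diameter > 0,
            cfg$robot_diameter < cfg$zone_diameter,
            cfg$steps_per_trial >= 1,
            cfg$wheel_speed_max > 0,
            cfg$collision_displacement > 0)
  r <- cfg$zone_diameter / 2
  inside <- cfg$zone_centers[, 1] >= r & cfg$zone_centers[, 1] <= cfg$side_length - r &
            cfg$zone_centers[, 2] >= r & cfg$zone_centers[, 2] <= cfg$side_length - r
  if (!all(inside)) stop("food zones must lie fully inside the arena")
  if (all(cfg$zone_centers[1, ] == cfg$zone_centers[2, ]))
    stop("zone centers must be distinct")
  invisible(cfg)
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config> ", x$side_length, "x", x$side_length,
      " cm arena, 2 food zones (d = ", x$zone_diameter, " cm), ",
      "4 robots (d = ", x$robot_diameter, " cm), ",
      x$steps_per_trial, " steps/trial\n", sep = "")
  invisible(x)
}

#' Initial world state
#'
#' Places the four robots uniformly at random with non-overlapping chassis
#' (pairwise center distance at least one robot diameter) and uniform random
#' headings. Deterministic given the seed.
#'
#' @param config An [arena_config()].
#' @param seed Non-negative integer seed.
#' @return A \code{world_state}: list with \code{poses} (data frame with
#'   columns x, y, heading, colour; one row per robot) and \code{step_index}.
#' @export
init_world <- function(config, seed) {
  stopifnot(inherits(config, "arena_config"), seed >= 0)
  m <- .init_world_cpp(unclass(config), as.numeric(seed))
  poses <- data.frame(x = m[, "x"], y = m[, "y"], heading = m[, "heading"],
                      colour = robot_colours(), stringsAsFactors = FALSE)
  structure(list(poses = poses, step_index = 0L, seed = as.numeric(seed)),
            class = "world_state")
}

#' One closed-form kinematic step of a differential-drive robot
#'
#' Exact arc integration of the unicycle model over one time step: linear
#' velocity (v_left + v_right)/2, angular velocity
#' (v_right - v_left)/robot_diameter. Pure translation and pure rotation are
#' exact; no Euler discretisation error.
#'
#' @param pose Numeric vector \code{c(x, y, heading)} or a one-row pose data
#'   frame.
#' @param v_left,v_right Wheel speeds (cm/step); callers are expected to
#'   clamp them to \code{wheel_speed_max}.
#' @param config An [arena_config()] (supplies the wheel separation).
#' @return Numeric vector \code{c(x, y, heading)}, heading wrapped to
#'   \code{[0, 2*pi)}.
#' @examples
#' cfg <- arena_config()
#' step_kinematics(c(0, 0, 0), 1, 1, cfg)  # 1 cm straight along +x
#' @export
step_kinematics <- function(pose, v_left, v_right, config) {
  if (is.data.frame(pose)) pose <- c(pose$x[1], pose$y[1], pose$heading[1])
  d <- config$robot_diameter
  v <- (v_left + v_right) / 2
  w <- (v_right - v_left) / d
  x <- pose[1]; y <- pose[2]; th <- pose[3]
  if (abs(w) < 1e-12) {
    x <- x + v * cos(th)
    y <- y + v * sin(th)
  } else {
    r <- v / w
    x <- x + r * (sin(th + w) - sin(th))
    y <- y - r * (cos(th + w) - cos(th))
    th <- (th + w) %% (2 * pi)
  }
  c(x = unname(x), y = unname(y), heading = unname(th))
}

#' Resolve wall and robot-robot collisions
#'
#' Any robot whose chassis protrudes beyond a wall or overlaps another robot
#' (center distance below one diameter) is displaced by
#' \code{collision_displacement} in a random direction, repeatedly until it
#' reaches a legal position, and is given a uniform random heading.
#' Non-colliding robots are untouched.
#'
#' @param state A \code{world_state}.
#' @param config An [arena_config()].
#' @param seed Integer seed for the displacement draws.
#' @return The repaired \code{world_state}.
#' @export
resolve_collisions <- function(state, config, seed) {
  m <- as.matrix(state$poses[, c("x", "y", "heading")])
  out <- .resolve_collisions_cpp(m, unclass(config), as.numeric(seed))
  state$poses$x <- out[, "x"]
  state$poses$y <- out[, "y"]
  state$poses$heading <- out[, "heading"]
  state
}

#' Which food zone (if any) a robot is on
#'
#' Zone membership uses the robot-center-inside-disc convention: the ground
#' sensor sits at the chassis center, so a robot is on a zone when its center
#' is strictly within the zone radius of that zone's center.
#'
#' @param pose Numeric \code{c(x, y)} (a heading element is ignored) or a
#'   one-row pose data frame.
#' @param config An [arena_config()].
#' @return Integer zone id (1 or 2) or \code{NA_integer_} if on white floor.
#' @export
in_zone <- function(pose, config) {
  if (is.data.frame(pose)) pose <- c(pose$x[1], pose$y[1])
  r <- config$zone_diameter / 2
  d <- sqrt((config$zone_centers[, 1] - pose[1])^2 +
            (config$zone_centers[, 2] - pose[2])^2)
  k <- which(d < r)
  if (length(k) == 0) NA_integer_ else as.integer(k[1])
}
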