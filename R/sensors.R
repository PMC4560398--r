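# Robot perceptive system: 5-photoreceptor RGB linear retina over a 90-degree
# field of view, three quadrant smell sensors on two binary lines, and a
# ground sensor. These R implementations are the readable reference; the
# trial simulator carries an equivalent compiled path.

# wrap an angle to (-pi, pi]
wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a <= 0] <- a[a <= 0] + 2 * pi
  a - pi
}

# wrap an angle to [0, 2*pi)
wrap_2pi <- function(a) a %% (2 * pi)

#' Read the linear RGB retina of one robot
#'
#' The retina spans a 90-degree field of view, from -45 to +45 degrees
#' relative to the heading, divided into five 18-degree photoreceptor
#' sectors (leftmost first; sectors are half-open on the right except the
#' last). Another robot at center distance d subtends a closed angular
#' extent of half-angle asin(r/d) around its bearing, r being the chassis
#' radius. A photoreceptor fires when its sector overlaps the extent of at
#' least one robot, and takes the normalized RGB colour (component/255) of
#' the nearest such robot (occlusion). There is no range limit and no
#' intensity falloff: distance is conveyed only by how many sectors a robot
#' covers. Walls and food zones are invisible to the retina.
#'
#' @param state A \code{world_state} (or any list with a \code{poses} data
#'   frame of 4 rows).
#' @param observer Robot index in 1..4.
#' @param config An [arena_config()].
#' @return Numeric vector of 15 values in \code{[0, 1]}, ordered
#'   R0,G0,B0,...,R4,G4,B4 by photoreceptor index.
#' @export
read_retina <- function(state, observer, config) {
  if (!(observer %in% 1:4)) stop("observer index out of range")
  poses <- state$poses
  r <- config$robot_diameter / 2
  sec_lo <- (-45 + 18 * (0:4)) * pi / 180
  sec_hi <- sec_lo + 18 * pi / 180
  rgb <- colour_rgb() / 255
  best_d <- rep(Inf, 5)
  out <- numeric(15)
  for (j in seq_len(nrow(poses))) {
    if (j == observer || is.na(poses$x[j])) next
    dx <- poses$x[j] - poses$x[observer]
    dy <- poses$y[j] - poses$y[observer]
    d <- sqrt(dx^2 + dy^2)
    if (d < 1e-9) next
    half <- asin(min(1, r / d))
    b <- wrap_pi(atan2(dy, dx) - poses$heading[observer])
    lo <- b - half
    hi <- b + half
    for (k in 1:5) {
      hit <- if (k == 5) lo <= sec_hi[k] && hi >= sec_lo[k]
             else        lo <  sec_hi[k] && hi >= sec_lo[k]
      if (hit && d < best_d[k]) {
        best_d[k] <- d
        out[(3 * k - 2):(3 * k)] <- rgb[j, ]
      }
    }
  }
  out
}

#' Read the quadrant smell sensors
#'
#' Three smell sensors cover the full circle around the robot and signal, on
#' two binary lines, which quadrant currently faces the nearest food zone:
#' bearing in \code{[0, 90)} degrees activates sensor 1 (code 0,1),
#' \code{[90, 270)} sensor 2 (code 1,0) and \code{[270, 360)} sensor 3
#' (code 1,1). Range is unlimited, so exactly one sensor is active at every
#' step and the code (0,0) never occurs.
#'
#' @param pose Numeric \code{c(x, y, heading)} or a one-row pose data frame.
#' @param config An [arena_config()].
#' @return Integer vector \code{c(s0, s1)}.
#' @export
read_smell <- function(pose, config) {
  if (is.data.frame(pose)) pose <- c(pose$x[1], pose$y[1], pose$heading[1])
  d2 <- (config$zone_centers[, 1] - pose[1])^2 +
        (config$zone_centers[, 2] - pose[2])^2
  k <- which.min(d2)
  b <- wrap_2pi(atan2(config$zone_centers[k, 2] - pose[2],
                      config$zone_centers[k, 1] - pose[1]) - pose[3])
  if (b < pi / 2) c(s0 = 0L, s1 = 1L)
  else if (b < 3 * pi / 2) c(s0 = 1L, s1 = 0L)
  else c(s0 = 1L, s1 = 1L)
}

#' Read the ground sensor
#'
#' Returns 1.0 when the chassis center is on a grey food zone and 0.0 on the
#' white floor, consistent with [in_zone()].
#'
#' @inheritParams read_smell
#' @return 0.0 or 1.0.
#' @export
read_ground <- function(pose, config) {
  if (is.na(in_zone(pose, config))) 0.0 else 1.0
}

#' Assemble the 18-value controller input vector of one robot
#'
#' Fixed input ordering: 15 retina values (R0,G0,B0,...,R4,G4,B4), the two
#' smell lines S0, S1, then the ground value G.
#'
#' @inheritParams read_retina
#' @return Numeric vector of length 18, each value in \code{[0, 1]}.
#' @export
sensor_inputs <- function(state, observer, config) {
  pose <- state$poses[observer, ]
  c(read_retina(state, observer, config),
    as.numeric(read_smell(pose, config)),
    read_ground(pose, config))
}
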