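# Shared test helpers: small configurations and hand-built trial logs.

# default geometry with a shortened lifetime, for fast simulated tests
short_config <- function(steps = 500, ...) {
  arena_config(steps_per_trial = steps, ...)
}

# a pose matrix with robots at given (x, y, heading); NA rows = removed
pose_matrix <- function(...) {
  rows <- list(...)
  m <- matrix(NA_real_, 4, 3)
  for (i in seq_along(rows)) if (!is.null(rows[[i]])) m[i, ] <- rows[[i]]
  m
}

# build a trial_log directly from per-robot coordinate paths (constant
# heading 0, zero controls, no collisions); paths: list of n x 2 matrices
log_from_paths <- function(paths, config, pinned = NULL, sensors = NULL) {
  steps <- nrow(paths[[1]]) - 1
  pose <- matrix(0, steps + 1, 12)
  for (i in 1:4) {
    pose[, i] <- paths[[i]][, 1]
    pose[, 4 + i] <- paths[[i]][, 2]
  }
  zone <- matrix(NA_integer_, steps, 4)
  for (i in 1:4)
    for (t in seq_len(steps))
      zone[t, i] <- in_zone(c(pose[t + 1, i], pose[t + 1, 4 + i]), config)
  swarmlead:::new_trial_log(seed = 0, config = config, pinned = pinned,
                            removed = NULL, pose = pose,
                            control = matrix(0, steps, 8), zone = zone,
                            collided = matrix(1L, steps, 4),
                            sensors = sensors)
}

# stationary path at a point
path_at <- function(p, steps) matrix(rep(p, each = steps + 1), steps + 1, 2)

# brute-force retina oracle: which sectors does any robot cover, sampling
# bearings across the field of view at `res` degrees. `slack` (degrees)
# grows or shrinks every angular extent: the grid cannot resolve overlaps
# narrower than its resolution, so exact sector sets are checked against
# the bracket [oracle(-res), oracle(+res)].
retina_sectors_oracle <- function(poses, observer, config, res = 0.1,
                                  slack = 0) {
  grid <- seq(-45, 45, by = res) * pi / 180
  r <- config$robot_diameter / 2
  covered <- rep(FALSE, length(grid))
  for (j in seq_len(4)) {
    if (j == observer || is.na(poses[j, 1])) next
    dx <- poses[j, 1] - poses[observer, 1]
    dy <- poses[j, 2] - poses[observer, 2]
    d <- sqrt(dx^2 + dy^2)
    half <- asin(min(1, r / d)) + slack * pi / 180
    if (half <= 0) next
    b <- swarmlead:::wrap_pi(atan2(dy, dx) - poses[observer, 3])
    covered <- covered | abs(swarmlead:::wrap_pi(grid - b)) <= half
  }
  sector <- pmin(floor((grid * 180 / pi + 45) / 18), 4)
  sort(unique(as.integer(sector[covered])))
}

# TRUE iff the exact sector set lies within the oracle bracket
retina_oracle_agrees <- function(poses, observer, config, got, res = 0.1) {
  lo <- retina_sectors_oracle(poses, observer, config, res, slack = -res)
  hi <- retina_sectors_oracle(poses, observer, config, res, slack = res)
  all(lo %in% got) && all(got %in% hi)
}

# sectors active in a 15-value retina reading (0-based)
active_sectors <- function(reading) {
  which(vapply(0:4, function(k)
    any(reading[(3 * k + 1):(3 * k + 3)] > 0), logical(1))) - 1L
}
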