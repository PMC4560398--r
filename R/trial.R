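# One trial = one lifetime of the 4-robot team in the arena. Neural teams
# run through the compiled simulator; scripted teams (test fixtures) run
# through a plain R loop. Both produce the same per-robot summary statistics
# and the same trial_log layout, so every measure works on either.

#' Bundle four genotypes into a team
#'
#' @param genotypes List of four 688-bit genotypes, in robot-index order
#'   (green, blue, light-blue, yellow).
#' @return A \code{genotype_team}.
#' @export
genotype_team <- function(genotypes) {
  stopifnot(length(genotypes) == 4)
  lapply(genotypes, check_genotype)
  structure(list(genotypes = genotypes), class = "genotype_team")
}

#' Run one trial of a team
#'
#' Simulates \code{steps_per_trial} time steps of the sense - think - move -
#' collide loop and scores the team. Fitness modes: \code{"collective"}
#' (+1 to every robot on each step on which the whole group stands in the
#' same food zone), \code{"individual"} (+1 per step a robot stands on any
#' zone), \code{"mixed"} (sum of both).
#'
#' @param team A [genotype_team()] or [scripted_team()].
#' @param config An [arena_config()].
#' @param seed Integer seed; the trial is bit-identical given
#'   (team, config, seed).
#' @param fitness_mode One of "collective", "individual", "mixed".
#' @param pinned Optional robot index (1..4) held motionless at the arena
#'   center for the whole trial.
#' @param removed Optional integer indices of robots deleted from the world
#'   (at most 2); they are invisible to sensors and excluded from scoring.
#' @param reach_radius Radius (cm) within which a follower counts as having
#'   reached a pinned robot.
#' @param bary_exclude_pinned If TRUE the group barycenter is computed over
#'   the free robots only (n = 3) instead of all robots (n = 4, default).
#' @param keep_log Keep the full trajectory log.
#' @param log_sensors Also log the 18 sensor values per robot per step
#'   (needed by the vision measure).
#' @param init_poses Optional 4 x 3 matrix (x, y, heading) overriding the
#'   random initial placement.
#' @return A list with per-robot vectors \code{fitness},
#'   \code{steps_in_zone}, \code{mean_dist_barycenter}, \code{vision_steps},
#'   \code{cells_visited}, \code{first_reach_step} (censored at
#'   \code{steps_per_trial}), and \code{log} (a \code{trial_log} or NULL).
#' @export
simulate_trial <- function(team, config, seed, fitness_mode = "collective",
                           pinned = NULL, removed = NULL, reach_radius = 11,
                           bary_exclude_pinned = FALSE,
                           keep_log = FALSE, log_sensors = FALSE,
                           init_poses = NULL) {
  UseMethod("simulate_trial")
}

removed_mask <- function(removed) {
  mask <- rep(FALSE, 4)
  if (!is.null(removed) && length(removed)) {
    stopifnot(all(removed %in% 1:4))
    mask[removed] <- TRUE
  }
  mask
}

#' @export
simulate_trial.genotype_team <- function(team, config, seed,
                                         fitness_mode = "collective",
                                         pinned = NULL, removed = NULL,
                                         reach_radius = 11,
                                         bary_exclude_pinned = FALSE,
                                         keep_log = FALSE, log_sensors = FALSE,
                                         init_poses = NULL) {
  mask <- removed_mask(removed)
  res <- .sim_trial_cpp(team_param_matrix(team$genotypes), unclass(config),
                        as.numeric(seed),
                        if (is.null(pinned)) -1L else as.integer(pinned) - 1L,
                        mask, fitness_mode, reach_radius, bary_exclude_pinned,
                        keep_log, log_sensors,
                        if (is.null(init_poses)) NULL else init_poses)
  out <- res[c("fitness", "steps_in_zone", "mean_dist_barycenter",
               "vision_steps", "cells_visited", "first_reach_step")]
  out$log <- if (keep_log) {
    zone <- res$log$zone
    zone[zone < 0] <- NA_integer_
    zone <- zone + 1L
    new_trial_log(seed = seed, config = config, pinned = pinned,
                  removed = removed, pose = res$log$pose,
                  control = res$log$control, zone = zone,
                  collided = res$log$collided, sensors = res$log$sensors)
  } else NULL
  out
}

# ------------------------------------------------------------ trial log ----

new_trial_log <- function(seed, config, pinned, removed, pose, control, zone,
                          collided, sensors = NULL) {
  colnames(pose) <- c(paste0("x", 1:4), paste0("y", 1:4), paste0("h", 1:4))
  colnames(control) <- as.vector(rbind(paste0("vl", 1:4), paste0("vr", 1:4)))
  colnames(zone) <- paste0("zone", 1:4)
  colnames(collided) <- paste0("collided", 1:4)
  if (!is.null(sensors)) {
    nm <- c(paste0(rep(paste0("p", 0:4), each = 3), c("R", "G", "B")),
            "s0", "s1", "g")
    colnames(sensors) <- as.vector(vapply(1:4, function(i)
      paste0("r", i, "_", nm), character(18)))
  }
  structure(list(seed = seed, config = config,
                 pinned = pinned, removed = removed,
                 pose = pose, control = control, zone = zone,
                 collided = collided, sensors = sensors),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat("<trial_log> ", nrow(x$control), " steps, 4 robots",
      if (!is.null(x$pinned)) paste0(", robot ", x$pinned, " pinned") else "",
      if (length(x$removed)) paste0(", removed: ",
                                    paste(x$removed, collapse = ",")) else "",
      if (is.null(x$sensors)) "" else ", sensors logged",
      "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a trial log
#'
#' Recomputes, from the logged trajectory alone, the same per-robot
#' summaries the simulator reports: fitness under a given mode, steps spent
#' on any zone, mean distance to the group barycenter, retina-active step
#' count (if sensors were logged), distinct grid cells visited, and the
#' first step within \code{reach_radius} of the pinned robot.
#'
#' @param log A \code{trial_log}.
#' @param fitness_mode One of "collective", "individual", "mixed".
#' @param reach_radius Reach radius in cm.
#' @param bary_exclude_pinned Compute the barycenter over free robots only.
#' @return A list of per-robot vectors, as in [simulate_trial()].
#' @export
trial_stats <- function(log, fitness_mode = "collective", reach_radius = 11,
                        bary_exclude_pinned = FALSE) {
  config <- log$config
  steps <- nrow(log$control)
  active <- !(1:4 %in% log$removed)
  n_active <- sum(active)
  X <- log$pose[, 1:4, drop = FALSE]
  Y <- log$pose[, 5:8, drop = FALSE]
  zone <- log$zone
  in_any <- !is.na(zone)

  together <- rep(FALSE, steps)
  zact <- zone[, active, drop = FALSE]
  together <- apply(zact, 1, function(z) !anyNA(z) && length(unique(z)) == 1)

  fitness <- steps_in_zone <- mean_db <- rep(NA_real_, 4)
  vision <- cells <- reach <- rep(NA_integer_, 4)

  bidx <- active
  if (bary_exclude_pinned && !is.null(log$pinned)) bidx[log$pinned] <- FALSE
  # post-move states are pose rows 2..steps+1
  bx <- rowMeans(X[-1, bidx, drop = FALSE])
  by <- rowMeans(Y[-1, bidx, drop = FALSE])

  cell <- config$robot_diameter
  ncell <- ceiling(config$side_length / cell)
  for (i in which(active)) {
    f_col <- as.numeric(together)
    f_ind <- as.numeric(in_any[, i])
    fitness[i] <- switch(fitness_mode,
                         collective = sum(f_col),
                         individual = sum(f_ind),
                         mixed = sum(f_col + f_ind),
                         stop("unknown fitness mode"))
    steps_in_zone[i] <- sum(in_any[, i])
    mean_db[i] <- mean(sqrt((X[-1, i] - bx)^2 + (Y[-1, i] - by)^2))
    cx <- pmin(pmax(floor(X[, i] / cell), 0), ncell - 1)
    cy <- pmin(pmax(floor(Y[, i] / cell), 0), ncell - 1)
    cells[i] <- length(unique(cy * ncell + cx))
    if (!is.null(log$sensors)) {
      ret <- log$sensors[, (i - 1) * 18 + (1:15), drop = FALSE]
      vision[i] <- sum(rowSums(ret > 0) > 0)
    }
    if (!is.null(log$pinned) && i != log$pinned) {
      p <- log$pinned
      d <- sqrt((X[, i] - X[, p])^2 + (Y[, i] - Y[, p])^2)
      hit <- which(d <= reach_radius)
      reach[i] <- if (length(hit)) hit[1] - 1L else steps
    }
  }
  list(fitness = fitness, steps_in_zone = steps_in_zone,
       mean_dist_barycenter = mean_db, vision_steps = vision,
       cells_visited = cells, first_reach_step = reach)
}

#' Check that a trial log replays under the kinematic model
#'
#' Re-applies [step_kinematics()] to every logged (pose, control) pair and
#' compares with the next logged pose. Steps on which a robot was displaced
#' by collision handling are exempt (the displacement is a teleport, not a
#' kinematic move), as are pinned and removed robots.
#'
#' @param log A \code{trial_log}.
#' @param tol Position/heading tolerance.
#' @return TRUE if every replayed pose matches; otherwise the maximum
#'   discrepancy is reported in the error.
#' @export
verify_log_replay <- function(log, tol = 1e-9) {
  config <- log$config
  steps <- nrow(log$control)
  active <- !(1:4 %in% log$removed)
  worst <- 0
  for (i in which(active)) {
    if (!is.null(log$pinned) && i == log$pinned) next
    for (t in seq_len(steps)) {
      if (log$collided[t, i] == 1) next
      p0 <- c(log$pose[t, i], log$pose[t, 4 + i], log$pose[t, 8 + i])
      p1 <- step_kinematics(p0, log$control[t, 2 * i - 1],
                            log$control[t, 2 * i], config)
      err <- max(abs(p1[1:2] - c(log$pose[t + 1, i], log$pose[t + 1, 4 + i])))
      herr <- abs(wrap_pi(p1[3] - log$pose[t + 1, 8 + i]))
      worst <- max(worst, err, herr)
    }
  }
  if (worst > tol) stop("log does not replay: max discrepancy ", worst)
  TRUE
}
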