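# Post-evolution measurement battery: barycenter-based leadership
# detection, individual and collective fitness indicators, follower
# capability, leader mobility and vision, and removal (perturbation) tests.

#' Barycenter (centroid) of a set of 2D points
#'
#' @param points An n x 2 numeric matrix (or a length-2 vector for n = 1).
#' @return Numeric \code{c(x, y)}: the arithmetic mean of the coordinates.
#' @examples
#' barycenter(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))  # (1, 1)
#' @export
barycenter <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(points) < 1) stop("barycenter of an empty point set")
  c(x = mean(points[, 1]), y = mean(points[, 2]))
}

#' Euclidean distance between two 2D points
#'
#' @param p,q Numeric length-2 vectors.
#' @return The distance \eqn{\sqrt{(p_x-q_x)^2 + (p_y-q_y)^2}}.
#' @export
euclidean_distance <- function(p, q) {
  sqrt(sum((as.numeric(p)[1:2] - as.numeric(q)[1:2])^2))
}

# shared loop: run trials over the last n_generations teams under a given
# pin setting and average a per-robot statistic
average_over_teams <- function(replication, config, stat, n_generations,
                               n_trials, seed, stream, pinned_seq = list(NULL),
                               ...) {
  gens <- seq.int(max(1L, replication$generations - n_generations + 1L),
                  replication$generations)
  acc <- numeric(4)
  cnt <- numeric(4)
  for (g in gens) {
    team <- team_at_generation(replication, g)
    for (pin in pinned_seq) {
      for (tr in seq_len(n_trials)) {
        res <- simulate_trial(team, config,
                              seed = derive_seed(seed, stream, g,
                                                 if (is.null(pin)) 0 else pin,
                                                 tr),
                              pinned = pin, keep_log = FALSE, ...)
        v <- stat(res, pin)
        ok <- !is.na(v)
        acc[ok] <- acc[ok] + v[ok]
        cnt[ok] <- cnt[ok] + 1
      }
    }
  }
  acc / cnt
}

#' The barycenter test: who aggregates the group?
#'
#' Each robot in turn is pinned motionless at the arena center while the
#' other three move freely for \code{n_trials} trials; at every step the
#' distance between the pinned robot and the group barycenter is recorded.
#' Averaging over steps, trials and the teams of the last
#' \code{n_generations} generations yields one value per robot: the robot
#' with the minimum value is the leader (the group gathers around it).
#'
#' @param replication A \code{replication_result} (or a
#'   \code{scripted_replication} fixture).
#' @param config An [arena_config()].
#' @param n_generations,n_trials Averaging depth (20 x 20 by default).
#' @param seed Master seed of the test's random draws.
#' @param bary_exclude_pinned If TRUE the barycenter is taken over the three
#'   free robots only instead of all four.
#' @return A named \code{barycenter_quadruple} (cm), one value per robot
#'   colour.
#' @export
barycenter_test <- function(replication, config = arena_config(),
                            n_generations = 20, n_trials = 20, seed = 1,
                            bary_exclude_pinned = FALSE) {
  if (replication$generations < n_generations)
    stop("replication has fewer than ", n_generations, " generations")
  out <- numeric(4)
  for (pin in 1:4) {
    v <- average_over_teams(replication, config,
                            stat = function(res, p) {
                              x <- rep(NA_real_, 4)
                              x[p] <- res$mean_dist_barycenter[p]
                              x
                            },
                            n_generations, n_trials, seed, "barycenter",
                            pinned_seq = list(pin),
                            bary_exclude_pinned = bary_exclude_pinned)
    out[pin] <- v[pin]
  }
  names(out) <- robot_colours()
  structure(out, class = "barycenter_quadruple")
}

#' Leadership measure of a replication
#'
#' The population standard deviation (divisor n) of the four barycenter-test
#' values. Zero when the quadruple is constant (no leader/follower
#' asymmetry); grows with the gap between the leader's distance and the
#' followers' distances; scales linearly with distance.
#'
#' @param quadruple A [barycenter_test()] result (any 4 numeric values).
#' @return Non-negative scalar (cm).
#' @export
leadership_measure <- function(quadruple) {
  x <- as.numeric(quadruple)
  stopifnot(length(x) == 4)
  sqrt(mean((x - mean(x))^2))
}

#' Leader identity from a barycenter quadruple
#'
#' @param quadruple A [barycenter_test()] result.
#' @return The colour id of the robot with the minimum distance.
#' @export
identify_leader <- function(quadruple) {
  robot_colours()[which.min(as.numeric(quadruple))]
}

#' The individual (virtual) fitness test
#'
#' All four robots move freely; each robot scores +1 for every step its
#' center stands on any food zone, independently of the others. Averaged
#' over \code{n_trials} trials and the last \code{n_generations} teams. This
#' virtual fitness is never used for selection; it indexes each robot's own
#' zone-reaching skill.
#'
#' @inheritParams barycenter_test
#' @return Named numeric vector of 4 mean per-trial scores (steps).
#' @export
individual_fitness_test <- function(replication, config = arena_config(),
                                    n_generations = 20, n_trials = 20,
                                    seed = 1) {
  if (replication$generations < n_generations)
    stop("replication has fewer than ", n_generations, " generations")
  v <- average_over_teams(replication, config,
                          stat = function(res, p) res$steps_in_zone,
                          n_generations, n_trials, seed, "indfit")
  names(v) <- robot_colours()
  v
}

#' Collective fitness indicator
#'
#' Mean of the per-generation best group fitness over the final
#' \code{n_generations} generations of the evolutionary run.
#'
#' @param replication A \code{replication_result}.
#' @param n_generations Window length (default 20).
#' @return Scalar (steps; at most \code{steps_per_trial}).
#' @export
collective_fitness_indicator <- function(replication, n_generations = 20) {
  gf <- replication$group_fitness
  if (length(gf) < n_generations)
    stop("replication has fewer than ", n_generations, " generations")
  mean(utils::tail(gf, n_generations))
}

#' Capability of followers: reaction time to a pinned leader
#'
#' The leader is pinned at the arena center and the followers move freely;
#' for each follower the first time step at which it comes within
#' \code{reach_radius} of the leader is recorded (censored at the trial
#' length if it never does). The mean over followers and \code{n_trials}
#' trials of the final-generation team is returned; smaller is more
#' reactive.
#'
#' @param replication A replication (or scripted fixture).
#' @param leader Leader colour id (from [identify_leader()]).
#' @param config An [arena_config()].
#' @param n_trials Number of trials.
#' @param seed Master seed.
#' @param reach_radius Reach radius in cm (default two chassis diameters).
#' @return Scalar mean reaching time (steps).
#' @export
capability_of_followers <- function(replication, leader,
                                    config = arena_config(), n_trials = 20,
                                    seed = 1, reach_radius = 11) {
  pin <- match(leader, robot_colours())
  if (is.na(pin)) stop("unknown leader colour '", leader, "'")
  team <- team_at_generation(replication, replication$generations)
  vals <- vapply(seq_len(n_trials), function(tr) {
    res <- simulate_trial(team, config,
                          seed = derive_seed(seed, "capability", tr),
                          pinned = pin, reach_radius = reach_radius)
    mean(res$first_reach_step[-pin], na.rm = TRUE)
  }, numeric(1))
  mean(vals)
}

#' Mobility of a leader from trial logs
#'
#' Counts the distinct robot_diameter-sized grid cells (a 20 x 20 grid under
#' the default geometry) the leader's center visits in each trial, averaged
#' over trials.
#'
#' @param trial_logs A list of \code{trial_log} objects (free runs).
#' @param leader Leader colour id.
#' @return Mean distinct-cell count per trial.
#' @export
mobility_of_leaders <- function(trial_logs, leader) {
  i <- match(leader, robot_colours())
  if (is.na(i)) stop("unknown leader colour '", leader, "'")
  mean(vapply(trial_logs, function(log)
    as.numeric(trial_stats(log)$cells_visited[i]), numeric(1)))
}

#' Vision of a leader from trial logs
#'
#' Counts the time steps on which at least one of the leader's 15 retina
#' photoreceptor components is active, averaged over trials. The logs must
#' have been produced with \code{log_sensors = TRUE}.
#'
#' @inheritParams mobility_of_leaders
#' @return Mean retina-active step count per trial.
#' @export
vision_of_leaders <- function(trial_logs, leader) {
  i <- match(leader, robot_colours())
  if (is.na(i)) stop("unknown leader colour '", leader, "'")
  vals <- vapply(trial_logs, function(log) {
    if (is.null(log$sensors)) stop("trial log has no sensor records")
    as.numeric(trial_stats(log)$vision_steps[i])
  }, numeric(1))
  mean(vals)
}

# free runs of the final-generation team, returning per-trial summary stats
# (fast path used by the measure suite; equivalent to logging trials and
# applying mobility_of_leaders / vision_of_leaders)
leader_free_runs <- function(replication, config, n_trials, seed) {
  team <- team_at_generation(replication, replication$generations)
  lapply(seq_len(n_trials), function(tr)
    simulate_trial(team, config, seed = derive_seed(seed, "freerun", tr)))
}

#' Robot-removal perturbation test
#'
#' Re-runs the final-generation team with one robot (or the identified
#' leader) deleted from the world: it is invisible to the others' sensors
#' and the collective same-zone condition applies to the three survivors.
#' Compares mean collective fitness with the intact baseline over
#' \code{n_trials} trials.
#'
#' @param replication A replication (or scripted fixture).
#' @param removed A colour id, \code{"leader"}, or \code{NULL} (pure
#'   baseline re-run); at most 2 colours.
#' @param config An [arena_config()].
#' @param n_trials Trials per condition.
#' @param seed Master seed.
#' @param leader Leader colour, required when \code{removed = "leader"}.
#' @return List with \code{fitness_removed}, \code{fitness_baseline} (mean
#'   collective scores) and \code{removed} (resolved colour ids).
#' @export
removal_test <- function(replication, removed = "leader",
                         config = arena_config(), n_trials = 20, seed = 1,
                         leader = NULL) {
  if (!is.null(removed) && identical(removed, "leader")) {
    if (is.null(leader)) stop("removed = 'leader' requires the leader colour")
    removed <- leader
  }
  idx <- NULL
  if (!is.null(removed)) {
    idx <- match(removed, robot_colours())
    if (anyNA(idx)) stop("unknown colour in 'removed'")
    if (length(idx) > 2) stop("removing more than 2 robots is unsupported")
  }
  team <- team_at_generation(replication, replication$generations)
  one <- function(rem) {
    mean(vapply(seq_len(n_trials), function(tr) {
      res <- simulate_trial(team, config,
                            seed = derive_seed(seed, "removal", tr),
                            removed = rem)
      mean(res$fitness, na.rm = TRUE)
    }, numeric(1)))
  }
  list(fitness_removed = one(idx), fitness_baseline = one(NULL),
       removed = if (is.null(idx)) character(0) else robot_colours()[idx])
}

#' Run the full measure battery on one replication
#'
#' Computes the barycenter quadruple, leadership measure, leader identity,
#' individual fitness quadruple, collective fitness indicator, capability of
#' followers, and the leader's mobility and vision, with a shared seed.
#'
#' @inheritParams barycenter_test
#' @param reach_radius Reach radius for the capability test (cm).
#' @return A \code{measure_suite_result} list; see the fields above.
#'   \code{as.data.frame()} turns it into a one-row summary.
#' @export
measure_suite <- function(replication, config = arena_config(),
                          n_generations = 20, n_trials = 20, seed = 1,
                          reach_radius = 11) {
  bq <- barycenter_test(replication, config, n_generations, n_trials, seed)
  leader <- identify_leader(bq)
  indfit <- individual_fitness_test(replication, config, n_generations,
                                    n_trials, seed)
  cfi <- if (!is.null(replication$group_fitness) &&
             length(replication$group_fitness) >= n_generations)
    collective_fitness_indicator(replication, n_generations) else NA_real_
  cap <- capability_of_followers(replication, leader, config, n_trials, seed,
                                 reach_radius)
  runs <- leader_free_runs(replication, config, n_trials, seed)
  i <- match(leader, robot_colours())
  mob <- mean(vapply(runs, function(r) as.numeric(r$cells_visited[i]),
                     numeric(1)))
  vis <- mean(vapply(runs, function(r) as.numeric(r$vision_steps[i]),
                     numeric(1)))
  structure(list(barycenter_quadruple = bq,
                 leadership_measure = leadership_measure(bq),
                 leader = leader,
                 individual_fitness = indfit,
                 collective_fitness_indicator = cfi,
                 capability_of_followers = cap,
                 mobility_of_leaders = mob,
                 vision_of_leaders = vis,
                 n_generations = n_generations, n_trials = n_trials,
                 seed = seed),
            class = "measure_suite_result")
}

#' @export
print.measure_suite_result <- function(x, ...) {
  cat("<measure_suite_result>\n")
  cat("  barycenter quadruple (cm): ",
      paste(sprintf("%s=%.2f", names(x$barycenter_quadruple),
                    x$barycenter_quadruple), collapse = ", "), "\n", sep = "")
  cat(sprintf("  leader: %s   leadership measure: %.3f cm\n",
              x$leader, x$leadership_measure))
  cat("  individual fitness (steps): ",
      paste(sprintf("%s=%.1f", names(x$individual_fitness),
                    x$individual_fitness), collapse = ", "), "\n", sep = "")
  cat(sprintf("  collective fitness indicator: %.1f\n",
              x$collective_fitness_indicator))
  cat(sprintf("  capability of followers: %.1f steps\n",
              x$capability_of_followers))
  cat(sprintf("  mobility of leader: %.1f cells   vision of leader: %.1f steps\n",
              x$mobility_of_leaders, x$vision_of_leaders))
  invisible(x)
}

#' @export
as.data.frame.measure_suite_result <- function(x, ...) {
  bq <- as.numeric(x$barycenter_quadruple)
  indf <- as.numeric(x$individual_fitness)
  data.frame(bary_green = bq[1], bary_blue = bq[2], bary_light_blue = bq[3],
             bary_yellow = bq[4],
             leadership_measure = x$leadership_measure, leader = x$leader,
             indfit_green = indf[1], indfit_blue = indf[2],
             indfit_light_blue = indf[3], indfit_yellow = indf[4],
             collective_fitness_indicator = x$collective_fitness_indicator,
             capability_of_followers = x$capability_of_followers,
             mobility_of_leaders = x$mobility_of_leaders,
             vision_of_leaders = x$vision_of_leaders,
             stringsAsFactors = FALSE)
}
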