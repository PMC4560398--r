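# The Heterogeneous Genetic Algorithm (HGA): each robot role (colour) has
# its own population of genotypes which is evaluated in mixed teams but
# ranked and reproduced separately, sustaining genetic variation between
# team members.

#' Genetic-algorithm hyperparameters
#'
#' @param populations_size Genotypes per population; also the number of team
#'   trials per generation (the permutation schedule evaluates every
#'   genotype exactly once per generation).
#' @param parents_count Top-ranked genotypes selected per population.
#' @param offspring_per_parent Offspring per parent;
#'   \code{parents_count * offspring_per_parent} must rebuild the population.
#' @param elitism_count How many of each parent's offspring are exact copies
#'   (the rest are mutated).
#' @param mutation_rate Independent per-bit flip probability.
#' @return A validated \code{ga_config} list.
#' @export
ga_config <- function(populations_size = 20, parents_count = 4,
                      offspring_per_parent = 5, elitism_count = 1,
                      mutation_rate = 0.02) {
  stopifnot(parents_count * offspring_per_parent == populations_size,
            elitism_count >= 0, elitism_count <= offspring_per_parent,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(populations_size = as.integer(populations_size),
                 parents_count = as.integer(parents_count),
                 offspring_per_parent = as.integer(offspring_per_parent),
                 elitism_count = as.integer(elitism_count),
                 mutation_rate = mutation_rate),
            class = "ga_config")
}

#' Create one population of random genotypes
#'
#' @param colour_role The chassis colour this population controls (fixed for
#'   the whole evolutionary run).
#' @param size Number of genotypes.
#' @return A \code{population}: list with \code{genotypes} and
#'   \code{colour_role}. Uses the current R RNG stream.
#' @export
new_population <- function(colour_role, size = 20) {
  stopifnot(colour_role %in% robot_colours())
  structure(list(genotypes = random_genotype(size), colour_role = colour_role),
            class = "population")
}

#' Sample a generation's trial schedule
#'
#' One independent uniform permutation of the genotype indices per
#' population; trial t pairs the t-th element of each permutation. This
#' guarantees that no index quadruple repeats within a generation and that
#' every genotype is evaluated exactly once. Uses the current R RNG stream.
#'
#' @param size Population size.
#' @return \code{size} x 4 integer matrix of 1-based genotype indices; row t
#'   is the quadruple of trial t.
#' @export
sample_schedule <- function(size = 20) {
  m <- vapply(1:4, function(p) sample.int(size), integer(size))
  colnames(m) <- robot_colours()
  m
}

# flip each bit independently with probability rate (current R RNG stream)
mutate_genotype <- function(bits, rate) {
  flip <- stats::runif(length(bits)) < rate
  bits[flip] <- 1L - bits[flip]
  bits
}

#' Rank a population and produce the next generation
#'
#' Genotypes are sorted by descending fitness (ties broken by lower index);
#' each of the top \code{parents_count} parents contributes
#' \code{elitism_count} bit-identical copies and
#' \code{offspring_per_parent - elitism_count} mutated copies (independent
#' per-bit flips at \code{mutation_rate}). Population size is conserved.
#' Uses the current R RNG stream for mutation.
#'
#' @param population A \code{population}.
#' @param fitness Numeric fitness vector, one value per genotype.
#' @param ga A [ga_config()].
#' @return The next-generation \code{population}.
#' @export
rank_and_reproduce <- function(population, fitness, ga = ga_config()) {
  n <- length(population$genotypes)
  stopifnot(length(fitness) == n, n == ga$populations_size)
  ord <- order(-fitness, seq_len(n))
  parents <- ord[seq_len(ga$parents_count)]
  offspring <- vector("list", n)
  k <- 0
  for (p in parents) {
    g <- population$genotypes[[p]]
    for (j in seq_len(ga$offspring_per_parent)) {
      k <- k + 1
      offspring[[k]] <- if (j <= ga$elitism_count) g
                        else mutate_genotype(g, ga$mutation_rate)
    }
  }
  population$genotypes <- offspring
  population
}

#' Run one trial and return the full log
#'
#' Convenience wrapper over [simulate_trial()] that always keeps the
#' trajectory log.
#'
#' @inheritParams simulate_trial
#' @return List with \code{fitness} (per robot) and \code{log}.
#' @export
run_trial <- function(team, config, seed, fitness_mode = "collective",
                      log_sensors = FALSE) {
  res <- simulate_trial(team, config, seed, fitness_mode = fitness_mode,
                        keep_log = TRUE, log_sensors = log_sensors)
  list(fitness = res$fitness, log = res$log)
}

# evaluate one generation: permutation schedule, one trial per quadruple;
# returns per-genotype fitness (size x 4), the schedule, and group fitness
evaluate_generation <- function(populations, config, master_seed, gen,
                                ga, fitness_mode) {
  size <- ga$populations_size
  schedule <- with_seed(derive_seed(master_seed, "schedule", gen),
                        sample_schedule(size))
  fitness <- matrix(NA_real_, size, 4)
  best_trial <- -Inf
  for (t in seq_len(size)) {
    idx <- schedule[t, ]
    team <- genotype_team(lapply(1:4, function(p)
      populations[[p]]$genotypes[[idx[p]]]))
    res <- simulate_trial(team, config,
                          seed = derive_seed(master_seed, "trial", gen, t),
                          fitness_mode = fitness_mode)
    for (p in 1:4) fitness[idx[p], p] <- res$fitness[p]
    best_trial <- max(best_trial, max(res$fitness))
  }
  list(fitness = fitness, schedule = schedule, group_fitness = best_trial)
}

#' Run one evolutionary replication
#'
#' Initializes four random populations (one per robot colour) and loops:
#' sample a permutation trial schedule, evaluate all teams, record the
#' best-of-generation team, then rank and reproduce each population
#' separately. Fully reproducible from the master seed: every random draw
#' comes from a named substream derived from it, so a run can also be
#' extended or resumed without changing its trajectory.
#'
#' @param config An [arena_config()].
#' @param generations Number of generations.
#' @param seed Master seed of the replication.
#' @param ga A [ga_config()].
#' @param fitness_mode Fitness used for selection ("collective" is the
#'   default; "individual" and "mixed" are the rejected alternatives, kept
#'   as options).
#' @param checkpoint_every Archive full populations every this many
#'   generations (and at the final generation).
#' @param resume A previous \code{replication_result} to extend; its stored
#'   populations and series are continued up to \code{generations}.
#' @param verbose Print a fitness line per generation.
#' @return A \code{replication_result}: list with \code{group_fitness}
#'   (per-generation best collective trial score), \code{fitness} (array
#'   generations x size x 4 of per-genotype scores), \code{best_teams}
#'   (per-generation list of the 4 top-ranked genotypes),
#'   \code{checkpoints} (archived populations), \code{populations} (final),
#'   \code{seed}, \code{generations}, \code{ga}, \code{fitness_mode}.
#' @export
run_replication <- function(config = arena_config(), generations = 600,
                            seed = 1, ga = ga_config(),
                            fitness_mode = "collective",
                            checkpoint_every = 10, resume = NULL,
                            verbose = FALSE) {
  stopifnot(generations >= 1)
  size <- ga$populations_size
  if (is.null(resume)) {
    populations <- with_seed(derive_seed(seed, "init"),
                             lapply(robot_colours(), new_population, size = size))
    g0 <- 0L
    group_fitness <- numeric(0)
    fitness <- array(NA_real_, c(0, size, 4))
    best_teams <- list()
    checkpoints <- list()
  } else {
    stopifnot(inherits(resume, "replication_result"),
              resume$seed == seed, generations > resume$generations)
    populations <- resume$populations
    g0 <- resume$generations
    group_fitness <- resume$group_fitness
    fitness <- resume$fitness
    best_teams <- resume$best_teams
    checkpoints <- resume$checkpoints
  }
  add_fit <- array(NA_real_, c(generations - g0, size, 4))
  for (gen in seq.int(g0 + 1L, generations)) {
    ev <- evaluate_generation(populations, config, seed, gen, ga, fitness_mode)
    group_fitness[gen] <- ev$group_fitness
    add_fit[gen - g0, , ] <- ev$fitness
    best_teams[[gen]] <- lapply(1:4, function(p) {
      i <- order(-ev$fitness[, p], seq_len(size))[1]
      populations[[p]]$genotypes[[i]]
    })
    populations <- with_seed(derive_seed(seed, "mutation", gen),
                             lapply(1:4, function(p)
                               rank_and_reproduce(populations[[p]],
                                                  ev$fitness[, p], ga)))
    if (gen %% checkpoint_every == 0 || gen == generations)
      checkpoints[[as.character(gen)]] <- populations
    if (verbose)
      message(sprintf("generation %d: best group fitness %.0f",
                      gen, ev$group_fitness))
  }
  if (g0 > 0) {
    full <- array(NA_real_, c(generations, size, 4))
    full[seq_len(g0), , ] <- resume$fitness
    full[seq.int(g0 + 1, generations), , ] <- add_fit
    fitness <- full
  } else {
    fitness <- add_fit
  }
  structure(list(group_fitness = group_fitness, fitness = fitness,
                 best_teams = best_teams, checkpoints = checkpoints,
                 populations = populations, seed = seed,
                 generations = as.integer(generations), ga = ga,
                 fitness_mode = fitness_mode, config = config),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  last <- utils::tail(x$group_fitness, 20)
  cat("<replication_result> seed ", x$seed, ", ", x$generations,
      " generations\n  best group fitness: final ",
      x$group_fitness[x$generations], ", last-20 mean ",
      round(mean(last), 1), " (max possible ",
      x$config$steps_per_trial, ")\n", sep = "")
  invisible(x)
}

#' Run several replications
#'
#' @param n_replications Number of independent replications.
#' @param seeds Optional vector of master seeds (default 1..n).
#' @inheritParams run_replication
#' @return List of \code{replication_result} objects.
#' @export
run_experiment <- function(n_replications = 30, config = arena_config(),
                           generations = 600, seeds = seq_len(n_replications),
                           ga = ga_config(), fitness_mode = "collective",
                           checkpoint_every = 10, verbose = FALSE) {
  lapply(seeds, function(s)
    run_replication(config, generations, seed = s, ga = ga,
                    fitness_mode = fitness_mode,
                    checkpoint_every = checkpoint_every, verbose = verbose))
}

# team of the 4 top-ranked genotypes at generation g (1-based)
team_at_generation <- function(replication, g) {
  UseMethod("team_at_generation")
}

#' @export
team_at_generation.replication_result <- function(replication, g) {
  stopifnot(g >= 1, g <= replication$generations)
  genotype_team(replication$best_teams[[g]])
}

#' @export
team_at_generation.scripted_replication <- function(replication, g) {
  if (!is.null(replication$teams)) replication$teams[[g]] else replication$team
}
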