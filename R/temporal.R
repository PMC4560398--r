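# Temporal analysis over generations: measure curves sampled every 10
# generations, Friedman super-smoothing, derivatives, event ordering
# (skills before leadership?), Pearson correlations, and the
# leadership-style classifier.

#' Construct a temporal curve
#'
#' @param generation Strictly increasing generation samples.
#' @param value Measure values, same length.
#' @return A data frame with columns \code{generation} and \code{value},
#'   class \code{temporal_curve}.
#' @export
temporal_curve <- function(generation, value) {
  stopifnot(length(generation) == length(value),
            !is.unsorted(generation, strictly = TRUE))
  structure(data.frame(generation = as.numeric(generation),
                       value = as.numeric(value)),
            class = c("temporal_curve", "data.frame"))
}

check_aligned <- function(curves) {
  g <- curves[[1]]$generation
  for (cv in curves)
    if (!isTRUE(all.equal(cv$generation, g)))
      stop("curves are not sampled on the same generation grid")
  g
}

#' Temporal measure curves of a replication
#'
#' Re-runs single-generation versions of the barycenter and individual
#' fitness protocols at every \code{sample_every}-th generation and reads
#' the collective fitness series from the stored record. Gives the
#' generation-resolved view of when skills and leadership appear.
#'
#' @param replication A \code{replication_result}.
#' @param config An [arena_config()].
#' @param sample_every Sampling step in generations (default 10).
#' @param n_trials Trials per robot per sampled generation.
#' @param seed Master seed.
#' @param bary_exclude_pinned Barycenter over free robots only.
#' @return List with \code{barycenter} and \code{individual_fitness} (each a
#'   list of 4 [temporal_curve()]s named by colour) and \code{collective}
#'   (one curve).
#' @export
temporal_curves <- function(replication, config = arena_config(),
                            sample_every = 10, n_trials = 20, seed = 1,
                            bary_exclude_pinned = FALSE) {
  gens <- seq.int(sample_every, replication$generations, by = sample_every)
  if (length(gens) < 2) stop("too few generations to sample curves")
  bary <- matrix(NA_real_, length(gens), 4)
  indf <- matrix(NA_real_, length(gens), 4)
  for (s in seq_along(gens)) {
    g <- gens[s]
    team <- team_at_generation(replication, g)
    for (pin in 1:4) {
      bary[s, pin] <- mean(vapply(seq_len(n_trials), function(tr)
        simulate_trial(team, config,
                       seed = derive_seed(seed, "tbary", g, pin, tr),
                       pinned = pin,
                       bary_exclude_pinned = bary_exclude_pinned
                       )$mean_dist_barycenter[pin], numeric(1)))
    }
    zf <- vapply(seq_len(n_trials), function(tr)
      simulate_trial(team, config,
                     seed = derive_seed(seed, "tindfit", g, tr)
                     )$steps_in_zone, numeric(4))
    indf[s, ] <- rowMeans(zf)
  }
  cols <- robot_colours()
  list(barycenter = stats::setNames(lapply(1:4, function(i)
         temporal_curve(gens, bary[, i])), cols),
       individual_fitness = stats::setNames(lapply(1:4, function(i)
         temporal_curve(gens, indf[, i])), cols),
       collective = temporal_curve(gens, replication$group_fitness[gens]))
}

#' Mean pairwise gap among the four barycenter curves
#'
#' At each sampled generation, the mean absolute difference over the six
#' unordered pairs of the four per-robot barycenter curves. A rising gap
#' curve signals a growing leader/follower asymmetry.
#'
#' @param curves List of 4 aligned [temporal_curve()]s.
#' @return A [temporal_curve()].
#' @export
distance_among_barycenter_curves <- function(curves) {
  stopifnot(length(curves) == 4)
  g <- check_aligned(curves)
  v <- vapply(seq_along(g), function(s) {
    x <- vapply(curves, function(cv) cv$value[s], numeric(1))
    mean(abs(c(x[1] - x[2], x[1] - x[3], x[1] - x[4],
               x[2] - x[3], x[2] - x[4], x[3] - x[4])))
  }, numeric(1))
  temporal_curve(g, v)
}

#' Smooth a temporal curve with Friedman's super-smoother
#'
#' Variable-span running-linear smoother with cross-validated span selection
#' (\code{stats::supsmu}), evaluated on the curve's own generation grid.
#'
#' @param curve A [temporal_curve()] with at least 10 samples.
#' @param ... Passed to [stats::supsmu()] (e.g. \code{bass}).
#' @return The smoothed [temporal_curve()].
#' @export
smooth_curve <- function(curve, ...) {
  if (nrow(curve) < 10) stop("too few samples to smooth")
  sm <- stats::supsmu(curve$generation, curve$value, ...)
  v <- stats::approx(sm$x, sm$y, xout = curve$generation, rule = 2)$y
  temporal_curve(curve$generation, v)
}

#' Finite-difference derivative of a temporal curve
#'
#' Central differences in the interior, one-sided at the ends, with respect
#' to the generation axis.
#'
#' @param curve A [temporal_curve()] with at least 2 samples.
#' @return A [temporal_curve()] of the derivative (value per generation).
#' @export
curve_derivative <- function(curve) {
  g <- curve$generation
  v <- curve$value
  n <- length(g)
  if (n < 2) stop("need at least 2 samples")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (g[2] - g[1])
  d[n] <- (v[n] - v[n - 1]) / (g[n] - g[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (g[i + 1] - g[i - 1])
  }
  temporal_curve(g, d)
}

#' Do skills rise before leadership?
#'
#' Smooths the leader's individual-fitness curve and the negation of its
#' barycenter curve (the barycenter falls as leadership consolidates, so the
#' inverted curve rises), differentiates both, and compares the generations
#' of maximum slope. TRUE when the individual-fitness derivative peaks
#' strictly earlier; ties give FALSE.
#'
#' @param fitness_curve The leader's individual-fitness [temporal_curve()].
#' @param barycenter_curve The leader's barycenter [temporal_curve()].
#' @return Logical scalar.
#' @export
event_order <- function(fitness_curve, barycenter_curve) {
  check_aligned(list(fitness_curve, barycenter_curve))
  df <- curve_derivative(smooth_curve(fitness_curve))
  inv <- temporal_curve(barycenter_curve$generation, -barycenter_curve$value)
  db <- curve_derivative(smooth_curve(inv))
  gf <- df$generation[which.max(df$value)]
  gb <- db$generation[which.max(db$value)]
  gf < gb
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson correlation is undefined for a constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Classify leadership styles from the leaders' vision values
#'
#' Heuristic analogue of sorting the per-replication vision activations and
#' cutting the bar plot where it jumps: values are sorted ascending and the
#' two largest consecutive gaps become breakpoints; the lowest group is
#' \code{passive}, the middle \code{weak_active}, the highest
#' \code{strong_active}. Manual thresholds can override the gap heuristic.
#'
#' @param vision Per-replication vision values (length >= 3).
#' @param mobility Optional per-replication mobility values, carried through
#'   for reporting (not used by the gap heuristic).
#' @param thresholds Optional manual cut points \code{c(t1, t2)}; a value v
#'   is passive if \code{v <= t1}, weak_active if \code{v <= t2}, else
#'   strong_active.
#' @return Factor of labels (levels passive, weak_active, strong_active) in
#'   the input order. If all values are equal the input is degenerate: all
#'   labels are \code{passive} and the attribute \code{degenerate} is TRUE.
#' @export
classify_style <- function(vision, mobility = NULL, thresholds = NULL) {
  n <- length(vision)
  if (n < 3) stop("need at least 3 replications to classify styles")
  lev <- c("passive", "weak_active", "strong_active")
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
    lab <- ifelse(vision <= thresholds[1], "passive",
                  ifelse(vision <= thresholds[2], "weak_active",
                         "strong_active"))
    return(factor(lab, levels = lev))
  }
  if (max(vision) == min(vision)) {
    out <- factor(rep("passive", n), levels = lev)
    attr(out, "degenerate") <- TRUE
    warning("all vision values equal; style classification is degenerate")
    return(out)
  }
  ord <- order(vision)
  sorted <- vision[ord]
  gaps <- diff(sorted)
  cuts <- sort(order(-gaps)[1:2])  # positions of the two largest gaps
  grp <- findInterval(seq_len(n), c(cuts[1] + 0.5, cuts[2] + 0.5)) + 1
  lab <- character(n)
  lab[ord] <- lev[grp]
  factor(lab, levels = lev)
}

#' Aggregate replication measures into an analysis report
#'
#' Takes one measure row per replication (see
#' \code{as.data.frame.measure_suite_result}), attaches leadership-style
#' labels, and computes the three headline Pearson correlations: leadership
#' measure vs collective fitness indicator, capability of followers vs
#' mobility of leaders, and mobility vs vision of leaders.
#'
#' @param measures A data frame with one row per replication, containing at
#'   least the columns \code{leadership_measure},
#'   \code{collective_fitness_indicator}, \code{capability_of_followers},
#'   \code{mobility_of_leaders}, \code{vision_of_leaders}.
#' @return A \code{leadership_report}: list with the labelled table and the
#'   three correlation blocks.
#' @export
analysis_report <- function(measures) {
  stopifnot(is.data.frame(measures), nrow(measures) >= 3)
  style <- classify_style(measures$vision_of_leaders,
                          measures$mobility_of_leaders)
  measures$style <- as.character(style)
  structure(list(
    table = measures,
    cor_leadership_fitness = pearson(measures$leadership_measure,
                                     measures$collective_fitness_indicator),
    cor_capability_mobility = pearson(measures$capability_of_followers,
                                      measures$mobility_of_leaders),
    cor_mobility_vision = pearson(measures$mobility_of_leaders,
                                  measures$vision_of_leaders)
  ), class = "leadership_report")
}

#' @export
print.leadership_report <- function(x, ...) {
  cat("<leadership_report> ", nrow(x$table), " replications\n", sep = "")
  cat("  styles: ", paste(sprintf("%s=%d",
      names(table(x$table$style)), as.integer(table(x$table$style))),
      collapse = ", "), "\n", sep = "")
  f <- function(nm, b) cat(sprintf("  %s: rho = %.3f, p = %.3g, n = %d\n",
                                   nm, b$rho, b$p, b$n))
  f("leadership ~ collective fitness", x$cor_leadership_fitness)
  f("capability ~ mobility", x$cor_capability_mobility)
  f("mobility ~ vision", x$cor_mobility_vision)
  invisible(x)
}
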