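test_that("pairwise gap among barycenter curves follows pair arithmetic", {
  g <- seq(10, 100, by = 10)
  flat <- function(v) temporal_curve(g, rep(v, length(g)))
  same <- distance_among_barycenter_curves(list(flat(4), flat(4), flat(4),
                                                flat(4)))
  expect_equal(same$value, rep(0, 10))
  # (0,0,0,c): 3 of the 6 pairs differ by c -> mean gap c/2
  gap <- distance_among_barycenter_curves(list(flat(0), flat(0), flat(0),
                                               flat(6)))
  expect_equal(gap$value, rep(3, 10))
  # translation invariance
  shifted <- distance_among_barycenter_curves(list(flat(10), flat(10),
                                                   flat(10), flat(16)))
  expect_equal(shifted$value, gap$value)
  expect_error(distance_among_barycenter_curves(list(flat(0), flat(0), flat(0),
    temporal_curve(g + 5, rep(0, 10)))), "grid")
})

test_that("the super-smoother passes lines through and tames noise", {
  g <- seq(10, 600, by = 10)
  line <- temporal_curve(g, 0.5 * g + 3)
  expect_equal(smooth_curve(line)$value, line$value, tolerance = 1e-6)
  const <- temporal_curve(g, rep(2, length(g)))
  expect_equal(smooth_curve(const)$value, const$value, tolerance = 1e-9)
  # noisy sigmoid: smoothing should beat the noise floor
  set.seed(5)
  truth <- 1000 / (1 + exp(-(g - 300) / 50))
  sigma <- 50
  noisy <- temporal_curve(g, truth + rnorm(length(g), 0, sigma))
  sm <- smooth_curve(noisy)
  rmse <- sqrt(mean((sm$value - truth)^2))
  expect_lt(rmse, sigma)
})

test_that("derivatives recover slopes, curvature and inflection points", {
  g <- seq(10, 400, by = 10)
  lin <- curve_derivative(temporal_curve(g, 2.5 * g - 7))
  expect_equal(lin$value, rep(2.5, length(g)))
  quad <- curve_derivative(temporal_curve(g, g^2))
  expect_equal(which.max(quad$value), length(g))
  expect_equal(quad$value[2:(length(g) - 1)], 2 * g[2:(length(g) - 1)])
  # logistic: derivative peaks at the inflection sample
  lg <- temporal_curve(g, 1 / (1 + exp(-(g - 200) / 30)))
  dv <- curve_derivative(lg)
  expect_equal(dv$generation[which.max(dv$value)], 200)
})

test_that("event order detects fitness rising before leadership", {
  g <- seq(10, 600, by = 10)
  logistic <- function(center) 1000 / (1 + exp(-(g - center) / 40))
  fit <- temporal_curve(g, logistic(200))
  # barycenter falls as leadership emerges
  bary <- temporal_curve(g, 40 - 30 / 1000 * logistic(300))
  expect_true(event_order(fit, bary))
  # reversed centering and exact ties are both FALSE
  fit2 <- temporal_curve(g, logistic(300))
  bary2 <- temporal_curve(g, 40 - 30 / 1000 * logistic(200))
  expect_false(event_order(fit2, bary2))
  expect_false(event_order(fit, temporal_curve(g, -fit$value)))
})

test_that("pearson matches the covariance formula and flags degenerate input", {
  x <- c(1.2, 3.5, 2.2, 8, 4.4, 5.1, 0.3, 9.9, 6.6, 7.1)
  y <- 2 * x + 1
  expect_equal(pearson(x, y)$rho, 1)
  expect_equal(pearson(x, -x)$rho, -1)
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- 0.4 * a + rnorm(30)
    got <- pearson(a, b)
    rho <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tstat <- rho * sqrt((30 - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), 30 - 2)
    expect_equal(got$rho, rho, tolerance = 1e-12)
    expect_equal(got$p, p, tolerance = 1e-12)
    expect_equal(got$n, 30)
  }
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("style classification cuts the two largest gaps in sorted vision", {
  v <- c(10, 12, 500, 520, 2500, 2600)
  got <- classify_style(v)
  expect_equal(as.character(got), c("passive", "passive", "weak_active",
                                    "weak_active", "strong_active",
                                    "strong_active"))
  # scale invariance
  expect_equal(as.character(classify_style(7 * v)), as.character(got))
  # input order is preserved
  shuf <- c(2500, 10, 520, 2600, 12, 500)
  got2 <- classify_style(shuf)
  expect_equal(as.character(got2), c("strong_active", "passive", "weak_active",
                                     "strong_active", "passive",
                                     "weak_active"))
  # manual thresholds override the heuristic
  man <- classify_style(v, thresholds = c(15, 3000))
  expect_equal(as.character(man), c("passive", "passive", "weak_active",
                                    "weak_active", "weak_active",
                                    "weak_active"))
  # degenerate: all equal
  expect_warning(deg <- classify_style(rep(5, 6)), "degenerate")
  expect_true(attr(deg, "degenerate"))
  expect_equal(length(unique(as.character(deg))), 1L)
})

test_that("temporal curves respond only where the archive changes", {
  cfg <- short_config(300)
  # a pseudo-replication whose team switches behaviour at generation 30:
  # before, everyone random-walks; after, a passive leader group
  led <- make_fixture("passive_leader_group", cfg, seed = 1)$team
  rnd <- make_fixture("leaderless_group", cfg, seed = 1)$team
  fake <- scripted_replication(led, generations = 50,
                               group_fitness = c(rep(0, 30), rep(100, 20)),
                               teams = c(rep(list(rnd), 30),
                                         rep(list(led), 20)))
  tc <- temporal_curves(fake, cfg, sample_every = 10, n_trials = 2, seed = 3)
  expect_equal(tc$collective$generation, c(10, 20, 30, 40, 50))
  expect_equal(tc$collective$value, c(0, 0, 0, 100, 100))
  # before the switch all four barycenter values are alike; afterwards the
  # leader (green) separates downwards
  lm_pre <- leadership_measure(vapply(tc$barycenter, function(cv)
    cv$value[2], numeric(1)))
  lm_post <- leadership_measure(vapply(tc$barycenter, function(cv)
    cv$value[5], numeric(1)))
  expect_lt(lm_pre, lm_post)
})

test_that("the analysis report carries styles and three correlation blocks", {
  set.seed(44)
  n <- 30
  mobility <- runif(n, 10, 200)
  measures <- data.frame(
    leadership_measure = runif(n, 1, 12),
    collective_fitness_indicator = runif(n, 200, 2500),
    capability_of_followers = 3000 - 10 * mobility + rnorm(n, 0, 150),
    mobility_of_leaders = mobility,
    vision_of_leaders = c(runif(10, 0, 100), runif(10, 800, 1200),
                          runif(10, 2200, 3000)))
  rep <- analysis_report(measures)
  expect_s3_class(rep, "leadership_report")
  expect_equal(sort(as.character(unique(rep$table$style))),
               c("passive", "strong_active", "weak_active"))
  for (blk in list(rep$cor_leadership_fitness, rep$cor_capability_mobility,
                   rep$cor_mobility_vision)) {
    expect_true(is.numeric(blk$rho) && abs(blk$rho) <= 1)
    expect_true(blk$p >= 0 && blk$p <= 1)
    expect_equal(blk$n, n)
  }
  expect_lt(rep$cor_capability_mobility$rho, 0)
  expect_output(print(rep), "mobility ~ vision")
})
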