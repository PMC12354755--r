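test_that("probability of direction matches brute-force counting", {
  expect_equal(probability_of_direction(c(1, 2, -1, 3)), 75)
  expect_equal(probability_of_direction(rep(2, 10)), 100)
  expect_equal(probability_of_direction(c(-3, -1, 1, 3)), 50)

  set.seed(1)
  for (i in 1:100) {
    x <- rnorm(sample(5:200, 1), mean = runif(1, -1, 1))
    if (i %% 7 == 0) x[sample(length(x), 2)] <- 0
    n_pos <- 0; n_neg <- 0
    for (v in x) {  # brute-force oracle
      if (v > 0) n_pos <- n_pos + 1
      if (v < 0) n_neg <- n_neg + 1
    }
    expect_identical(probability_of_direction(x),
                     100 * max(n_pos, n_neg) / length(x))
  }
  expect_error(probability_of_direction(numeric(0)), "empty")
})

test_that("highest density interval matches closed-form targets", {
  set.seed(2)
  x <- rnorm(1e5)
  h <- hdi(x, mass = 0.89)
  z <- qnorm((1 + 0.89) / 2)  # 1.598 for a symmetric unimodal density
  expect_lt(abs(h[["lower"]] + z), 0.02)
  expect_lt(abs(h[["upper"]] - z), 0.02)

  expect_equal(unname(hdi(rep(3.2, 50))), c(3.2, 3.2))

  u <- runif(1e5)
  expect_lt(abs(diff(unname(hdi(u, 0.89))) - 0.89), 0.01)

  # permutation invariance and range bound
  y <- rnorm(500)
  expect_identical(hdi(y), hdi(sample(y)))
  expect_lte(diff(unname(hdi(y))), diff(range(y)))

  expect_error(hdi(rnorm(100), mass = 1.2), "mass")
})

test_that("ROPE fractions and decisions follow the 0.1 SD convention", {
  r <- rope_fraction(rnorm(100), 1)
  expect_equal(unname(r$rope), c(-0.1, 0.1))

  far <- rope_fraction(runif(1000, 0.2, 0.9), 1)
  expect_equal(far$pct_inside, 0)
  expect_equal(far$decision, "reject-null")

  null <- rope_fraction(rep(0, 1000), 1)
  expect_equal(null$pct_inside, 100)
  expect_equal(null$decision, "accept-null")

  # brute-force counting equality on random vectors
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(sample(10:500, 1), sd = runif(1, 0.01, 2))
    s <- runif(1, 0.1, 3)
    cnt <- sum(vapply(x, function(v) v >= -0.1 * s && v <= 0.1 * s,
                      logical(1)))
    expect_identical(rope_fraction(x, s)$pct_inside, 100 * cnt / length(x))
  }
  expect_error(rope_fraction(rnorm(10), 0), "positive")
})

test_that("drug contrasts are computed draw-wise", {
  ids <- c("P01", "P02", "P03")
  # zero offsets in every draw: contrast identically zero
  pos0 <- fake_posterior(fake_crossover_cols(ids, mu_beta = 0.4), ids)
  expect_true(all(drug_contrast(pos0, "beta") == 0))

  # known offset: contrast equals the closed form in every draw
  pos1 <- fake_posterior(fake_crossover_cols(ids, mu_beta = 0.2,
                                             mu_delta_beta = 0.5), ids)
  expect_equal(as.numeric(drug_contrast(pos1, "beta")),
               rep(10 * pnorm(0.7) - 10 * pnorm(0.2), 50))

  # placebo - placebo is identically zero
  pl <- group_natural_draws(pos1, "beta", "placebo")
  expect_true(all(pl - pl == 0))

  # single-session fits have no drug parameters
  coh <- generate_cohort_behaviour(cohort_ground_truth(), 3, seed = 4)
  m <- build_model(coh$data[coh$data$drug_state == "placebo", ],
                   "gain", "single_session")
  f <- sample_posterior(m, chains = 2, iter = 120, warmup = 60, seed = 5)
  expect_error(drug_contrast(f, "beta"), "crossover")
})

test_that("optimal-grid simulation respects chance-level rows and degenerate tasks", {
  opt <- simulate_optimal_grid("gain", alpha_step = 0.25, beta_step = 2.5,
                               n_agents_per_cell = 400, seed = 6)
  surf <- opt$hit_rate_surface
  n_obs <- 400 * 48
  se3 <- 3 * sqrt(0.25 / n_obs)
  # no learning (alpha = 0) or random choice (beta = 0): chance
  expect_true(all(abs(surf[1, ] - 0.5) < se3))
  expect_true(all(abs(surf[, 1] - 0.5) < se3))

  # uninformative task: flat surface, argmax not meaningfully above
  # chance (trials within an agent are autocorrelated once learning is
  # on, so the bound is absolute, not a naive binomial SE)
  flat <- simulate_optimal_grid("gain", alpha_step = 0.25, beta_step = 2.5,
                                n_agents_per_cell = 400,
                                contingency = 0.5, seed = 7)
  # high-alpha/high-beta agents lock onto an option for long runs, so
  # cell SEs reach ~0.015 at 400 agents; bounds sit well below the real
  # task's ~0.25 structure while tolerating that noise
  expect_lt(max(flat$hit_rate_surface) - 0.5, 0.05)
  expect_lt(diff(range(flat$hit_rate_surface)), 0.08)

  expect_error(simulate_optimal_grid("gain", alpha_step = 2), "degenerate")
})

test_that("joint distances follow the scalar formula draw by draw", {
  ids <- c("P01", "P02")
  opt <- structure(list(alpha_star = 0.25, beta_star = 10,
                        condition = "gain"), class = "optimal_point")

  # draws at the optimum have zero distance
  at_opt <- fake_posterior(
    fake_crossover_cols(ids, mu_alpha = qnorm(0.25), mu_beta = 40), ids)
  d0 <- joint_distance_posterior(at_opt, opt)
  expect_equal(unname(d0$placebo), rep(0, 50))

  # (0, 0) against (1, 10): sqrt(101)
  opt2 <- structure(list(alpha_star = 1, beta_star = 10,
                         condition = "gain"), class = "optimal_point")
  at00 <- fake_posterior(
    fake_crossover_cols(ids, mu_alpha = -40, mu_beta = -40), ids)
  expect_equal(unname(joint_distance_posterior(at00, opt2)$placebo),
               rep(sqrt(101), 50))

  # equals the scalar formula on every draw; invariant to draw order
  set.seed(8)
  cols <- fake_crossover_cols(ids)
  cols$mu_alpha <- rnorm(50); cols$mu_beta <- rnorm(50)
  cols$mu_delta_beta <- rnorm(50, 0.3)
  pos <- fake_posterior(cols, ids)
  d <- joint_distance_posterior(pos, opt)
  manual <- sqrt((pnorm(cols$mu_alpha) - 0.25)^2 +
                   (10 * pnorm(cols$mu_beta) - 10)^2)
  expect_equal(unname(d$placebo), manual)
  expect_equal(d$contrast, d$atomoxetine - d$placebo)
  perm <- sample(50)
  cols_p <- lapply(cols, `[`, perm)
  expect_equal(sort(joint_distance_posterior(
    fake_posterior(cols_p, ids), opt)$placebo), sort(d$placebo))

  # cohort whose atomoxetine truth sits at the optimum: contrast mass
  # predominantly negative
  cols2 <- fake_crossover_cols(ids, mu_alpha = qnorm(0.6), mu_beta = -1)
  cols2$mu_alpha <- rnorm(50, qnorm(0.6), 0.05)
  cols2$mu_beta <- rnorm(50, -1, 0.05)
  cols2$mu_delta_alpha <- rnorm(50, qnorm(0.25) - qnorm(0.6), 0.05)
  cols2$mu_delta_beta <- rnorm(50, 41, 0.05)
  pos2 <- fake_posterior(cols2, ids)
  dc <- joint_distance_posterior(pos2, opt)
  expect_gt(mean(dc$contrast < 0), 0.95)
})

test_that("contrast summaries assemble the house statistics", {
  set.seed(9)
  x <- rnorm(4000, 0.5, 0.2)
  s <- summarize_contrast(x, group_sd = 1)
  expect_equal(s$median, median(x))
  expect_equal(s$p_dir, probability_of_direction(x))
  expect_equal(s$rope_pct, rope_fraction(x, 1)$pct_inside)
  path <- tempfile(fileext = ".json")
  repjs <- write_contrast_summary(x, 1, path, label = "demo")
  expect_true(file.exists(path))
  got <- jsonlite::read_json(path)
  expect_equal(got$median, s$median, tolerance = 1e-12)
})
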