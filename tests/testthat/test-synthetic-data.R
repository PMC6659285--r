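test_that("world generation is deterministic and satisfies its contract", {
  cfg <- tiny_world_config(seed = 1)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)

  # every centroid has at least one point within the buffer radius
  for (j in seq_len(nrow(w1$neighbourhoods))) {
    d <- sqrt((w1$points$x - w1$neighbourhoods$x[j])^2 +
                (w1$points$y - w1$neighbourhoods$y[j])^2)
    expect_true(min(d) <= cfg$buffer_radius_m)
  }

  # single-neighbourhood case
  w3 <- generate_world(tiny_world_config(seed = 2, n_neighbourhoods = 1L,
                                         point_spacing_m = 100))
  d <- sqrt((w3$points$x - w3$neighbourhoods$x[1])^2 +
              (w3$points$y - w3$neighbourhoods$y[1])^2)
  expect_true(any(d <= 1000))
})

test_that("segment spacing yields floor(length/spacing) + 1 points", {
  expect_length(sample_segment(1000, 100), 11L)
  expect_length(sample_segment(950, 100), 10L)
  expect_error(sample_segment(1000, 0), "spacing")
})

test_that("world config validation rejects degenerate settings", {
  expect_error(world_config(point_spacing_m = 3000, buffer_radius_m = 1000),
               "config error")
  expect_error(world_config(headings = c(0, 0, 90)), "distinct")
  expect_error(world_config(headings = c(0, 360)), "360")
  expect_error(world_config(n_neighbourhoods = 0), ">= 1")
})

test_that("scene features are one simplex vector per (point, heading)", {
  ts <- tiny_scene_set(seed = 3)
  x <- scene_features_matrix(ts$scenes)
  expect_equal(nrow(ts$scenes),
               nrow(ts$world$points) * length(ts$cfg$headings))
  expect_true(all(abs(rowSums(x) - 1) < 1e-9))
  expect_equal(ncol(x), ts$cfg$n_object_classes)
  # determinism
  sc2 <- generate_scene_features(ts$world$points, ts$world$neighbourhoods,
                                 ts$cfg, ts$truth, seed = 3)
  expect_identical(ts$scenes, sc2)
  expect_error(generate_scene_features(ts$world$points[0],
                                       ts$world$neighbourhoods,
                                       ts$cfg, ts$truth, 1),
               "non-empty")
})

test_that("symmetric Dirichlet draws have component means 1/K", {
  set.seed(11)
  draws <- perceptPA:::rdirichlet(10000, rep(1, 4))
  expect_true(all(abs(colMeans(draws) - 0.25) < 0.01))
})

test_that("latent perception is the clipped linear score", {
  truth <- simulation_truth()
  K <- truth$n_object_classes
  p <- rep(1 / K, K)

  t0 <- simulation_truth(indicator_weights = matrix(0, 6, K),
                         indicator_intercepts = rep(5, 6))
  expect_equal(latent_perception(p, t0, "safe"), 5)

  t_hi <- simulation_truth(indicator_weights = matrix(1, 6, K),
                           indicator_intercepts = rep(20, 6))
  expect_equal(latent_perception(p, t_hi, "lively"), 10)

  # weights 10 * e1 on a 2-class composition, intercept 0 -> dot product
  W <- matrix(0, 6, K); W[, 1] <- 10
  t_dot <- simulation_truth(indicator_weights = W,
                            indicator_intercepts = rep(0, 6))
  expect_equal(latent_perception(c(0.3, 0.7, rep(0, K - 2)), t_dot, "safe"), 3)

  expect_error(latent_perception(c(0.5, 0.5), truth, "safe"),
               "dimension mismatch")
})

test_that("rater oracle adds clipped Gaussian noise", {
  expect_equal(rater_oracle(c(0, 3.3, 10), 0), c(0, 3.3, 10))
  set.seed(4)
  expect_true(all(rater_oracle(rep(10, 500), 2) <= 10))
  set.seed(5)
  r <- rater_oracle(rep(5, 10000), 0.5)
  expect_true(abs(sd(r) - 0.5) < 0.02)
  expect_error(rater_oracle(11, 0.1), "\\[0, 10\\]")
})

test_that("survey generation obeys the outcome model and IPAQ factoring", {
  cfg <- tiny_world_config(seed = 6)
  nb <- data.table::data.table(nbhd_id = sprintf("nb%02d", 1:4))
  for (ind in PERCEPT_INDICATORS) nb[, (ind) := c(4, 5, 6, 7)]

  # degenerate world: no noise, no effects -> eta equals the intercept
  b0 <- default_outcome_beta(); b0[] <- 0; b0[["(Intercept)"]] <- 5
  t0 <- simulation_truth(beta = b0, sigma2_u = 0, sigma2_e = 1e-12)
  sv0 <- generate_survey(nb, cfg, t0, seed = 1)
  expect_true(all(abs(sv0$eta_true - 5) < 1e-5))

  # factoring identity: days x minutes reconstructs total up to rounding
  truth <- simulation_truth()
  sv <- generate_survey(nb, cfg, truth, seed = 2)
  recon <- with(sv, light_days * light_min_per_day +
                  moderate_days * moderate_min_per_day +
                  vigorous_days * vigorous_min_per_day)
  expect_true(all(abs(recon - sv$total_pa_true) <= 3 * 3.5 + 3 * 0.5))
  expect_true(all(sv[, .(light_days, moderate_days, vigorous_days)] <= 7))
  # minutes zero whenever days zero
  for (k in c("light", "moderate", "vigorous")) {
    zero_days <- sv[[paste0(k, "_days")]] == 0
    expect_true(all(sv[[paste0(k, "_min_per_day")]][zero_days] == 0))
  }
  expect_true(all(sv$age >= 18))
  # determinism
  expect_identical(sv, generate_survey(nb, cfg, truth, seed = 2))
})

test_that("respondent totals follow the per-neighbourhood Poisson design", {
  cfg <- world_config(seed = 8)  # 35 x mean 23
  nb <- data.table::data.table(nbhd_id = sprintf("nb%02d", 1:35))
  for (ind in PERCEPT_INDICATORS) nb[, (ind) := 5]
  n <- vapply(1:20, function(r) {
    nrow(generate_survey(nb, cfg, simulation_truth(), seed = r))
  }, 0L)
  # total ~ Poisson(805): all runs within +-5 SD
  expect_true(all(abs(n - 805) < 5 * sqrt(805)))
})

test_that("latent point scores differ between neighbourhoods (ANOVA F)", {
  ts <- tiny_scene_set(seed = 9, cfg = tiny_world_config(
    seed = 9, n_neighbourhoods = 6L, cell_m = 900))
  lat <- latent_perception(ts$scenes, ts$truth, "safe")
  d2 <- outer(ts$world$points$x, ts$world$neighbourhoods$x, "-")^2 +
    outer(ts$world$points$y, ts$world$neighbourhoods$y, "-")^2
  nearest <- max.col(-d2)
  nb_of_image <- nearest[match(ts$scenes$point_id, ts$world$points$point_id)]
  fit <- stats::aov(lat ~ factor(nb_of_image))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_lt(p, 1e-6)
})

test_that("generated variance components match truth over replicates", {
  # method-of-moments check on the transformed outcome around its fixed part
  cfg <- world_config(seed = 10)
  nb <- data.table::data.table(nbhd_id = sprintf("nb%02d", 1:35))
  for (ind in PERCEPT_INDICATORS) nb[, (ind) := 5]
  b0 <- default_outcome_beta(); b0[] <- 0; b0[["(Intercept)"]] <- 5.3
  truth <- simulation_truth(beta = b0, sigma2_u = 0.022, sigma2_e = 0.141)
  s2u_hat <- s2e_hat <- numeric(200)
  for (r in 1:200) {
    sv <- generate_survey(nb, cfg, truth, seed = 30000 + r)
    dev <- sv$eta_true - 5.3
    gm <- tapply(dev, sv$nbhd_id, mean)
    nj <- tabulate(factor(sv$nbhd_id))
    s2e_hat[r] <- sum((dev - gm[sv$nbhd_id])^2) / (length(dev) - length(gm))
    msb <- sum(nj * (gm - mean(dev))^2) / (length(gm) - 1)
    s2u_hat[r] <- (msb - s2e_hat[r]) / mean(nj)
  }
  expect_lt(abs(mean(s2e_hat) - 0.141), 0.005)
  expect_lt(abs(mean(s2u_hat) - 0.022), 0.005)
})

test_that("simulation truth validates its parameters", {
  expect_error(simulation_truth(sigma2_u = -1), "sigma2_u")
  expect_error(simulation_truth(rater_sd = -0.1), "rater_sd")
  expect_error(simulation_truth(indicator_weights = matrix(0, 5, 12)),
               "6 x n_object_classes")
  expect_error(default_indicator_weights(5), "at least 7")
})
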