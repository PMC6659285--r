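test_that("initial model handles constant targets and is reproducible", {
  st <- constant_state(value = 7)
  x <- st$train_x
  expect_equal(perceptPA:::state_predict(st, x), rep(7, nrow(x)))
  expect_equal(unname(suppressWarnings(score_images(st, x[1:3, ]))),
               rep(7, 3), ignore_attr = TRUE)

  # same seed -> identical forest predictions
  set.seed(99); f1 <- rf_fit(x, seq_len(nrow(x)), ntree = 30)
  set.seed(99); f2 <- rf_fit(x, seq_len(nrow(x)), ntree = 30)
  expect_identical(rf_predict(f1, x), rf_predict(f2, x))

  cfgs <- scoring_config()
  expect_error(fit_initial_model(x[1, , drop = FALSE], 5, "safe", cfgs),
               "training error")
  expect_error(fit_initial_model(rbind(x[1, ], x[1, ]), c(5, 6), "safe",
                                 cfgs), "training error")
})

test_that("rolling RMSE matches its definition and brute force at each step", {
  tr <- data.table::data.table(recommended = c(4, 6), corrected = c(5, 5))
  expect_equal(perceptPA:::rolling_rmse(tr, 2), 1)
  expect_true(is.na(perceptPA:::rolling_rmse(tr, 3)))

  # oracle equivalence along a real calibration run
  ts <- tiny_scene_set(seed = 21)
  x <- scene_features_matrix(ts$scenes)
  cfgs <- scoring_config(initial_batch = 60, rmse_window = 10,
                         retrain_every = 5, seed = 21,
                         regressor_params = list(ntree = 40))
  oracle <- make_rater_oracle(ts$truth, "safe", rater_sd = 0.25)
  set.seed(21)
  st <- fit_initial_model(x[1:60, ], oracle(x[1:60, ]), "safe", cfgs)
  for (i in 61:90) st <- calibration_step(st, x[i, , drop = FALSE], oracle)
  expect_equal(st$images_consumed, 30L)
  expect_equal(nrow(st$trace), 30L)
  for (s in 10:30) {
    window <- st$trace[(s - 9):s]
    expect_equal(st$trace$rolling_rmse[s],
                 sqrt(mean((window$recommended - window$corrected)^2)))
  }
  expect_true(all(st$trace$rolling_rmse >= 0 & st$trace$rolling_rmse <= 10,
                  na.rm = TRUE))
})

test_that("calibration converges trivially when the oracle echoes the model", {
  st <- constant_state(value = 7, config = scoring_config(
    rmse_window = 20, rmse_threshold = 0.5, seed = 2))
  echo_oracle <- function(x) perceptPA:::state_predict(st, x)
  set.seed(2)
  stream <- matrix(runif(50 * 12), 50, 12); stream <- stream / rowSums(stream)
  out <- run_adversarial_calibration(st, stream, echo_oracle)
  expect_true(out$converged)
  expect_equal(out$images_consumed, 20L)  # exactly rmse_window steps
  expect_equal(out$trace$rolling_rmse[20], 0)

  # constant residual c -> rolling RMSE = c
  st2 <- constant_state(value = 5, config = scoring_config(
    rmse_window = 15, rmse_threshold = 10, seed = 3,
    retrain_every = 1000L))
  shift_oracle <- function(x) perceptPA:::state_predict(st2, x) + 2
  out2 <- run_adversarial_calibration(st2, stream, shift_oracle)
  expect_true(out2$converged)  # threshold 10 always converges after window
  expect_equal(out2$trace$rolling_rmse[15], 2)

  expect_error(run_adversarial_calibration(st, stream[1:10, ], echo_oracle),
               "exhausted")
})

test_that("the system learns the latent score on a synthetic world", {
  ts <- tiny_scene_set(seed = 31, cfg = tiny_world_config(
    seed = 31, n_neighbourhoods = 9L, point_spacing_m = 100))
  x <- scene_features_matrix(ts$scenes)
  lat <- latent_perception(ts$scenes, ts$truth, "beautiful")
  set.seed(31)
  idx <- sample(nrow(x))
  train <- idx[1:500]; hold <- idx[501:700]
  cfgs <- scoring_config(seed = 31)
  st <- fit_initial_model(x[train, ], lat[train], "beautiful", cfgs)
  pred <- perceptPA:::state_predict(st, x[hold, ])
  expect_gt(cor(pred, lat[hold]), 0.9)  # noiseless learnability
})

test_that("score_images is deterministic, bounded and type-checked", {
  ts <- tiny_scene_set(seed = 41)
  x <- scene_features_matrix(ts$scenes)
  cfgs <- scoring_config(initial_batch = 80, seed = 41,
                         regressor_params = list(ntree = 40))
  oracle <- make_rater_oracle(ts$truth, "lively", rater_sd = 0.25)
  set.seed(41)
  st <- fit_initial_model(x[1:80, ], oracle(x[1:80, ]), "lively", cfgs)
  expect_warning(s1 <- score_images(st, ts$scenes), "not converged")
  s2 <- suppressWarnings(score_images(st, ts$scenes))
  expect_identical(s1, s2)
  expect_true(all(s1$score >= 0 & s1$score <= 10))
  expect_equal(nrow(s1), nrow(ts$scenes))
  expect_error(suppressWarnings(score_images(st, x[, 1:5])),
               "feature length mismatch")
})

test_that("holdout validation handles shifts and degenerate inputs", {
  st <- constant_state(value = 5, n = 60, seed = 51)
  set.seed(51)
  x <- matrix(runif(40 * 12), 40, 12); x <- x / rowSums(x)

  # constant model scores -> degenerate status, not NaN
  v <- validate_holdout(st, x, function(z) runif(nrow(z), 0, 10),
                        holdout_n = 40)
  expect_equal(v$status, "degenerate")

  # shift invariance of Pearson r: oracle = model + 2
  ts <- tiny_scene_set(seed = 52)
  xm <- scene_features_matrix(ts$scenes)
  cfgs <- scoring_config(initial_batch = 100, seed = 52,
                         regressor_params = list(ntree = 40))
  lat <- latent_perception(ts$scenes, ts$truth, "safe")
  set.seed(52)
  st2 <- fit_initial_model(xm[1:100, ], lat[1:100], "safe", cfgs)
  shifted <- function(z) pmin(10, perceptPA:::state_predict(st2, z) + 2)
  v2 <- validate_holdout(st2, xm[101:200, ], shifted, holdout_n = 100)
  expect_equal(v2$status, "ok")
  expect_equal(v2$r, 1, tolerance = 1e-8)
  expect_equal(v2$n, 100)
})

test_that("scoring config validates its fields", {
  expect_error(scoring_config(rmse_window = 0), "rmse_window")
  expect_error(scoring_config(rmse_threshold = 0), "rmse_threshold")
  expect_error(scoring_config(retrain_every = 0), "retrain_every")
})
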