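#' Configuration of the human-machine adversarial scoring system
#'
#' Defaults are tuned for the synthetic world (12 object classes, rater
#' noise SD 0.25). The original field deployment used an initial batch of
#' 3000 rated images and a printed RMSE threshold of 5 on the 0-10 scale;
#' that threshold is extremely loose on a 0-10 scale (a near-random model
#' would pass), so the synthetic default is 0.5 and the deployment value
#' remains available as a documented "paper mode" setting.
#'
#' @param initial_batch number of pre-rated images fitting the first model
#'   (default 300).
#' @param rmse_window rolling-RMSE window length (default 100 images).
#' @param rmse_threshold convergence threshold in score units (default 0.5).
#' @param retrain_every refit the forest after this many corrections
#'   (default 25; set 1 to refit after every correction).
#' @param max_calibration_images hard cap on calibration images
#'   (default 5000).
#' @param regressor_params list passed to [rf_fit()] (ntree, mtry, min_node).
#' @param holdout_n validation holdout size (default 100).
#' @param seed integer seed for the scoring stage.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(initial_batch = 300L,
                           rmse_window = 100L,
                           rmse_threshold = 0.5,
                           retrain_every = 25L,
                           max_calibration_images = 5000L,
                           regressor_params = list(ntree = 150L,
                                                   mtry = NULL,
                                                   min_node = 5L),
                           holdout_n = 100L,
                           seed = 1L) {
  if (rmse_window < 1L) stop("rmse_window must be >= 1")
  if (rmse_threshold <= 0) stop("rmse_threshold must be > 0")
  if (retrain_every < 1L) stop("retrain_every must be >= 1")
  structure(list(initial_batch = as.integer(initial_batch),
                 rmse_window = as.integer(rmse_window),
                 rmse_threshold = rmse_threshold,
                 retrain_every = as.integer(retrain_every),
                 max_calibration_images = as.integer(max_calibration_images),
                 regressor_params = regressor_params,
                 holdout_n = as.integer(holdout_n),
                 seed = as.integer(seed)),
            class = "scoring_config")
}

fit_forest <- function(x, y, params) {
  rf_fit(x, y,
         ntree = params$ntree %||% 150L,
         mtry = params$mtry,
         min_node = params$min_node %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the initial scoring model from pre-rated scenes
#'
#' Trains the per-indicator forest regressor on the initial batch of rated
#' scene composition vectors. Predictions are always clipped to the 0-10
#' scale. Reproducible given the RNG state (seed the caller or use the
#' config seed through [run_scoring()]).
#'
#' @param features numeric matrix of scene compositions (rows = images) or a
#'   scenes data.table with `class_*` columns.
#' @param scores numeric vector of (volunteer) ratings, one per row.
#' @param indicator indicator name this model scores.
#' @param config a [scoring_config()].
#' @return a `scoring_state` object.
#' @export
fit_initial_model <- function(features, scores, indicator, config) {
  x <- if (is.matrix(features)) features else scene_matrix(
    data.table::as.data.table(features))
  if (nrow(x) < 2L || nrow(unique(x)) < 2L)
    stop("training error: need at least 2 rated scenes with distinct features")
  if (length(scores) != nrow(x))
    stop("one score per rated scene required")
  forest <- fit_forest(x, as.numeric(scores), config$regressor_params)
  structure(list(indicator = indicator,
                 forest = forest,
                 train_x = x,
                 train_y = as.numeric(scores),
                 trace = data.table::data.table(recommended = numeric(0),
                                                corrected = numeric(0),
                                                rolling_rmse = numeric(0)),
                 converged = FALSE,
                 images_consumed = 0L,
                 config = config),
            class = "scoring_state")
}

state_predict <- function(state, features) {
  x <- if (is.matrix(features)) features else scene_matrix(
    data.table::as.data.table(features))
  clip_score(rf_predict(state$forest, x))
}

rolling_rmse <- function(trace, window) {
  if (nrow(trace) < window) return(NA_real_)
  tail_idx <- (nrow(trace) - window + 1L):nrow(trace)
  sqrt(mean((trace$recommended[tail_idx] - trace$corrected[tail_idx])^2))
}

#' One calibration step of the adversarial loop
#'
#' The model recommends a score for the scene, the oracle (volunteer)
#' corrects it, the corrected pair joins the training set, the forest is
#' refit every `retrain_every` corrections, and the rolling RMSE over the
#' last `rmse_window` trace entries is updated.
#'
#' @param state a `scoring_state`.
#' @param scene a single scene: numeric composition vector or 1-row table.
#' @param oracle function mapping scene features to a corrected rating.
#' @return the updated `scoring_state`.
#' @export
calibration_step <- function(state, scene, oracle) {
  x <- if (is.matrix(scene)) scene else if (is.numeric(scene))
    matrix(scene, nrow = 1) else scene_matrix(data.table::as.data.table(scene))
  recommended <- state_predict(state, x)
  corrected <- as.numeric(oracle(x))
  state$train_x <- rbind(state$train_x, x)
  state$train_y <- c(state$train_y, corrected)
  state$images_consumed <- state$images_consumed + 1L
  if (state$images_consumed %% state$config$retrain_every == 0L)
    state$forest <- fit_forest(state$train_x, state$train_y,
                               state$config$regressor_params)
  state$trace <- rbind(state$trace, data.table::data.table(
    recommended = recommended, corrected = corrected,
    rolling_rmse = NA_real_))
  state$trace$rolling_rmse[nrow(state$trace)] <-
    rolling_rmse(state$trace, state$config$rmse_window)
  rr <- state$trace$rolling_rmse[nrow(state$trace)]
  state$converged <- !is.na(rr) && rr < state$config$rmse_threshold
  state
}

#' Run the adversarial calibration loop to convergence
#'
#' Consumes scenes from the stream until the rolling RMSE between
#' recommended and corrected scores over the last `rmse_window` images drops
#' below `rmse_threshold` (converged), or `max_calibration_images` scenes
#' have been consumed (not converged). The full trace is retained for audit.
#'
#' @param state a fitted `scoring_state`.
#' @param scene_stream matrix or scenes table; rows are presented in order.
#' @param oracle correcting oracle, as in [calibration_step()].
#' @param config a [scoring_config()]; defaults to the state's config.
#' @return the final `scoring_state`.
#' @export
run_adversarial_calibration <- function(state, scene_stream, oracle,
                                        config = state$config) {
  x <- if (is.matrix(scene_stream)) scene_stream else
    scene_matrix(data.table::as.data.table(scene_stream))
  if (nrow(x) < config$rmse_window)
    stop("scene stream exhausted before rmse_window scenes were available")
  state$config <- config
  budget <- min(nrow(x), config$max_calibration_images)
  for (i in seq_len(budget)) {
    state <- calibration_step(state, x[i, , drop = FALSE], oracle)
    if (state$converged) break
  }
  state
}

#' Score images with a calibrated model
#'
#' @param state a `scoring_state` (a warning is issued if not converged).
#' @param scenes scenes table with `image_id` and `class_*` columns, or a
#'   bare feature matrix.
#' @return data.table (image_id, indicator, score) when `scenes` carries
#'   image ids, otherwise a numeric score vector. Scores lie in `[0, 10]`.
#' @export
score_images <- function(state, scenes) {
  if (!state$converged)
    warning("scoring model has not converged; scores may be unreliable")
  s <- state_predict(state, scenes)
  if (!is.matrix(scenes) && "image_id" %in% names(scenes)) {
    return(data.table::data.table(image_id = scenes$image_id,
                                  indicator = state$indicator, score = s))
  }
  s
}

#' Validate a scoring model on a fresh holdout
#'
#' Pearson correlation between model scores and fresh oracle ratings on
#' `holdout_n` scenes disjoint from training and calibration.
#'
#' @param state a `scoring_state`.
#' @param scenes holdout scenes (matrix or table), disjoint from training.
#' @param oracle rating oracle.
#' @param holdout_n number of scenes used (first `holdout_n` rows).
#' @return list with `status` ("ok" or "degenerate"), and for "ok": `r`,
#'   `p`, `n`. Zero variance in either vector yields status "degenerate"
#'   rather than NaN propagation.
#' @export
validate_holdout <- function(state, scenes, oracle,
                             holdout_n = state$config$holdout_n) {
  x <- if (is.matrix(scenes)) scenes else
    scene_matrix(data.table::as.data.table(scenes))
  n <- min(holdout_n, nrow(x))
  x <- x[seq_len(n), , drop = FALSE]
  model_scores <- state_predict(state, x)
  ratings <- as.numeric(oracle(x))
  if (stats::sd(model_scores) == 0 || stats::sd(ratings) == 0)
    return(list(status = "degenerate", indicator = state$indicator, n = n,
                reason = "zero variance in model scores or ratings"))
  ct <- stats::cor.test(model_scores, ratings)
  list(status = "ok", indicator = state$indicator,
       r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Run the full scoring stage for all six indicators
#'
#' For each indicator: sample the initial batch of scenes and rate them with
#' the oracle, fit the initial forest, reserve a disjoint holdout, run the
#' adversarial calibration on the remaining scenes (random order), score all
#' images, and validate on the holdout. Seeded and deterministic.
#'
#' @param scenes scenes table from [generate_scene_features()].
#' @param truth a [simulation_truth()] supplying the rating oracle.
#' @param config a [scoring_config()].
#' @return list with `image_scores` (long data.table), `states`,
#'   `validation` (per-indicator list), and `trace` (long calibration trace).
#' @export
run_scoring <- function(scenes, truth, config = scoring_config()) {
  x <- scene_matrix(scenes)
  n <- nrow(x)
  need <- config$initial_batch + config$holdout_n + config$rmse_window
  if (n < need)
    stop(sprintf("scoring needs at least %d scenes, got %d", need, n))
  states <- list()
  validation <- list()
  scores_list <- list()
  trace_list <- list()
  for (i in seq_along(truth$indicators)) {
    ind <- truth$indicators[i]
    set.seed(stage_seed(config$seed, 10L + i))
    oracle <- make_rater_oracle(truth, ind)
    ord <- sample.int(n)
    init_idx <- ord[seq_len(config$initial_batch)]
    hold_idx <- ord[config$initial_batch + seq_len(config$holdout_n)]
    cal_idx <- ord[-seq_len(config$initial_batch + config$holdout_n)]

    st <- fit_initial_model(x[init_idx, , drop = FALSE],
                            oracle(x[init_idx, , drop = FALSE]), ind, config)
    st <- run_adversarial_calibration(st, x[cal_idx, , drop = FALSE], oracle)
    states[[ind]] <- st
    validation[[ind]] <- validate_holdout(st, x[hold_idx, , drop = FALSE],
                                          oracle)
    sc <- score_images(st, scenes)
    scores_list[[ind]] <- sc
    tr <- data.table::copy(st$trace)
    tr[, indicator := ind]
    tr[, step := .I]
    trace_list[[ind]] <- tr
  }
  list(image_scores = data.table::rbindlist(scores_list),
       states = states,
       validation = validation,
       trace = data.table::rbindlist(trace_list))
}
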