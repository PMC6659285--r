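# Small synthetic-world fixtures used across test files. Everything is
# generated in code at test time; nothing is stored on disk.

tiny_world_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_neighbourhoods = 4L, point_spacing_m = 150, cell_m = 600,
         block_m = 300, seed = seed),
    list(...))
  do.call(world_config, args)
}

# Reduced-scale configuration for end-to-end replicates (same noise and
# effect sizes as the defaults; only image counts are scaled down).
reduced_world_config <- function(seed = 1) {
  world_config(seed = seed, point_spacing_m = 150)
}

reduced_scoring_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(initial_batch = 150L, rmse_window = 100L, rmse_threshold = 0.5,
         retrain_every = 50L, max_calibration_images = 600L,
         regressor_params = list(ntree = 60L, min_node = 5L),
         holdout_n = 50L, seed = seed),
    list(...))
  do.call(scoring_config, args)
}

tiny_scene_set <- function(seed = 1, cfg = tiny_world_config(seed),
                           truth = simulation_truth()) {
  world <- generate_world(cfg)
  scenes <- generate_scene_features(world$points, world$neighbourhoods,
                                    cfg, truth, seed = seed)
  list(world = world, scenes = scenes, cfg = cfg, truth = truth)
}

scene_features_matrix <- function(scenes) {
  as.matrix(scenes[, grep("^class_", names(scenes)), with = FALSE])
}

# A scoring state fitted on a constant target: predicts that constant
# everywhere (useful for trivial-path tests).
constant_state <- function(value = 7, n = 40, k = 12, seed = 1,
                           config = scoring_config(seed = seed)) {
  set.seed(seed)
  x <- matrix(runif(n * k), n, k)
  x <- x / rowSums(x)
  fit_initial_model(x, rep(value, n), "safe", config)
}
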