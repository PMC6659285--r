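log_stage <- function(con, stage, ..., t0 = NULL) {
  counts <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                  collapse = " ")
  # wall time goes to stderr only, so the run-log file stays byte-stable
  if (!is.null(t0))
    message(sprintf("[perceptPA] %s %s elapsed=%.1fs", stage, counts,
                    as.numeric(Sys.time()) - t0))
  cat(sprintf("stage=%s %s\n", stage, counts), file = con)
}

#' Run the full pipeline: simulate, score, aggregate, fit
#'
#' One seed drives the world, the scene compositions, the rating oracle, the
#' adversarial calibration, the survey and the model suite; two invocations
#' with the same seed produce byte-identical output trees.
#'
#' Files written to `out_dir`: `points.geojson`, `neighbourhoods.geojson`,
#' `scenes.csv`, `truth.json`, `image_scores.csv`, `calibration_trace.csv`,
#' `validation.json`, `exposure_primary.csv`, `exposure_sensitivity.csv`,
#' `survey.csv`, `models.json`, `tables.txt`, `vif.csv`, `run.log`.
#'
#' @param config a configuration list from [read_config()]/[default_config()]
#'   or a path to a YAML file.
#' @param seed master integer seed (mandatory).
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return list with `suite`, `validation`, `world`, `truth`, `survey`,
#'   `exposure` tables, invisibly.
#' @export
run_all <- function(config = default_config(), seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory for pipeline runs")
  if (is.character(config)) config <- read_config(config)
  t0 <- as.numeric(Sys.time())
  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  } else logcon <- stderr()

  wcfg <- do.call(world_config, c(config$world, list(seed = seed)))
  truth <- do.call(simulation_truth,
                   c(list(n_object_classes = wcfg$n_object_classes),
                     config$truth))
  world <- generate_world(wcfg)
  log_stage(logcon, "world", points = nrow(world$points),
            neighbourhoods = nrow(world$neighbourhoods), t0 = t0)

  scenes <- generate_scene_features(world$points, world$neighbourhoods,
                                    wcfg, truth, seed = seed)
  log_stage(logcon, "scenes", images = nrow(scenes), t0 = t0)

  rp <- config$pipeline$radius_primary_m
  rs <- config$pipeline$radius_sensitivity_m
  true_expo <- true_neighbourhood_scores(scenes, world$points,
                                         world$neighbourhoods, truth, rp)
  nb <- merge(world$neighbourhoods,
              true_expo[, c("nbhd_id", truth$indicators), with = FALSE],
              by = "nbhd_id")
  survey <- build_outcomes(generate_survey(nb, wcfg, truth, seed = seed))
  log_stage(logcon, "survey", respondents = nrow(survey), t0 = t0)

  scfg <- do.call(scoring_config, c(config$scoring, list(seed = seed)))
  scored <- run_scoring(scenes, truth, scfg)
  conv <- vapply(scored$states, function(s) s$converged, TRUE)
  log_stage(logcon, "scoring", image_scores = nrow(scored$image_scores),
            converged = sum(conv), t0 = t0)

  img <- merge(scored$image_scores, scenes[, .(image_id, point_id)],
               by = "image_id")
  pts <- point_score_table(img, world$points,
                           expected_headings = length(wcfg$headings))
  expo_p <- build_exposure_table(pts, world$neighbourhoods, rp,
                                 indicators = truth$indicators)
  expo_s <- build_exposure_table(pts, world$neighbourhoods, rs,
                                 indicators = truth$indicators)
  log_stage(logcon, "aggregate",
            mean_points_per_nbhd = round(mean(expo_p$n_points), 1), t0 = t0)

  suite <- run_model_suite(survey, expo_p, expo_s,
                           transform = config$pipeline$transform,
                           method = config$pipeline$method)
  log_stage(logcon, "models", fitted = length(suite$fits),
            n_model1 = suite$n[["Model1"]], t0 = t0)

  if (!is.null(out_dir)) {
    w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                         row.names = FALSE)
    write_points_geojson(world$points, file.path(out_dir, "points.geojson"))
    write_points_geojson(world$neighbourhoods,
                         file.path(out_dir, "neighbourhoods.geojson"),
                         id_col = "nbhd_id")
    w(scenes, "scenes.csv")
    write_truth_json(truth, file.path(out_dir, "truth.json"))
    w(scored$image_scores, "image_scores.csv")
    w(scored$trace, "calibration_trace.csv")
    jsonlite::write_json(scored$validation,
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    w(expo_p, "exposure_primary.csv")
    w(expo_s, "exposure_sensitivity.csv")
    w(survey, "survey.csv")
    jsonlite::write_json(suite_as_list(suite),
                         file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_tables(suite), file.path(out_dir, "tables.txt"))
    w(suite$vif$table, "vif.csv")
    log_stage(logcon, "write", files = 14L, t0 = t0)
  }
  invisible(list(suite = suite, validation = scored$validation,
                 world = world, truth = truth, survey = survey,
                 exposure = list(primary = expo_p, sensitivity = expo_s),
                 config = config, seed = seed))
}

# JSON-serialisable view of a model suite.
suite_as_list <- function(suite) {
  fits <- lapply(suite$fits, function(f) list(
    coefficients = f$coefficients,
    sigma2_u = f$sigma2_u, sigma2_e = f$sigma2_e, icc = f$icc,
    loglik = f$loglik, aic = f$aic,
    n_individuals = f$n_individuals, n_groups = f$n_groups,
    n_dropped = f$n_dropped, method = f$method, converged = f$converged,
    outcome = f$spec$outcome, transform = f$spec$transform))
  list(fits = fits, n = as.list(suite$n), radii = as.list(suite$radii),
       exclusions = suite$exclusions,
       vif = list(table = suite$vif$table, max = suite$vif$max,
                  mean = suite$vif$mean))
}
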