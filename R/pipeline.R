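#' Derive weekly PA minutes from IPAQ-style items
#'
#' Per intensity, minutes per week = days/week x minutes/day; total PA is
#' the sum over light, moderate and vigorous.
#'
#' @param survey data.table with `*_days` and `*_min_per_day` columns.
#' @return the survey with `light_pa`, `moderate_pa`, `vigorous_pa`,
#'   `total_pa` columns added.
#' @export
build_outcomes <- function(survey) {
  sv <- data.table::as.data.table(data.table::copy(survey))
  for (k in c("light", "moderate", "vigorous")) {
    d <- sv[[paste0(k, "_days")]]
    m <- sv[[paste0(k, "_min_per_day")]]
    bad <- which(d < 0 | m < 0 | d > 7)
    if (length(bad))
      stop(sprintf("invalid IPAQ items (%s) at rows: %s", k,
                   paste(utils::head(bad, 5), collapse = ", ")))
    sv[, paste0(k, "_pa") := d * m]
  }
  sv[, total_pa := light_pa + moderate_pa + vigorous_pa]
  sv[]
}

# Fixed-effect terms and reference levels of the fully adjusted models.
analysis_terms <- function(indicators = PERCEPT_INDICATORS) {
  list(fixed = c(indicators, "gender", "age", "marital", "education",
                 "income_band", "household_size", "length_of_stay",
                 "functional_restriction"),
       ref_levels = list(gender = "female",
                         marital = "single_divorced_widowed",
                         education = "primary_or_below",
                         income_band = "le_10k"))
}

#' Model specification for one of the analysis-suite models
#'
#' @param outcome outcome column (`total_pa`, `light_pa`, ...).
#' @param transform outcome transform (default `log1p`).
#' @param method `"REML"` or `"ML"`.
#' @return a [model_spec()].
#' @export
suite_model_spec <- function(outcome = "total_pa", transform = "log1p",
                             method = "REML") {
  at <- analysis_terms()
  model_spec(outcome = outcome, fixed = at$fixed, group = "nbhd_id",
             ref_levels = at$ref_levels, method = method,
             transform = transform)
}

#' Run the seven-model analysis suite
#'
#' Model 1: total PA on all six perception indicators (jointly) plus the
#' full covariate set, exposures at the primary radius. Sensitivity models:
#' Model 2 excludes respondents with functional restrictions, Model 3
#' excludes respondents aged above 70, Model 4 swaps in exposures at the
#' sensitivity radius. Models 5-7 repeat Model 1 for light, moderate and
#' vigorous PA. A VIF report on Model 1's design matrix is attached.
#'
#' @param survey respondent table (outcomes are added via [build_outcomes()]
#'   if absent).
#' @param exposure_primary exposure table at the primary radius.
#' @param exposure_sensitivity exposure table at the sensitivity radius.
#' @param transform outcome transform (default `log1p`).
#' @param method estimation method (default REML).
#' @param age_cutoff Model 3 exclusion threshold (default 70 years).
#' @return a `model_suite` list: `fits` (Model1..Model7), `n`, `radii`,
#'   `exclusions`, `vif`.
#' @export
run_model_suite <- function(survey, exposure_primary, exposure_sensitivity,
                            transform = "log1p", method = "REML",
                            age_cutoff = 70) {
  sv <- data.table::as.data.table(survey)
  if (!"total_pa" %in% names(sv)) sv <- build_outcomes(sv)
  drop_cols <- intersect(PERCEPT_INDICATORS, names(sv))
  if (length(drop_cols)) sv <- sv[, !drop_cols, with = FALSE]

  merge_exposure <- function(expo) {
    m <- merge(sv, expo[, c("nbhd_id", PERCEPT_INDICATORS), with = FALSE],
               by = "nbhd_id")
    orphans <- setdiff(unique(sv$nbhd_id), unique(expo$nbhd_id))
    if (length(orphans))
      warning("dropping respondents in neighbourhoods without exposure: ",
              paste(orphans, collapse = ", "))
    m
  }
  d1 <- merge_exposure(exposure_primary)
  d4 <- merge_exposure(exposure_sensitivity)

  fits <- list()
  fits$Model1 <- fit_random_intercept(
    d1, suite_model_spec("total_pa", transform, method))
  fits$Model2 <- fit_random_intercept(
    d1[functional_restriction == FALSE],
    suite_model_spec("total_pa", transform, method))
  fits$Model3 <- fit_random_intercept(
    d1[age <= age_cutoff], suite_model_spec("total_pa", transform, method))
  fits$Model4 <- fit_random_intercept(
    d4, suite_model_spec("total_pa", transform, method))
  fits$Model5 <- fit_random_intercept(
    d1, suite_model_spec("light_pa", transform, method))
  fits$Model6 <- fit_random_intercept(
    d1, suite_model_spec("moderate_pa", transform, method))
  fits$Model7 <- fit_random_intercept(
    d1, suite_model_spec("vigorous_pa", transform, method))

  vif_report <- vif(fits$Model1$X)
  structure(list(
    fits = fits,
    n = vapply(fits, function(f) f$n_individuals, 0L),
    radii = c(primary = exposure_primary$radius_m[1],
              sensitivity = exposure_sensitivity$radius_m[1]),
    exclusions = list(
      Model2 = sum(d1$functional_restriction),
      Model3 = sum(d1$age > age_cutoff)),
    vif = vif_report
  ), class = "model_suite")
}

#' Render the analysis suite as fixed-format text tables
#'
#' One block per model in the journal layout: a "Fixed part" of
#' `estimate<stars> (SE)` rows, a "Random part" with the two variance
#' components, then ICC, sample sizes, log-likelihood and AIC. Output is
#' byte-stable for identical inputs.
#'
#' @param suite a `model_suite` from [run_model_suite()].
#' @return character vector of lines.
#' @export
render_tables <- function(suite) {
  lines <- character(0)
  for (nm in names(suite$fits)) {
    f <- suite$fits[[nm]]
    lines <- c(lines,
               sprintf("== %s (outcome: %s, method: %s) ==",
                       nm, f$spec$outcome, f$method),
               "Fixed part")
    ct <- f$coefficients
    lines <- c(lines, sprintf("  %-28s %9.3f%-3s (%.3f)",
                              ct$term, ct$estimate, ct$stars, ct$se))
    lines <- c(lines,
               "Random part",
               sprintf("  Var (neighbourhoods) %.4f", f$sigma2_u),
               sprintf("  Var (individuals)    %.4f", f$sigma2_e),
               sprintf("ICC %.4f", f$icc),
               sprintf("Number of individuals %d", f$n_individuals),
               sprintf("Number of neighbourhoods %d", f$n_groups),
               sprintf("Log likelihood %.3f", f$loglik),
               sprintf("AIC %.3f", f$aic),
               "")
  }
  lines
}

# One full synthetic replicate up to the Model-1 data (true or scored
# exposures); the workhorse of the recovery experiments.
replicate_model1 <- function(seed, world_cfg, truth, radius_m = 1000,
                             scoring_cfg = NULL) {
  wcfg <- world_cfg
  wcfg$seed <- seed
  world <- generate_world(wcfg)
  scenes <- generate_scene_features(world$points, world$neighbourhoods,
                                    wcfg, truth, seed = seed)
  true_expo <- true_neighbourhood_scores(scenes, world$points,
                                         world$neighbourhoods, truth,
                                         radius_m = radius_m)
  nb <- merge(world$neighbourhoods, true_expo[, c("nbhd_id", truth$indicators),
                                              with = FALSE], by = "nbhd_id")
  survey <- generate_survey(nb, wcfg, truth, seed = seed)
  survey <- build_outcomes(survey)

  expo <- if (is.null(scoring_cfg)) {
    true_expo
  } else {
    sc <- scoring_cfg
    sc$seed <- seed
    scored <- run_scoring(scenes, truth, sc)
    img <- merge(scored$image_scores,
                 scenes[, .(image_id, point_id)], by = "image_id")
    pts <- point_score_table(img, world$points,
                             expected_headings = length(wcfg$headings))
    build_exposure_table(pts, world$neighbourhoods, radius_m,
                         indicators = truth$indicators)
  }
  drop_cols <- intersect(truth$indicators, names(survey))
  sv <- if (length(drop_cols)) survey[, !drop_cols, with = FALSE] else survey
  dat <- merge(sv, expo[, c("nbhd_id", truth$indicators), with = FALSE],
               by = "nbhd_id")
  fit <- fit_random_intercept(
    dat, suite_model_spec("total_pa", truth$outcome_transform, "REML"))
  list(fit = fit, data = dat, true_exposure = true_expo, exposure = expo)
}

#' Parameter-recovery experiment for the outcome model
#'
#' Regenerates the synthetic world, true neighbourhood scores and survey
#' `n_replicates` times and refits the fully adjusted total-PA model with the
#' TRUE exposures, then summarises per-coefficient bias, RMSE, 95% Wald CI
#' coverage, sign recovery among estimates significant at the 0.10 level,
#' the type-I rate of the true-zero "wealthy" effect at the 0.05 level, and
#' recovery of the conditional ICC.
#'
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed.
#' @param world_cfg a [world_config()].
#' @param truth a [simulation_truth()].
#' @param use_scoring if `TRUE`, exposures come from the full adversarial
#'   scoring pipeline (`scoring_cfg`) instead of the latent truth.
#' @param scoring_cfg [scoring_config()] used when `use_scoring = TRUE`.
#' @return list with `coefficients` (per-term summary data.table),
#'   `estimates` (per-replicate long table), `icc` summary and
#'   `type1_wealthy`.
#' @export
parameter_recovery_experiment <- function(n_replicates, seed = 1L,
                                          world_cfg = world_config(),
                                          truth = simulation_truth(
                                            world_cfg$n_object_classes),
                                          use_scoring = FALSE,
                                          scoring_cfg = scoring_config()) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  rows <- vector("list", n_replicates)
  icc_est <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_out <- replicate_model1(stage_seed(seed, 1000L + r), world_cfg, truth,
                                scoring_cfg = if (use_scoring) scoring_cfg)
    f <- rep_out$fit
    rows[[r]] <- data.table::data.table(
      replicate = r, term = names(f$beta), estimate = f$beta, se = f$se,
      p = f$coefficients$p)
    icc_est[r] <- f$icc
  }
  est <- data.table::rbindlist(rows)
  bt <- data.table::data.table(term = names(truth$beta),
                               truth = as.numeric(truth$beta))
  est <- merge(est, bt, by = "term")
  est[, covered := abs(estimate - truth) <= qnorm(0.975) * se]
  est[, sig05 := p < 0.05]
  est[, sig10 := p < 0.10]
  est[, sign_ok := sign(estimate) == sign(truth)]

  coef_summary <- est[, .(
    truth = truth[1],
    mean_estimate = mean(estimate),
    bias = mean(estimate) - truth[1],
    rel_bias = if (truth[1] != 0) (mean(estimate) - truth[1]) / truth[1]
               else NA_real_,
    rmse = sqrt(mean((estimate - truth[1])^2)),
    coverage95 = mean(covered),
    rejection05 = mean(sig05),
    sign_recovery10 = if (truth[1] != 0) mean(sig10 & sign_ok) else NA_real_
  ), by = term]

  icc_truth <- icc(truth$sigma2_u, truth$sigma2_e)
  list(coefficients = coef_summary,
       estimates = est,
       icc = list(truth = icc_truth, median = stats::median(icc_est),
                  mean = mean(icc_est), estimates = icc_est),
       type1_wealthy = coef_summary[term == "wealthy", rejection05],
       n_replicates = n_replicates)
}

#' ICC-recovery experiment on null-effect worlds
#'
#' Generates surveys from a two-level model with no fixed effects beyond the
#' intercept (set to the log1p of roughly 200 weekly minutes) and variance
#' components fixed at the target ICC, fits the null random-intercept model,
#' and summarises the recovered ICC distribution.
#'
#' @param n_replicates number of simulated datasets.
#' @param seed master seed.
#' @param icc_true target intraclass correlation (default 0.137).
#' @param sigma2_e residual variance (default 0.141).
#' @param world_cfg a [world_config()] (only sample sizes are used).
#' @return list with `icc_true`, `median`, `estimates`.
#' @export
icc_recovery_experiment <- function(n_replicates = 200L, seed = 1L,
                                    icc_true = 0.137, sigma2_e = 0.141,
                                    world_cfg = world_config()) {
  sigma2_u <- sigma2_e * icc_true / (1 - icc_true)
  beta0 <- default_outcome_beta()
  beta0[] <- 0
  beta0[["(Intercept)"]] <- log1p(198.7)
  truth <- simulation_truth(world_cfg$n_object_classes, beta = beta0,
                            sigma2_u = sigma2_u, sigma2_e = sigma2_e)
  nb <- data.table::data.table(
    nbhd_id = sprintf("nb%02d", seq_len(world_cfg$n_neighbourhoods)))
  for (ind in truth$indicators) nb[, (ind) := 0]
  null_spec <- model_spec("total_pa", character(0), "nbhd_id",
                          method = "REML", transform = "log1p")
  est <- vapply(seq_len(n_replicates), function(r) {
    sv <- generate_survey(nb, world_cfg, truth,
                          seed = stage_seed(seed, 2000L + r))
    fit <- fit_random_intercept(build_outcomes(sv), null_spec)
    fit$icc
  }, 0)
  list(icc_true = icc_true, median = stats::median(est),
       mean = mean(est), estimates = est)
}
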