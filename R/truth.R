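#' Ground-truth parameters of the synthetic world
#'
#' Bundles every generating value of the simulation so each downstream stage
#' can be tested by parameter recovery: the latent linear perception function
#' per indicator, the volunteer-rater noise, the outcome model's fixed
#' effects and variance components, and the Dirichlet concentrations that
#' control between- and within-neighbourhood scene contrast.
#'
#' Defaults encode the stated world: six indicators on a 0-10 scale with
#' neighbourhood means near the reported descriptive values (wealthy 4.9,
#' safe 4.7, lively 4.8, depressing 6.3, boring 5.7, beautiful 3.9),
#' between-neighbourhood score SD about 0.4, outcome fixed effects equal to
#' the reported total-PA coefficients with the non-significant "wealthy"
#' effect set to an exact zero, and additional random components
#' `sigma2_u = 0.022`, `sigma2_e = 0.141` (null ICC contribution 0.135).
#' The default outcome transform is `log1p`: on that scale the implied mean
#' outcome (about 5.6, i.e. roughly 260 weekly minutes) is consistent with
#' coefficients of this magnitude, while raw minutes would not be.
#'
#' @param n_object_classes number of scene object classes K (>= 7 for the
#'   default weight construction).
#' @param indicator_weights optional 6 x K weight matrix (rows named by
#'   indicator); defaults to orthonormal zero-sum contrasts scaled so the
#'   image-level latent score SD is about 1.1 and the between-neighbourhood
#'   SD about 0.4 at the default concentrations.
#' @param indicator_intercepts length-6 intercepts of the latent perception
#'   functions.
#' @param rater_sd SD of the volunteer-rater Gaussian noise (score units).
#' @param beta named fixed-effect vector of the outcome model; names must
#'   match the fitted design-matrix columns.
#' @param sigma2_u between-neighbourhood outcome variance (>= 0).
#' @param sigma2_e within-neighbourhood residual variance (> 0).
#' @param outcome_transform `"log1p"` (default) or `"identity"`.
#' @param nbhd_concentration total Dirichlet concentration of neighbourhood
#'   mean compositions (controls between-neighbourhood contrast).
#' @param image_concentration total Dirichlet concentration of image
#'   compositions around their neighbourhood mean.
#' @param pa_shares_alpha Dirichlet parameters splitting total PA into
#'   light/moderate/vigorous shares (means roughly 0.51/0.22/0.26).
#' @param days_lambda Poisson rate for active days per week (truncated to
#'   1..7 for active intensities).
#' @return a `simulation_truth` object.
#' @export
simulation_truth <- function(n_object_classes = 12L,
                             indicator_weights = NULL,
                             indicator_intercepts = c(
                               wealthy = 4.902, safe = 4.718, lively = 4.832,
                               depressing = 6.286, boring = 5.721,
                               beautiful = 3.884),
                             rater_sd = 0.25,
                             beta = default_outcome_beta(),
                             sigma2_u = 0.022,
                             sigma2_e = 0.141,
                             outcome_transform = c("log1p", "identity"),
                             nbhd_concentration = 55,
                             image_concentration = 6.5,
                             pa_shares_alpha = c(light = 5.1, moderate = 2.2,
                                                 vigorous = 2.6),
                             days_lambda = 4) {
  outcome_transform <- match.arg(outcome_transform)
  K <- as.integer(n_object_classes)
  if (is.null(indicator_weights))
    indicator_weights <- default_indicator_weights(K)
  indicator_weights <- as.matrix(indicator_weights)
  if (nrow(indicator_weights) != 6L || ncol(indicator_weights) != K)
    stop("indicator_weights must be a 6 x n_object_classes matrix")
  rownames(indicator_weights) <- PERCEPT_INDICATORS
  if (sigma2_u < 0) stop("sigma2_u must be >= 0")
  # sigma2_e = 0 is admitted for degenerate no-noise test worlds; model
  # fitting itself still requires positive residual variance.
  if (sigma2_e < 0) stop("sigma2_e must be >= 0")
  if (rater_sd < 0) stop("rater_sd must be >= 0")
  structure(list(
    indicators = PERCEPT_INDICATORS,
    n_object_classes = K,
    indicator_weights = indicator_weights,
    indicator_intercepts = setNames(as.numeric(indicator_intercepts),
                                    PERCEPT_INDICATORS),
    rater_sd = rater_sd,
    beta = beta,
    sigma2_u = sigma2_u,
    sigma2_e = sigma2_e,
    outcome_transform = outcome_transform,
    nbhd_concentration = nbhd_concentration,
    image_concentration = image_concentration,
    pa_shares_alpha = pa_shares_alpha,
    days_lambda = days_lambda
  ), class = "simulation_truth")
}

#' Default latent perception weights
#'
#' Six orthonormal zero-sum contrast vectors over the K object classes
#' (from Helmert contrasts), scaled so that `sum(w^2) = 9 K`. Under the
#' default Dirichlet concentrations this yields image-level latent score SD
#' near 1.1 and between-neighbourhood SD near 0.4; orthogonality keeps the
#' six indicators identifiable in the outcome model.
#'
#' @param K number of object classes (>= 7).
#' @return 6 x K numeric matrix with rows named by indicator.
#' @export
default_indicator_weights <- function(K) {
  if (K < 7L) stop("need at least 7 object classes for 6 orthogonal contrasts")
  H <- stats::contr.helmert(K)[, 1:6, drop = FALSE]
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  W <- t(H) * sqrt(9 * K)
  rownames(W) <- PERCEPT_INDICATORS
  W
}

#' Default fixed effects of the synthetic outcome model
#'
#' The reported total-PA coefficients on the `log1p`-minutes scale, with the
#' non-significant "wealthy" effect set to zero so its type-I behaviour is
#' testable. Names match the design-matrix columns produced by the package's
#' model specification for the full covariate set.
#'
#' @return named numeric vector including the intercept.
#' @export
default_outcome_beta <- function() {
  c("(Intercept)" = 1.252,
    wealthy = 0, safe = 1.495, lively = 1.635, depressing = -1.232,
    boring = -1.227, beautiful = 1.009,
    gendermale = 0.064, age = 0.004, maritalmarried = -0.023,
    educationhigh_school = -0.049, educationcollege_or_above = -0.022,
    "income_band10_20k" = 0.104, "income_band20_40k" = 0.159,
    income_bandge_40k = 0.022,
    household_size = -0.026, length_of_stay = 0.001,
    functional_restrictionTRUE = -0.056)
}

# Dirichlet draws: n x K matrix; alpha either a vector or an n x K matrix.
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    g <- matrix(rgamma(length(alpha), shape = t(alpha)),
                nrow = n, byrow = TRUE)
  } else {
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), n)
  }
  g / rowSums(g)
}

#' Generate scene composition vectors for all sampling points
#'
#' Each neighbourhood receives a mean composition drawn from a symmetric
#' Dirichlet with total concentration `truth$nbhd_concentration`; every
#' sampling point inherits the mean of its nearest centroid, and each
#' (point, heading) image draws its composition from a Dirichlet centred on
#' that mean with total concentration `truth$image_concentration`. This
#' creates genuine between-neighbourhood perception contrast while images
#' within a neighbourhood vary realistically.
#'
#' @param points data.table from [generate_world()].
#' @param neighbourhoods data.table from [generate_world()].
#' @param cfg a [world_config()].
#' @param truth a [simulation_truth()].
#' @param seed integer seed.
#' @return data.table: image_id, point_id, heading, class_0..class_{K-1};
#'   every proportion row sums to 1.
#' @export
generate_scene_features <- function(points, neighbourhoods, cfg, truth,
                                    seed = cfg$seed) {
  if (nrow(points) == 0L) stop("points must be non-empty")
  K <- truth$n_object_classes
  set.seed(stage_seed(seed, 2L))
  J <- nrow(neighbourhoods)
  m <- rdirichlet(J, rep(truth$nbhd_concentration / K, K))  # J x K means

  # nearest-centroid assignment of points
  d2 <- outer(points$x, neighbourhoods$x, "-")^2 +
    outer(points$y, neighbourhoods$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")

  grid <- data.table::CJ(point_idx = seq_len(nrow(points)),
                         heading = cfg$headings, sorted = FALSE)
  data.table::setorder(grid, point_idx, heading)
  alpha <- m[nearest[grid$point_idx], , drop = FALSE] *
    truth$image_concentration
  comp <- rdirichlet(nrow(grid), alpha)
  colnames(comp) <- sprintf("class_%d", seq_len(K) - 1L)

  out <- data.table::data.table(
    image_id = sprintf("%s_h%03d", points$point_id[grid$point_idx],
                       as.integer(grid$heading)),
    point_id = points$point_id[grid$point_idx],
    heading = grid$heading)
  cbind(out, data.table::as.data.table(comp))
}

# Extract the composition matrix (class_* columns) from a scenes table.
scene_matrix <- function(scenes) {
  cols <- grep("^class_", names(scenes), value = TRUE)
  as.matrix(scenes[, cols, with = FALSE])
}

#' Latent perception score of scenes
#'
#' The noise-free score volunteers are assumed to perceive:
#' `clip(intercept + weights . proportions, 0, 10)`. Deterministic.
#'
#' @param features a proportion vector, a matrix of proportions (rows =
#'   scenes), or a scenes data.table with `class_*` columns.
#' @param truth a [simulation_truth()].
#' @param indicator one of the six indicator names.
#' @return numeric score(s) in `[0, 10]`.
#' @export
latent_perception <- function(features, truth, indicator) {
  indicator <- match.arg(indicator, truth$indicators)
  if (data.table::is.data.table(features) || is.data.frame(features))
    features <- scene_matrix(data.table::as.data.table(features))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  w <- truth$indicator_weights[indicator, ]
  if (ncol(features) != length(w))
    stop(sprintf("dimension mismatch: %d proportions vs %d weights",
                 ncol(features), length(w)))
  clip_score(truth$indicator_intercepts[[indicator]] +
               as.numeric(features %*% w))
}

#' Noisy volunteer-rater oracle
#'
#' Simulates a volunteer correcting a score: latent score plus Gaussian
#' noise with SD `rater_sd`, clipped to the 0-10 scale. Stochastic;
#' reproducible under the caller's RNG state.
#'
#' @param latent_score latent score(s) in `[0, 10]`.
#' @param rater_sd noise SD in score units (>= 0).
#' @return observed rating(s) in `[0, 10]`.
#' @export
rater_oracle <- function(latent_score, rater_sd) {
  if (any(latent_score < 0 | latent_score > 10))
    stop("latent scores must lie in [0, 10]")
  if (rater_sd < 0) stop("rater_sd must be >= 0")
  clip_score(latent_score + rnorm(length(latent_score), sd = rater_sd))
}

#' Build a rating oracle bound to one indicator
#'
#' @param truth a [simulation_truth()].
#' @param indicator indicator name.
#' @param rater_sd noise SD; defaults to `truth$rater_sd`.
#' @return function mapping scene features to noisy ratings.
#' @export
make_rater_oracle <- function(truth, indicator, rater_sd = truth$rater_sd) {
  force(indicator); force(rater_sd)
  function(features)
    rater_oracle(latent_perception(features, truth, indicator), rater_sd)
}

#' True (noise-free) neighbourhood perception scores
#'
#' Applies the aggregation chain (heading mean per point, buffer mean per
#' neighbourhood) to the latent scores, giving the ground-truth exposure
#' table the survey generator conditions on.
#'
#' @param scenes scenes table from [generate_scene_features()].
#' @param points,neighbourhoods tables from [generate_world()].
#' @param truth a [simulation_truth()].
#' @param radius_m buffer radius in metres.
#' @return data.table: nbhd_id, one column per indicator, n_points, radius_m.
#' @export
true_neighbourhood_scores <- function(scenes, points, neighbourhoods, truth,
                                      radius_m = 1000) {
  long <- data.table::rbindlist(lapply(truth$indicators, function(ind) {
    data.table::data.table(image_id = scenes$image_id,
                           point_id = scenes$point_id,
                           indicator = ind,
                           score = latent_perception(scenes, truth, ind))
  }))
  pts <- point_score_table(long, points)
  build_exposure_table(pts, neighbourhoods, radius_m,
                       indicators = truth$indicators)
}
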