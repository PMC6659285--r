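#' Generate the synthetic respondent survey
#'
#' Draws respondents per neighbourhood, covariates approximating the study
#' population margins (about 51% female, mean age 42.5, 82% married, income
#' concentrated in the 10-20k CNY/month band, household size 3.3, mean
#' length of stay 13.6 years, 4.1% with functional restrictions), then
#' generates the outcome from the two-level linear model
#' `eta_ij = x_ij' beta + u_j + e_ij` on the transformed scale, using each
#' neighbourhood's TRUE (noise-free) perception scores. Total weekly PA
#' minutes are back-transformed from `eta`, split into light/moderate/
#' vigorous shares, and factored into IPAQ-style (days/week, minutes/day)
#' items: active days are truncated-Poisson on 1..7 and minutes/day is the
#' rounded quotient, so `days * minutes/day` reconstructs each intensity's
#' minutes up to rounding (at most days/2 <= 3.5 minutes per intensity).
#'
#' @param neighbourhoods data.table carrying `nbhd_id` plus the six true
#'   perception score columns (as from [true_neighbourhood_scores()]).
#' @param cfg a [world_config()].
#' @param truth a [simulation_truth()].
#' @param seed integer seed.
#' @return data.table with one row per respondent: identifiers, covariates,
#'   IPAQ items (`*_days`, `*_min_per_day`), and generator ground truth
#'   (`eta_true`, `total_pa_true`, `u_true`).
#' @export
generate_survey <- function(neighbourhoods, cfg, truth, seed = cfg$seed) {
  missing_ind <- setdiff(truth$indicators, names(neighbourhoods))
  if (length(missing_ind))
    stop("neighbourhoods must carry true scores for: ",
         paste(missing_ind, collapse = ", "))
  set.seed(stage_seed(seed, 3L))
  J <- nrow(neighbourhoods)
  n_j <- pmax(1L, rpois(J, cfg$respondents_per_nbhd_mean))
  n <- sum(n_j)
  jj <- rep(seq_len(J), n_j)

  sv <- data.table::data.table(
    person_id = sprintf("p%05d", seq_len(n)),
    nbhd_id = neighbourhoods$nbhd_id[jj],
    gender = ifelse(runif(n) < 0.493, "male", "female"),
    age = pmin(90L, pmax(18L, as.integer(round(rnorm(n, 42.5, 13.8))))),
    marital = ifelse(runif(n) < 0.822, "married", "single_divorced_widowed"),
    education = sample(c("primary_or_below", "high_school",
                         "college_or_above"), n, replace = TRUE,
                       prob = c(0.028, 0.513, 0.459)),
    income_band = sample(c("le_10k", "10_20k", "20_40k", "ge_40k"), n,
                         replace = TRUE, prob = c(0.080, 0.710, 0.152, 0.058)),
    household_size = pmax(1L, as.integer(round(rnorm(n, 3.3, 0.9)))),
    length_of_stay = pmax(1, round(rgamma(n, shape = 1.45, scale = 9.4), 1)),
    functional_restriction = runif(n) < 0.041
  )

  # linear predictor on the transformed scale, using TRUE neighbourhood scores
  scores <- as.matrix(
    neighbourhoods[jj, truth$indicators, with = FALSE])
  b <- truth$beta
  eta <- b[["(Intercept)"]] +
    as.numeric(scores %*% b[truth$indicators]) +
    b[["gendermale"]] * (sv$gender == "male") +
    b[["age"]] * sv$age +
    b[["maritalmarried"]] * (sv$marital == "married") +
    b[["educationhigh_school"]] * (sv$education == "high_school") +
    b[["educationcollege_or_above"]] * (sv$education == "college_or_above") +
    b[["income_band10_20k"]] * (sv$income_band == "10_20k") +
    b[["income_band20_40k"]] * (sv$income_band == "20_40k") +
    b[["income_bandge_40k"]] * (sv$income_band == "ge_40k") +
    b[["household_size"]] * sv$household_size +
    b[["length_of_stay"]] * sv$length_of_stay +
    b[["functional_restrictionTRUE"]] * sv$functional_restriction

  u <- rnorm(J, sd = sqrt(truth$sigma2_u))
  e <- rnorm(n, sd = sqrt(truth$sigma2_e))
  eta <- eta + u[jj] + e
  total <- if (truth$outcome_transform == "log1p") {
    pmax(expm1(eta), 0)
  } else {
    pmax(eta, 0)
  }

  shares <- rdirichlet(n, truth$pa_shares_alpha)
  intens <- c("light", "moderate", "vigorous")
  for (k in seq_along(intens)) {
    minutes <- shares[, k] * total
    days <- integer(n)
    active <- minutes >= 0.5
    days[active] <- sample_trunc_pois(sum(active), truth$days_lambda)
    mpd <- integer(n)
    mpd[active] <- as.integer(round(minutes[active] / days[active]))
    sv[, paste0(intens[k], "_days") := days]
    sv[, paste0(intens[k], "_min_per_day") := mpd]
  }
  sv[, eta_true := eta]
  sv[, total_pa_true := total]
  sv[, u_true := u[jj]]
  sv[]
}

# Poisson truncated to {1..7}: exact inverse-probability sampling.
sample_trunc_pois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  probs <- stats::dpois(1:7, lambda)
  sample(1:7, n, replace = TRUE, prob = probs)
}
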