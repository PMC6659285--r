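test_that("profiled fit matches dense brute-force oracles (REML and ML)", {
  inst <- small_mlm_instance(seed = 42)
  f <- fit_random_intercept(inst$data, model_spec("y", c("x1", "x2"), "g"))
  bf <- brute_force_reml(inst$y, inst$X, inst$g)
  expect_equal(f$loglik, bf$loglik, tolerance = 1e-6)
  expect_equal(unname(f$beta), bf$beta, tolerance = 1e-5)
  expect_equal(f$sigma2_u, bf$s2u, tolerance = 1e-3)
  expect_equal(f$sigma2_e, bf$s2e, tolerance = 1e-4)

  fml <- fit_random_intercept(inst$data,
                              model_spec("y", c("x1", "x2"), "g",
                                         method = "ML"))
  bfml <- brute_force_ml(inst$y, inst$X, inst$g)
  expect_equal(fml$loglik, bfml$loglik, tolerance = 1e-6)
  expect_equal(unname(fml$beta), unname(bfml$beta), tolerance = 1e-4)
})

test_that("profiled REML agrees with lme4 on an independent implementation", {
  skip_if_not_installed("lme4")
  inst <- small_mlm_instance(seed = 7)
  f <- fit_random_intercept(inst$data, model_spec("y", c("x1", "x2"), "g"))
  m <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = inst$data, REML = TRUE)
  expect_equal(f$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(c(f$sigma2_u, f$sigma2_e), vc$vcov, tolerance = 1e-5)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 1e-5)
})

test_that("balanced one-way layout matches the closed-form REML estimators", {
  set.seed(13)
  g <- rep(1:8, each = 12)
  y <- rnorm(8, sd = 0.7)[g] + rnorm(96, sd = 1.1)
  f <- fit_random_intercept(data.frame(y = y, g = g),
                            model_spec("y", character(0), "g"))
  cf <- anova_reml_closed_form(y, g)
  expect_equal(f$sigma2_e, cf$s2e, tolerance = 1e-6)
  expect_equal(f$sigma2_u, cf$s2u, tolerance = 1e-6)
})

test_that("zero between-group variance collapses to OLS at the boundary", {
  set.seed(17)
  g <- rep(1:6, each = 10)
  x <- rnorm(60)
  e <- rnorm(60)
  e <- e - stats::ave(e, g)   # group means exactly zero -> MSB < MSW
  x <- x - stats::ave(x, g) + rnorm(60, sd = 1e-8)
  y <- 2 + 0.5 * x + e
  f <- fit_random_intercept(data.frame(y = y, x = x, g = g),
                            model_spec("y", "x", "g"))
  expect_equal(f$sigma2_u, 0)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(f$beta), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("icc follows its closed form and guards its domain", {
  expect_equal(icc(0, 1), 0)
  expect_equal(round(icc(0.022, 0.141), 4), 0.1350)
  expect_gt(icc(1, 1e-12), 1 - 1e-6)  # -> 1 as residual variance vanishes
  expect_error(icc(0, 0), "undefined")
  expect_error(icc(-0.1, 1), "non-negative")
})

test_that("vif matches closed forms and flags exact collinearity", {
  set.seed(23)
  # predictors orthogonal to each other and to the constant -> VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, 2:4]
  v <- vif(q)
  expect_equal(v$table$vif, rep(1, 3), tolerance = 1e-10)

  # exact sample correlation 0.9 -> VIF = 1 / (1 - 0.81)
  u <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 2), 100, 2))))[, 2:3]
  x1 <- u[, 1]
  x2 <- 0.9 * u[, 1] + sqrt(1 - 0.81) * u[, 2]
  v2 <- vif(cbind(x1, x2))
  expect_equal(v2$max, 1 / (1 - 0.81), tolerance = 1e-8)
  expect_equal(round(v2$max, 3), 5.263)

  # duplicated column -> infinite, flagged, no exception
  v3 <- vif(cbind(x1, x2, x1_dup = x1))
  expect_true(any(v3$table$collinear))
  expect_equal(v3$max, Inf)
})

test_that("wald table applies the printed star thresholds strictly", {
  wt <- wald_table(c(a = 0, b = 1.495, c = 1), se = c(1, 0.558, 1 / 1.96))
  expect_equal(wt$p[1], 1)
  expect_equal(wt$stars[1], "")
  # reported coefficient/SE pair: z = 2.679, p ~ 0.0074 -> ***
  expect_equal(wt$z[2], 2.679, tolerance = 1e-3)
  expect_equal(wt$p[2], 0.00738, tolerance = 1e-2)
  expect_equal(wt$stars[2], "***")
  # z = 1.96: p marginally below 0.05 -> strict inequality gives **
  expect_equal(wt$p[3], 0.05, tolerance = 1e-3)
  expect_equal(wt$stars[3], "**")
  # exactly at a threshold: no star at that level
  wt2 <- wald_table(c(d = qnorm(0.975)), se = 1)
  expect_equal(wt2$p, 0.05, tolerance = 1e-12)
  expect_equal(wt2$stars, "*")
})

test_that("fit is invariant to row order and group relabelling", {
  inst <- small_mlm_instance(seed = 29)
  d <- inst$data
  f1 <- fit_random_intercept(d, model_spec("y", c("x1", "x2"), "g"))
  set.seed(29)
  d2 <- d[sample(nrow(d)), ]
  d2$g <- paste0("zz", rev(LETTERS)[d2$g])
  f2 <- fit_random_intercept(d2, model_spec("y", c("x1", "x2"), "g"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$sigma2_u, f2$sigma2_u, tolerance = 1e-6)
})

test_that("rank deficiency is reported with the aliased terms", {
  inst <- small_mlm_instance(seed = 31)
  d <- inst$data
  d$x3 <- d$x1 + d$x2
  expect_error(fit_random_intercept(d, model_spec("y", c("x1", "x2", "x3"),
                                                  "g")),
               "rank deficient.*x3")
})

test_that("missing rows are dropped listwise with a recorded count", {
  inst <- small_mlm_instance(seed = 37)
  d <- inst$data
  d$y[c(3, 10, 55)] <- NA
  f <- fit_random_intercept(d, model_spec("y", c("x1", "x2"), "g"))
  expect_equal(f$n_dropped, 3L)
  expect_equal(f$n_individuals, 57L)
})

test_that("ML and REML variance estimates converge with many groups", {
  gap <- vapply(c(8, 40), function(J) {
    set.seed(J)
    g <- rep(seq_len(J), each = 8)
    y <- rnorm(J, sd = 0.5)[g] + rnorm(8 * J)
    d <- data.frame(y = y, g = g)
    fr <- fit_random_intercept(d, model_spec("y", character(0), "g"))
    fm <- fit_random_intercept(d, model_spec("y", character(0), "g",
                                             method = "ML"))
    abs(fr$sigma2_u - fm$sigma2_u)
  }, 0)
  expect_lt(gap[2], gap[1])
})

test_that("model guards: group count and unknown columns", {
  d <- data.frame(y = rnorm(10), g = 1)
  expect_error(fit_random_intercept(d, model_spec("y", character(0), "g")),
               "at least 2 groups")
  expect_error(fit_random_intercept(d, model_spec("z", character(0), "g")),
               "not found")
})
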